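test_that("network size counts only species with links", {
  expect_identical(network_size(net_from(matrix(1L, 2, 3))), 5L)
  net <- mixed_toy()
  pr <- prune(net, "all_nonmutualistic")
  expect_identical(network_size(net) - network_size(pr$pruned),
                   length(pr$dropped_birds) + length(pr$dropped_plants))
})

test_that("weighted connectance matches its closed forms", {
  # single link: LD = 1 over 2 species
  expect_equal(weighted_connectance(net_from(matrix(3L, 1, 1))), 0.5)
  # uniform complete matrices of any shape: 0.5
  for (dims in list(c(2, 5), c(3, 3), c(4, 2)))
    expect_equal(weighted_connectance(net_from(matrix(2L, dims[1], dims[2]))),
                 0.5)
  # 2x2 equal-weight diagonal: each species has one effective partner
  expect_equal(weighted_connectance(net_from(diag(2L) * 3L)), 0.25)
})

test_that("weighted NODF reproduces hand-computed values", {
  # equal marginals (checkerboard): every pair scores 0
  expect_equal(weighted_nodf(net_from(diag(2L))), 0)
  # perfectly nested triangle
  m <- matrix(c(3L, 2L, 1L, 2L, 1L, 0L, 1L, 0L, 0L), 3, 3, byrow = TRUE)
  expect_equal(weighted_nodf(net_from(m)), 100)
  # row pair 50, column pair 50
  expect_equal(weighted_nodf(net_from(matrix(c(2L, 1L, 1L, 1L), 2, 2,
                                             byrow = TRUE))), 50)
  # degenerate shapes are undefined
  expect_true(is.na(weighted_nodf(net_from(matrix(1:3, 1, 3)))))
})

test_that("weighted NODF agrees with vegan where the conventions coincide", {
  skip_if_not_installed("vegan")
  # vegan ranks and ties by binary fill, this package by marginal total;
  # both treat every pair identically when the strict orders of fill and
  # total coincide (ties then coincide too, and tied pairs score 0 on both
  # sides). Staircase-support matrices with random weights give distinct
  # fills on both guilds; keep the draws whose totals order the same way.
  consistent <- function(mat) {
    fills <- rowSums(mat > 0); tots <- rowSums(mat)
    all(outer(fills, fills, ">") == outer(tots, tots, ">"))
  }
  checked <- 0
  for (seed in 1:200) {
    set.seed(seed)
    n <- 4
    w <- matrix(0L, n, n)
    for (i in seq_len(n))
      w[i, seq_len(n + 1L - i)] <- sample.int(9L, n + 1L - i, replace = TRUE)
    dimnames(w) <- list(paste0("P", 1:n), paste0("B", 1:n))
    net <- labeled_network(w, "seed_dispersal")
    if (!consistent(w) || !consistent(t(w))) next
    checked <- checked + 1
    expect_equal(weighted_nodf(net),
                 unname(vegan::nestednodf(w, order = TRUE,
                                          weighted = TRUE)$statistic["NODF"]),
                 tolerance = 1e-10)
  }
  expect_gte(checked, 20)
})

test_that("H2' hits its extremes and the greedy minimum is exact on small cases", {
  # one-to-one diagonal: complete specialization
  expect_equal(h2_prime(net_from(diag(4L) * 2L)), 1)
  # exact outer product of the marginals: no specialization
  expect_equal(h2_prime(net_from(matrix(c(4L, 2L, 2L, 1L), 2, 2))), 0)
  # greedy minimum entropy equals exhaustive enumeration over tables
  for (margins in list(list(r = c(4, 2), c = c(3, 3)),
                       list(r = c(5, 2, 1), c = c(4, 3, 1)),
                       list(r = c(3, 3, 2), c = c(6, 1, 1)))) {
    expect_equal(dispnet:::h2_min_greedy(margins$r, margins$c),
                 oracle_h2min(margins$r, margins$c), tolerance = 1e-12)
  }
})

test_that("Barber modularity matches closed forms and the independent evaluator", {
  b <- matrix(0L, 4, 4); b[1:2, 1:2] <- 2L; b[3:4, 3:4] <- 2L
  net <- net_from(b)
  species <- c(rownames(net$weights), colnames(net$weights))
  two_mod <- stats::setNames(rep(c("a", "b", "a", "b"), c(2, 2, 2, 2)),
                             species)
  expect_equal(barber_q(net, two_mod), 0.5)
  one_mod <- stats::setNames(rep("m", 8), names(two_mod))
  expect_equal(barber_q(net, one_mod), 0)
  anti <- stats::setNames(rep(c("a", "b", "b", "a"), c(2, 2, 2, 2)),
                          names(two_mod))
  expect_equal(barber_q(net, anti), -0.5)
  expect_error(barber_q(net, two_mod[-1]), "cover")

  for (seed in 1:10) {
    net <- random_net(seed, P = 3, A = 4)
    w <- net$weights
    part <- stats::setNames(sample(c("x", "y", "z"), 7, replace = TRUE),
                            c(rownames(w), colnames(w)))
    expect_equal(barber_q(net, part),
                 oracle_q(w, part[rownames(w)], part[colnames(w)]),
                 tolerance = 1e-12)
  }
})

test_that("the modularity search finds the exhaustive optimum on small nets", {
  b <- matrix(0L, 3, 3); b[1, 1] <- 2L; b[2:3, 2:3] <- 2L
  fit <- lpawb_plus(net_from(b), seed = 1)
  expect_equal(fit$q, oracle_max_q(b), tolerance = 1e-10)
  # uniform matrix: no partition beats a single module
  expect_equal(lpawb_plus(net_from(matrix(2L, 3, 3)), seed = 1)$q, 0,
               tolerance = 1e-10)
  for (seed in 1:15) {
    net <- random_net(seed, P = 3, A = 3, max_w = 4)
    fit <- lpawb_plus(net, seed = seed, repeats = 10)
    expect_equal(fit$q, oracle_max_q(net$weights), tolerance = 1e-8)
    # the reported Q is consistent with the reported partition
    expect_equal(fit$q, barber_q(net, fit$partition), tolerance = 1e-10)
  }
})

test_that("metrics are invariant to permutation and weight scaling", {
  for (seed in 1:5) {
    net <- random_net(seed, P = 4, A = 5)
    w <- net$weights
    wp <- w[sample(nrow(w)), sample(ncol(w))]
    netp <- labeled_network(wp, "seed_dispersal")
    expect_equal(weighted_nodf(net), weighted_nodf(netp))
    expect_equal(h2_prime(net), h2_prime(netp))
    expect_equal(lpawb_plus(net, seed = 1, repeats = 5)$q,
                 lpawb_plus(netp, seed = 1, repeats = 5)$q, tolerance = 1e-8)

    net3 <- labeled_network(w * 3L, "seed_dispersal")
    expect_equal(weighted_nodf(net3), weighted_nodf(net))
    expect_equal(h2_prime(net3), h2_prime(net))
    expect_equal(weighted_connectance(net3), weighted_connectance(net))
    expect_equal(lpawb_plus(net3, seed = 1, repeats = 5)$q,
                 lpawb_plus(net, seed = 1, repeats = 5)$q, tolerance = 1e-8)
  }
})

test_that("the tidy metric report carries all five metrics per state", {
  rep <- network_metrics(mixed_toy(), state = "original", seed = 7)
  expect_identical(nrow(rep), 5L)
  expect_setequal(rep$metric, c("size", "weighted_connectance",
                                "weighted_nodf", "h2_prime", "modularity_q"))
  expect_true(all(rep$seed == 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  expect_identical(nrow(utils::read.csv(path)), 5L)
})
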