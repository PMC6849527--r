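test_that("one-tailed Wilcoxon handles unanimity, zeros and symmetry", {
  # five unanimous decreases: p = 1/32
  w <- wilcoxon_one_tailed(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 8), "decrease")
  expect_equal(w$p_value, 1 / 32)
  expect_identical(w$n_used, 5L)
  # a zero difference is dropped before testing
  wz <- wilcoxon_one_tailed(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 9), "decrease")
  expect_identical(wz$n_used, 4L)
  expect_equal(wz$p_value, 1 / 16)
  # antisymmetric differences sit near the middle of the distribution
  b <- c(0, 0, 0, 0, 0, 0)
  a <- c(1, -1, 2, -2, 3, -3)
  pa <- wilcoxon_one_tailed(b, a, "decrease")$p_value
  expect_gte(pa, 0.4); expect_lte(pa, 0.65)
  # all-zero differences are undefined
  expect_true(is.na(wilcoxon_one_tailed(1:5, 1:5, "decrease")$p_value))
})

test_that("exact Wilcoxon p equals 2^n sign enumeration, ties included", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(3:10, 1)
    before <- sample(0:6, n, replace = TRUE)
    after <- before + sample(c(-3:-1, 1:3), n, replace = TRUE)
    for (dir in c("decrease", "increase")) {
      expect_equal(wilcoxon_one_tailed(before, after, dir)$p_value,
                   oracle_wilcoxon(before, after, dir), tolerance = 1e-12)
    }
  }
})

test_that("tie-free exact p matches stats::wilcox.test", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    d <- sample(setdiff(-50:50, 0), n)  # distinct |d| almost surely not; force
    d <- sign(d) * sample(seq_len(60), n)  # distinct magnitudes
    before <- rnorm(n)
    after <- before + d
    ref <- stats::wilcox.test(after, before, paired = TRUE,
                              alternative = "less", exact = TRUE)$p.value
    expect_equal(wilcoxon_one_tailed(before, after, "decrease")$p_value, ref,
                 tolerance = 1e-12)
  }
})

test_that("the large-sample branch approximates the exact branch", {
  set.seed(12)
  before <- rnorm(30)
  after <- before - abs(rnorm(30, 0.4))
  p_norm <- wilcoxon_one_tailed(before, after, "decrease")$p_value
  ref <- stats::wilcox.test(after, before, paired = TRUE,
                            alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(p_norm, ref, tolerance = 1e-10)
})

test_that("Spearman one-tailed matches exhaustive permutation at small n", {
  expect_equal(spearman_one_tailed(1:5, 2:6, "positive")$rho, 1)
  expect_equal(spearman_one_tailed(1:5, 6:2, "positive")$rho, -1)
  expect_true(is.na(spearman_one_tailed(1:4, rep(2, 4), "positive")$rho))
  set.seed(4)
  for (k in 1:10) {
    x <- sample(1:20, 4); y <- sample(1:20, 4)
    got <- spearman_one_tailed(x, y, "positive")
    ref <- stats::cor.test(x, y, method = "spearman",
                           alternative = "greater", exact = TRUE)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the Bernoulli multiple-test probability is an exact binomial mass", {
  expect_equal(moran_probability(2, 1, 0.5), 0.5)
  expect_equal(moran_probability(6, 0, 0.05), 0.95^6)
  # normalization over K, and agreement with the binomial density oracle
  for (N in c(3, 6, 11)) for (alpha in c(0.05, 0.3)) {
    probs <- vapply(0:N, function(K) moran_probability(N, K, alpha), 0)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_equal(probs, stats::dbinom(0:N, N, alpha), tolerance = 1e-12)
  }
  expect_error(moran_probability(3, 4, 0.05), "K <= N")
  expect_error(moran_probability(3, 1, 1.2), "alpha")
})

test_that("comparison tables follow the reporting conventions", {
  # CV% fixture: sample sd of (2, 4) over |mean| = 47.1%
  s <- dispnet:::summarize_pair(c(0, 0), c(2, 4), "increase")
  expect_equal(s$cv_percent, 100 * sd(c(2, 4)) / 3, tolerance = 1e-12)
  expect_equal(round(s$cv_percent, 1), 47.1)

  cfg <- synthetic_config(n_plants = 10L, n_birds = 12L, seed = 2)
  nets <- generate_ensemble(cfg)$networks
  netrep <- NULL; sprep <- NULL
  for (net in nets) {
    pr <- prune(net, "all_nonmutualistic")$pruned
    for (st in list(list(net, "original"), list(pr, "pruned_all"))) {
      netrep <- rbind(netrep, network_metrics(st[[1]], st[[2]], seed = 1))
      co <- suppressWarnings(simulate_coextinction(st[[1]]))
      netrep <- rbind(netrep, data.frame(network_id = net$network_id,
                                         state = st[[2]], metric = "robustness",
                                         value = robustness(co), seed = 1))
      sm <- species_metrics(st[[1]], st[[2]])
      res <- resilience_75(co)
      sm$resilience_75 <- NA_real_
      hit <- sm$guild == "plant" & sm$species %in% names(res)
      sm$resilience_75[hit] <- res[sm$species[hit]]
      sprep <- rbind(sprep, sm)
    }
  }
  tabs <- build_comparison_tables(netrep, sprep,
                                  before_state = "original",
                                  after_state = "pruned_all")
  # 6 network-level rows, 5 species-level rows
  expect_identical(nrow(tabs$network_level), 6L)
  expect_identical(nrow(tabs$species_level), 5L)
  expect_setequal(tabs$species_level$metric,
                  c("degree", "frequency", "d_prime", "resilience_75",
                    "strength"))
  expect_identical(nrow(tabs$per_network), 5L * length(nets))
  expect_identical(tabs$moran$level, c("network_level", "species_level"))
  expect_true(all(tabs$moran$K <= tabs$moran$N))

  # identical states: zero changes and undefined tests
  same <- build_comparison_tables(
    transform(netrep[netrep$state == "original", ], state = "x"),
    transform(sprep[sprep$state == "original", ], state = "x"),
    before_state = "x", after_state = "x")
  expect_true(all(same$network_level$mean_change_absolute == 0))
  expect_true(all(is.na(same$network_level$wilcoxon_p)))

  # a missing state is a named error
  expect_error(build_comparison_tables(
    netrep[!(netrep$network_id == "S2" & netrep$state == "pruned_all"), ],
    sprep, "original", "pruned_all"), "S2")

  dir <- withr::local_tempdir()
  write_comparison_tables(tabs, dir)
  expect_setequal(list.files(dir),
                  c("network_level_changes.csv", "species_level_changes.csv",
                    "per_network_significance.csv", "moran_summary.csv"))
})

test_that("the exact test holds its size under a symmetric null", {
  set.seed(1)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(k) {
    before <- rnorm(20)
    after <- before + rnorm(20)
    wilcoxon_one_tailed(before, after, "decrease")$p_value < 0.05
  }, TRUE)
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})
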