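test_that("labelled network construction enforces its invariants", {
  w <- matrix(c(1L, 0L, 2L, 3L), 2, 2,
              dimnames = list(c("P1", "P2"), c("B1", "B2")))
  net <- labeled_network(w, "seed_dispersal")
  expect_s3_class(net, "labeled_network")
  expect_identical(n_links(net), 3L)
  expect_identical(total_frequency(net), 6L)
  expect_true(all(is.na(net$outcomes[w == 0L])))

  expect_error(labeled_network(unname(w), "seed_dispersal"), "names")
  expect_error(labeled_network(w - 2L, "seed_dispersal"), "non-negative")
  expect_error(labeled_network(w, "eaten"), "outcome")
  w0 <- w; w0[] <- 0L
  expect_error(labeled_network(w0, "seed_dispersal"), "total")
})

test_that("edge lists read back what was written, summing duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("network_id,plant,bird,count,outcome,provenance",
               "N1,P1,B1,2,seed_dispersal,direct",
               "N1,P1,B2,1,pulp_pecking,inferred",
               "N1,P2,B1,3,seed_predation,direct"), path)
  nets <- read_edge_list(path)
  expect_named(nets, "N1")
  expect_identical(n_links(nets$N1), 3L)
  expect_identical(dim(nets$N1$weights), c(2L, 2L))

  # duplicate rows with one outcome are summed
  writeLines(c("network_id,plant,bird,count,outcome,provenance",
               "N1,P1,B1,2,seed_dispersal,direct",
               "N1,P1,B1,2,seed_dispersal,direct"), path)
  expect_identical(read_edge_list(path)$N1$weights["P1", "B1"], 4L)

  # conflicting labels for one pair stop with the pair named
  writeLines(c("network_id,plant,bird,count,outcome,provenance",
               "N1,P1,B1,2,seed_dispersal,direct",
               "N1,P1,B1,1,seed_predation,direct"), path)
  expect_error(read_edge_list(path), "P1 x B1")

  # non-integer counts are rejected
  writeLines(c("network_id,plant,bird,count,outcome,provenance",
               "N1,P1,B1,1.5,seed_dispersal,direct"), path)
  expect_error(read_edge_list(path), "integer")

  # round trip is a fixed point
  nets <- list(mixed_toy(), worked_2x2())
  names(nets) <- c("mixed", "net")
  write_edge_list(nets, path)
  back <- read_edge_list(path)
  expect_identical(back$mixed$weights, nets$mixed$weights)
  expect_identical(back$mixed$outcomes, nets$mixed$outcomes)
  write_edge_list(back, p2 <- withr::local_tempfile(fileext = ".csv"))
  expect_identical(readLines(path), readLines(p2))
})

test_that("adjacency TSV layers round trip", {
  net <- mixed_toy()
  cp <- withr::local_tempfile(fileext = ".tsv")
  op <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency(net, cp, op)
  back <- read_adjacency(cp, op, network_id = "mixed")
  expect_identical(back$weights, net$weights)
  expect_identical(back$outcomes, net$outcomes)
})

test_that("rate conversion multiplies, rounds to nearest and halves go up", {
  expect_identical(rate_to_counts(0.5, 10), 5L)
  expect_identical(rate_to_counts(0.33, 10), 3L)
  expect_identical(rate_to_counts(0.25, 10), 3L)  # half rounds up
  expect_identical(rate_to_counts(c(0, 1.24), c(5, 10)), c(0L, 12L))
  expect_error(rate_to_counts(-1, 10), "non-negative")
  expect_error(rate_to_counts(1, 0), "positive")
})

test_that("outcome inference follows congener-first precedence and majority", {
  traits <- data.frame(
    plant = c("Sorbus aria", "Sorbus aucuparia", "Prunus avium", "Rubus sp"),
    genus = c("Sorbus", "Sorbus", "Prunus", "Rubus"),
    fruit_type = c("pome", "pome", "drupe", "berry"),
    fruit_size_class = c(2L, 2L, 2L, 1L),
    seed_size_class = c(1L, 1L, 2L, 1L))
  known <- data.frame(
    bird = "greenfinch", plant = "Sorbus aucuparia",
    outcome = "seed_predation")
  # a congeneric record transfers its label
  inf <- infer_outcome("greenfinch", "Sorbus aria", known, traits)
  expect_identical(inf$outcome, "seed_predation")
  expect_identical(inf$provenance, "inferred")

  # no congener, no trait match: unclassified, not an error
  expect_identical(
    infer_outcome("greenfinch", "Prunus avium", known, traits)$outcome,
    "unclassified")

  # majority vote among congeneric records
  known3 <- data.frame(
    bird = "tit", plant = c("Sorbus aucuparia", "Sorbus aucuparia", "Sorbus aria"),
    outcome = c("pulp_pecking", "pulp_pecking", "seed_predation"))
  expect_identical(
    infer_outcome("tit", "Sorbus sp2", known3,
                  rbind(traits, data.frame(plant = "Sorbus sp2",
                                           genus = "Sorbus", fruit_type = "pome",
                                           fruit_size_class = 2L,
                                           seed_size_class = 1L)))$outcome,
    "pulp_pecking")

  # trait similarity fires when no congener is known
  known_tr <- data.frame(bird = "warbler", plant = "Rubus sp",
                         outcome = "seed_dispersal")
  traits2 <- rbind(traits, data.frame(plant = "Fragaria", genus = "Fragaria",
                                      fruit_type = "berry",
                                      fruit_size_class = 1L,
                                      seed_size_class = 1L))
  expect_identical(
    infer_outcome("warbler", "Fragaria", known_tr, traits2)$outcome,
    "seed_dispersal")

  expect_error(infer_outcome("greenfinch", "Sorbus aucuparia", known, traits),
               "direct record")
})

test_that("pruning removes the targeted outcomes and records dropped species", {
  w <- matrix(c(1L, 1L, 1L), 1, 3,
              dimnames = list("P1", c("B1", "B2", "B3")))
  o <- matrix(c("seed_dispersal", "pulp_pecking", "seed_predation"), 1, 3,
              dimnames = dimnames(w))
  net <- labeled_network(w, o)
  pr_all <- prune(net, "all_nonmutualistic")
  expect_identical(n_links(pr_all$pruned), 1L)
  expect_setequal(pr_all$dropped_birds, c("B2", "B3"))
  pr_pred <- prune(net, "predation_only")
  expect_identical(n_links(pr_pred$pruned), 2L)
  expect_identical(pr_pred$dropped_birds, "B3")

  # an all-dispersal network is untouched
  net_sd <- worked_2x2()
  pr <- prune(net_sd, "all_nonmutualistic")
  expect_identical(pr$pruned$weights, net_sd$weights)
  expect_length(pr$dropped_birds, 0L)
  expect_length(pr$dropped_plants, 0L)
})

test_that("pruning is idempotent, cellwise and nested across modes", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_plants = 6L, n_birds = 8L)
    net <- generate_network(cfg, seed = seed)
    for (mode in c("all_nonmutualistic", "predation_only")) {
      pr <- prune(net, mode)
      # idempotent
      expect_identical(prune(pr$pruned, mode)$pruned$weights,
                       pr$pruned$weights)
      # cellwise: 0 or the original weight, totals non-increasing
      w0 <- net$weights; w1 <- pr$pruned$weights
      expect_true(all(w1 == 0L | w1 == w0))
      expect_lte(sum(w1), sum(w0))
      expect_lte(sum(w1 > 0), sum(w0 > 0))
    }
    # predation-only removes a subset of the all-non-mutualistic removals
    gone_pred <- net$weights > 0 & prune(net, "predation_only")$pruned$weights == 0
    gone_all <- net$weights > 0 & prune(net, "all_nonmutualistic")$pruned$weights == 0
    expect_true(all(gone_all[gone_pred]))
  }
})

test_that("traits reader validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant,genus,fruit_type,fruit_size_class,seed_size_class",
               "Sorbus aria,Sorbus,pome,2,1"), path)
  tr <- read_traits(path)
  expect_identical(tr$genus, "Sorbus")
  writeLines(c("plant,genus", "x,y"), path)
  expect_error(read_traits(path), "columns")
})
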