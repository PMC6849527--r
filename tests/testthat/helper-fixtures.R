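# Fixtures are built in code: small labelled networks reused across tests.

net_from <- function(w, outcomes = "seed_dispersal", id = "toy") {
  if (is.null(rownames(w)))
    dimnames(w) <- list(sprintf("P%d", seq_len(nrow(w))),
                        sprintf("B%d", seq_len(ncol(w))))
  labeled_network(w, outcomes, network_id = id)
}

# worked coextinction example: bird totals 5 and 3, removal order B2 then B1
worked_2x2 <- function() {
  net_from(matrix(c(4L, 0L, 1L, 3L), 2, 2, byrow = TRUE))
}

# one link of each outcome plus one extra dispersal link
mixed_toy <- function() {
  w <- matrix(c(2L, 1L, 0L,
                3L, 0L, 1L), 2, 3, byrow = TRUE)
  o <- matrix(c("seed_dispersal", "pulp_pecking", NA,
                "seed_dispersal", NA, "seed_predation"), 2, 3, byrow = TRUE)
  dimnames(w) <- list(c("P1", "P2"), c("B1", "B2", "B3"))
  labeled_network(w, o, network_id = "mixed")
}

random_net <- function(seed, P = 5, A = 6, max_w = 6, fill = 0.6) {
  set.seed(seed)
  repeat {
    w <- matrix(ifelse(runif(P * A) < fill,
                       sample.int(max_w, P * A, replace = TRUE), 0L), P, A)
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) break
  }
  storage.mode(w) <- "integer"
  net_from(w, id = paste0("rnd", seed))
}
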