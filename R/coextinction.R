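## Topological coextinction model: birds are removed from least to most
## abundant (interaction frequency as the abundance proxy) and a plant is
## considered to have undergone dispersal failure once it has lost at least
## the threshold fraction (default 75%) of its interaction frequency.

#' Bird removal sequence
#'
#' Orders the birds of a network from least to most total interaction
#' frequency (a proxy for abundance, the species most vulnerable to
#' anthropogenic pressure being removed first). Ties are broken by species
#' id for determinism; optionally ties are shuffled under a seed so that
#' tie-sensitive results can be averaged over orders.
#'
#' @param net A [labeled_network].
#' @param randomize_ties Shuffle tied birds instead of id order.
#' @param seed Seed used when `randomize_ties = TRUE`.
#' @return Character vector of bird ids with positive totals, in removal
#'   order (empty if none).
#' @export
removal_sequence <- function(net, randomize_ties = FALSE, seed = NULL) {
  tot <- bird_totals(net)
  tot <- tot[tot > 0L]
  if (length(tot) == 0L) return(character(0L))
  if (randomize_ties) {
    if (!is.null(seed)) set.seed(seed)
    names(tot)[order(tot, sample.int(length(tot)))]
  } else {
    names(tot)[order(tot, names(tot))]
  }
}

#' Simulate the coextinction cascade
#'
#' Removes birds one at a time following [removal_sequence()] (or a caller
#' supplied order). After each removal, a surviving plant fails when the
#' fraction of its original interaction frequency lost is at least
#' `failure_threshold` (the comparison is inclusive: lost >= threshold);
#' failure is absorbing. The survival curve records, at every step
#' including step 0, the fraction of birds removed and the fraction of
#' plants still dispersing.
#'
#' @param net A [labeled_network]. Plants with zero original totals are
#'   excluded from the curve with a warning.
#' @param failure_threshold Fraction of frequency lost at which a plant
#'   fails; must lie in (0, 1]. Default 0.75.
#' @param removal_order Optional explicit bird order (defaults to least to
#'   most frequent).
#' @return Object of class `coextinction_result`: list with
#'   `removal_order`, `curve` (data frame `step`, `birds_removed_fraction`,
#'   `plants_surviving_fraction`), `failure_step` (named integer per plant),
#'   `n_birds`, `threshold`.
#' @examples
#' w <- matrix(c(4, 0, 1, 3), 2, 2, byrow = TRUE,
#'             dimnames = list(c("P1", "P2"), c("B1", "B2")))
#' res <- simulate_coextinction(labeled_network(w, "seed_dispersal"))
#' robustness(res)        # 0.5
#' resilience_75(res)     # P1 = 1.0, P2 = 0.5
#' @export
simulate_coextinction <- function(net, failure_threshold = 0.75,
                                  removal_order = NULL) {
  if (failure_threshold <= 0 || failure_threshold > 1)
    stop("failure_threshold must lie in (0, 1]")
  if (is.null(removal_order)) removal_order <- removal_sequence(net)
  orig <- plant_totals(net)
  if (any(orig == 0L)) {
    warning("excluding ", sum(orig == 0L),
            " plant(s) with zero total from the coextinction model")
    orig <- orig[orig > 0L]
  }
  if (length(orig) == 0L) stop("no plants with positive totals")
  n_birds <- length(removal_order)
  if (n_birds == 0L) stop("no birds with positive totals")

  w <- net$weights[names(orig), , drop = FALSE]
  remaining <- orig
  alive <- rep(TRUE, length(orig)); names(alive) <- names(orig)
  failure_step <- rep(NA_integer_, length(orig)); names(failure_step) <- names(orig)
  surv <- numeric(n_birds + 1L)
  surv[1L] <- mean(alive)
  for (k in seq_len(n_birds)) {
    remaining <- remaining - w[, removal_order[k]]
    fails <- alive & (orig - remaining) / orig >= failure_threshold
    failure_step[fails] <- k
    alive[fails] <- FALSE
    surv[k + 1L] <- mean(alive)
  }
  structure(list(removal_order = removal_order,
                 curve = data.frame(
                   step = 0:n_birds,
                   birds_removed_fraction = (0:n_birds) / n_birds,
                   plants_surviving_fraction = surv),
                 failure_step = failure_step,
                 n_birds = n_birds,
                 threshold = failure_threshold),
            class = "coextinction_result")
}

#' @export
print.coextinction_result <- function(x, ...) {
  cat(sprintf(
    "Coextinction cascade: %d birds removed, %d plants, threshold %.2f\n",
    x$n_birds, length(x$failure_step), x$threshold))
  cat(sprintf("  robustness (AUC) = %.4f\n", robustness(x)))
  invisible(x)
}

#' Robustness of a network to bird removal
#'
#' Trapezoidal area under the curve of the fraction of plants still
#' dispersing against the fraction of birds removed, between 0 and 1.
#' Higher values mean plants keep their dispersal service longer as birds
#' are lost.
#'
#' @param result A `coextinction_result` from [simulate_coextinction()].
#' @return Robustness in \[0, 1\].
#' @export
robustness <- function(result) {
  x <- result$curve$birds_removed_fraction
  y <- result$curve$plants_surviving_fraction
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Per-plant resilience to bird removal
#'
#' Proportion of the bird species that must be removed from the network
#' before a given plant undergoes dispersal failure: its failure step
#' divided by the number of birds.
#'
#' @param result A `coextinction_result`.
#' @param plant Plant id(s); default all plants in the result.
#' @return Named numeric vector of resilience values in (0, 1\].
#' @export
resilience_75 <- function(result, plant = NULL) {
  if (is.null(plant)) plant <- names(result$failure_step)
  miss <- setdiff(plant, names(result$failure_step))
  if (length(miss) > 0L)
    stop("plant(s) not in the coextinction result: ",
         paste(miss, collapse = ", "))
  result$failure_step[plant] / result$n_birds
}

#' @rdname simulate_coextinction
#' @param result A `coextinction_result`.
#' @param path Output CSV path; the survival curve rows are followed by a
#'   summary row carrying the robustness value.
#' @export
write_coextinction_curve <- function(result, path) {
  curve <- result$curve
  curve$robustness <- NA_real_
  summary_row <- data.frame(step = NA_integer_,
                            birds_removed_fraction = NA_real_,
                            plants_surviving_fraction = NA_real_,
                            robustness = robustness(result))
  utils::write.csv(rbind(curve, summary_row), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
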