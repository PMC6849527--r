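## Quantitative null models conditional on the observed marginals, and the
## delta-transformation (observed metric minus null mean) used to correct
## metric changes for changes in network size.

#' Patefield sample of an integer matrix with fixed marginals
#'
#' Draws one table from the uniform-token model behind the Patefield
#' algorithm: the `m` interaction tokens carry row labels with
#' multiplicities equal to the row totals and are paired with a random
#' permutation of `m` column-label tokens; cell counts are the pair
#' tabulation. Marginals are reproduced exactly; cell `(i, j)` has
#' expectation \eqn{r_i c_j / m}.
#'
#' @param row_totals,col_totals Non-negative integer marginals with equal
#'   sums.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return Integer matrix with the requested marginals.
#' @export
patefield_sample <- function(row_totals, col_totals, seed = NULL) {
  if (sum(row_totals) != sum(col_totals))
    stop("row and column totals must have equal sums")
  if (sum(row_totals) <= 0) stop("total must be positive")
  if (!is.null(seed)) set.seed(seed)
  nr <- length(row_totals); nc <- length(col_totals)
  rows <- rep(seq_len(nr), row_totals)
  cols <- sample(rep(seq_len(nc), col_totals))
  matrix(tabulate((cols - 1L) * nr + rows, nbins = nr * nc), nr, nc)
}

#' Fill-conserving quasiswap sample
#'
#' Draws one integer matrix with the same marginal totals *and* the same
#' number of nonzero cells (fill / connectance) as the observed matrix:
#' starting from a marginal-conserving table, 2x2 submatrix updates move the
#' fill to the observed value and further fill-preserving swaps mix the
#' table. Delegated to the `quasiswap_count` algorithm of
#' \pkg{vegan}, the implementation in standard use for this null model.
#'
#' @param mat Observed non-negative integer matrix.
#' @param seed Optional seed.
#' @return Integer matrix with the observed marginals and fill.
#' @export
quasiswap_count_sample <- function(mat, seed = NULL) {
  s <- null_ensemble_matrices(mat, model = "quasiswap_count", n_samples = 1L,
                              seed = seed)[[1L]]
  dimnames(s) <- dimnames(mat)
  s
}

null_ensemble_matrices <- function(mat, model, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (model == "patefield") {
    lapply(seq_len(n_samples),
           function(k) patefield_sample(rowSums(mat), colSums(mat)))
  } else {
    nm <- vegan::nullmodel(mat, "quasiswap_count")
    sims <- stats::simulate(nm, nsim = n_samples,
                            seed = sample.int(2^31 - 1L, 1L))
    lapply(seq_len(n_samples), function(k) {
      s <- matrix(as.integer(sims[, , k]), nrow(mat), ncol(mat))
      s
    })
  }
}

#' Generate a null ensemble for a network
#'
#' @param net A [labeled_network] (only its weights are used; species with
#'   zero totals are excluded first).
#' @param model `"patefield"` (conserves size and marginal totals) or
#'   `"quasiswap_count"` (additionally conserves connectance, i.e. the
#'   number of nonzero cells).
#' @param n_samples Ensemble size (default 1000).
#' @param seed Optional seed; identical seeds give identical ensembles.
#' @return Object of class `null_ensemble`: list with `model`, `n_samples`,
#'   `seed` and `samples` (list of integer matrices carrying the observed
#'   dimnames).
#' @export
null_ensemble <- function(net, model = c("patefield", "quasiswap_count"),
                          n_samples = 1000L, seed = NULL) {
  model <- match.arg(model)
  w <- active_matrix(net)
  samples <- null_ensemble_matrices(w, model, n_samples, seed)
  samples <- lapply(samples, function(s) {
    dimnames(s) <- dimnames(w)
    s
  })
  structure(list(model = model, n_samples = n_samples, seed = seed,
                 network_id = net$network_id, samples = samples),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %d %s samples of network '%s' (seed %s)\n",
              x$n_samples, x$model, x$network_id,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Delta-transform a metric against a null ensemble
#'
#' Subtracts the mean metric value across the null ensemble from the
#' observed value, describing how far the observed structure deviates from
#' the random expectation under the conserved quantities. Samples on which
#' the metric is undefined (`NA`) are skipped and counted; if more than 10%
#' are skipped a warning is attached.
#'
#' @param metric_fn Function of a [labeled_network] returning one number.
#'   May take a second argument, the sample index, which stochastic metrics
#'   (e.g. a modularity search) can fold into their own seed.
#' @param net The observed [labeled_network].
#' @param ensemble A [null_ensemble] of the same network.
#' @return Object of class `delta_metric`: list with `observed`,
#'   `null_mean`, `delta` (= observed - null_mean), `n_used`, `n_skipped`.
#' @examples
#' w <- matrix(c(4, 1, 1, 3), 2, 2, dimnames = list(c("P1","P2"), c("B1","B2")))
#' net <- labeled_network(w, "seed_dispersal")
#' ens <- null_ensemble(net, "patefield", n_samples = 50, seed = 1)
#' delta_transform(total_frequency, net, ens)$delta  # 0: m is conserved
#' @export
delta_transform <- function(metric_fn, net, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (length(ensemble$samples) == 0L) stop("ensemble is empty")
  two_arg <- length(formals(metric_fn)) >= 2L
  vals <- vapply(seq_along(ensemble$samples), function(k) {
    sample_net <- as_unlabeled_network(ensemble$samples[[k]])
    if (two_arg) metric_fn(sample_net, k) else metric_fn(sample_net)
  }, 0)
  used <- !is.na(vals)
  observed <- if (two_arg) metric_fn(net, 0L) else metric_fn(net)
  out <- structure(list(observed = observed,
                        null_mean = mean(vals[used]),
                        delta = observed - mean(vals[used]),
                        n_used = sum(used), n_skipped = sum(!used)),
                   class = "delta_metric")
  if (sum(!used) > 0.1 * length(vals))
    warning(sprintf("metric undefined on %d of %d null samples",
                    sum(!used), length(vals)))
  out
}

#' @export
print.delta_metric <- function(x, ...) {
  cat(sprintf(
    "delta = %.4g (observed %.4g - null mean %.4g over %d samples%s)\n",
    x$delta, x$observed, x$null_mean, x$n_used,
    if (x$n_skipped > 0) sprintf(", %d skipped", x$n_skipped) else ""))
  invisible(x)
}

#' Cache a null ensemble as plain-text matrices
#'
#' Long runs can be made resumable by writing each sample as a TSV named
#' `{network_id}.{model}.{index}.tsv` in a cache directory.
#'
#' @param ensemble A [null_ensemble].
#' @param dir Cache directory (created if needed).
#' @return `write_ensemble_cache()` returns the file paths invisibly;
#'   `read_ensemble_cache()` rebuilds the `null_ensemble` from the files.
#' @export
write_ensemble_cache <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(ensemble$samples), function(k) {
    p <- file.path(dir, sprintf("%s.%s.%d.tsv", ensemble$network_id,
                                ensemble$model, k))
    utils::write.table(ensemble$samples[[k]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    p
  }, "")
  invisible(paths)
}

#' @rdname write_ensemble_cache
#' @param network_id,model Identify the cached ensemble to read.
#' @export
read_ensemble_cache <- function(dir, network_id, model) {
  paths <- list.files(dir, sprintf("^%s\\.%s\\.[0-9]+\\.tsv$",
                                   network_id, model), full.names = TRUE)
  idx <- as.integer(sub(".*\\.([0-9]+)\\.tsv$", "\\1", paths))
  paths <- paths[order(idx)]
  if (length(paths) == 0L) stop("no cached samples found")
  samples <- lapply(paths, function(p) {
    s <- as.matrix(utils::read.delim(p, row.names = 1L, check.names = FALSE))
    storage.mode(s) <- "integer"
    s
  })
  structure(list(model = model, n_samples = length(samples), seed = NULL,
                 network_id = network_id, samples = samples),
            class = "null_ensemble")
}
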