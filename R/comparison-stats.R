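## Paired one-tailed tests on before/after metric vectors, the
## Bernoulli-process multiple-test probability, and assembly of the
## change/variation summary tables.

#' Hypothesized direction of change for every metric
#'
#' The direction each metric is expected to move when non-mutualistic
#' interactions are removed (and hence the direction of the one-tailed
#' tests): sizes, specialization, modularity, robustness and the plant
#' metrics decrease; connectance, nestedness and frugivore strength
#' increase.
#'
#' @format Named character vector (`"increase"` / `"decrease"`).
#' @export
METRIC_DIRECTIONS <- c(
  size = "decrease", weighted_connectance = "increase",
  weighted_nodf = "increase", h2_prime = "decrease",
  modularity_q = "decrease", robustness = "decrease",
  degree = "decrease", frequency = "decrease", d_prime = "decrease",
  resilience_75 = "decrease", strength = "increase")

#' One-tailed paired Wilcoxon signed-rank test
#'
#' Tests whether paired values consistently moved in the hypothesized
#' direction. Differences `after - before` equal to zero are dropped
#' (classic signed-rank convention); absolute differences are mid-ranked in
#' case of ties. For `n <= 25` the p-value is exact, from the full
#' distribution of the positive-rank sum over the \eqn{2^n} equiprobable
#' sign assignments (computed by convolution, identical to enumeration);
#' above that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param before,after Paired numeric vectors.
#' @param direction Hypothesized direction of `after` relative to `before`:
#'   `"decrease"` or `"increase"`.
#' @return List with `statistic` (positive-rank sum W+), `p_value`, `n_used`
#'   (pairs left after dropping zeros and NAs) and `method`. `p_value` is
#'   `NA` when fewer than 3 informative pairs remain.
#' @examples
#' wilcoxon_one_tailed(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 8), "decrease")$p_value
#' # 1/32: all five pairs decreased
#' @export
wilcoxon_one_tailed <- function(before, after,
                                direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(length(before) == length(after))
  d <- (after - before)[!is.na(after) & !is.na(before)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 3L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = n,
                method = "insufficient informative pairs"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))        # doubled midranks are integers
    total <- sum(r2)
    dist <- c(1, numeric(total))          # counts over 0..total
    for (rk in r2) dist <- dist + c(numeric(rk), dist[seq_len(total + 1L - rk)])
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p <- if (direction == "increase") sum(dist[(w2 + 1L):(total + 1L)])
         else sum(dist[1L:(w2 + 1L)])
    method <- "exact sign-assignment distribution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- if (direction == "increase") (w - mu - 0.5) / sigma
         else (w - mu + 0.5) / sigma
    p <- if (direction == "increase") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal approximation with continuity correction"
  }
  list(statistic = w, p_value = p, n_used = n, method = method)
}

#' One-tailed Spearman rank correlation
#'
#' Rank correlation on mid-ranks with a one-tailed p-value. For `n <= 8`
#' the p-value is exact, by full enumeration of the `n!` permutations;
#' above that a t approximation on `n - 2` degrees of freedom is used.
#' Testing the positive alternative encodes the null hypothesis of
#' unchanged ranks: a *non-significant* p under `direction = "positive"`
#' flags a change in the ranking.
#'
#' @param x,y Paired numeric vectors.
#' @param direction `"positive"` or `"negative"` alternative.
#' @return List with `rho`, `p_value`, `n`, `method`; `rho` is `NA` when
#'   either vector is constant.
#' @export
spearman_one_tailed <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant vector or n < 3)"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    mx <- mean(rx); sx <- stats::sd(rx)
    my <- mean(ry); sy <- stats::sd(ry)
    cross <- matrix(ry[perms], nrow(perms)) %*% rx
    rhos <- (cross - n * mx * my) / ((n - 1) * sx * sy)
    p <- if (direction == "positive") mean(rhos >= rho - 1e-12)
         else mean(rhos <= rho + 1e-12)
    method <- "exact permutation distribution"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- if (direction == "positive") stats::pt(tstat, n - 2, lower.tail = FALSE)
         else stats::pt(tstat, n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

## all permutations of 1..n as an (n! x n) matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Bernoulli-process probability of K significant tests among N
#'
#' Exact point probability, under a Bernoulli process with per-test
#' significance level `alpha`, of obtaining exactly `K` significant results
#' in `N` independent tests:
#' \deqn{p = \frac{N!}{(N-K)!\,K!}\,\alpha^K (1-\alpha)^{N-K}.}
#' Used to judge whether a batch of significant one-tailed tests could be a
#' multiple-testing artefact.
#'
#' @param N Number of tests conducted.
#' @param K Number of tests below the significance level.
#' @param alpha Per-test significance level, in (0, 1).
#' @return The probability.
#' @examples
#' moran_probability(6, 4, 0.05)  # 8.46e-05
#' @export
moran_probability <- function(N, K, alpha) {
  if (N != round(N) || K != round(K) || K < 0 || K > N)
    stop("need integers 0 <= K <= N")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  exp(lchoose(N, K) + K * log(alpha) + (N - K) * log1p(-alpha))
}

## paired summary for one metric: changes, mean %, CV%, one-tailed tests
summarize_pair <- function(before, after, direction) {
  keep <- !is.na(before) & !is.na(after)
  ch <- (after - before)[keep]
  pct <- 100 * ch[before[keep] != 0] / before[keep][before[keep] != 0]
  wt <- wilcoxon_one_tailed(before[keep], after[keep], direction)
  sp <- spearman_one_tailed(before[keep], after[keep], "positive")
  data.frame(
    direction = direction,
    n_pairs = sum(keep),
    mean_change_absolute = mean(ch),
    mean_change_percent = if (length(pct)) mean(pct) else NA_real_,
    range_low = if (length(ch)) min(ch) else NA_real_,
    range_high = if (length(ch)) max(ch) else NA_real_,
    cv_percent = if (length(ch) > 1L && mean(ch) != 0)
      100 * stats::sd(ch) / abs(mean(ch)) else NA_real_,
    wilcoxon_p = wt$p_value,
    spearman_rho = sp$rho,
    spearman_p = sp$p_value,
    stringsAsFactors = FALSE)
}

#' Assemble before/after comparison tables
#'
#' Pairs the metric reports of two network states and produces (1) a
#' network-level change table (mean absolute and percentage change, range,
#' coefficient of variation, one-tailed Wilcoxon and Spearman tests per
#' metric), (2) a species-level change table where per-network mean changes
#' are averaged into an overall mean (the CV is computed across all species
#' pooled), (3) a per-network significance grid of the species-level
#' Wilcoxon tests, and (4) a Bernoulli-process multiple-test summary per
#' table. Test directions follow [METRIC_DIRECTIONS].
#'
#' @param network_reports Data frame from [network_metrics()] rows (plus
#'   optional `robustness` rows), covering at least 2 networks in both
#'   states.
#' @param species_reports Data frame from [species_metrics()] rows
#'   (optionally with a `resilience_75` column), covering both states.
#' @param before_state,after_state State labels to compare.
#' @param alpha Significance level used for the Moran summary counts.
#' @return Object of class `comparison_tables`: list with `network_level`,
#'   `species_level`, `per_network`, `moran`, `alpha`, `states`.
#' @export
build_comparison_tables <- function(network_reports, species_reports,
                                    before_state = "original",
                                    after_state = "pruned_all",
                                    alpha = 0.05) {
  states <- c(before_state, after_state)
  nr <- network_reports[network_reports$state %in% states, , drop = FALSE]
  for (id in unique(nr$network_id)) {
    have <- unique(nr$state[nr$network_id == id])
    if (!all(states %in% have))
      stop("network ", id, " is missing state ",
           paste(setdiff(states, have), collapse = ", "))
  }

  ## network level: one row per metric, networks are the pairing unit
  net_tab <- do.call(rbind, lapply(unique(nr$metric), function(met) {
    wide <- lapply(states, function(s) {
      sub <- nr[nr$metric == met & nr$state == s, ]
      stats::setNames(sub$value, sub$network_id)
    })
    ids <- intersect(names(wide[[1L]]), names(wide[[2L]]))
    out <- summarize_pair(wide[[1L]][ids], wide[[2L]][ids],
                          METRIC_DIRECTIONS[[met]])
    cbind(data.frame(metric = met, stringsAsFactors = FALSE), out)
  }))

  ## species level: per-network mean change, then mean of means
  sp <- species_reports[species_reports$state %in% states, , drop = FALSE]
  sp_metrics <- intersect(c("degree", "frequency", "d_prime",
                            "resilience_75", "strength"), names(sp))
  guild_of <- c(degree = "plant", frequency = "plant", d_prime = "plant",
                resilience_75 = "plant", strength = "bird")
  pair_species <- function(d, met) {
    b <- d[d$state == before_state, c("species", met)]
    a <- d[d$state == after_state, c("species", met)]
    ids <- intersect(b$species, a$species)
    list(before = stats::setNames(b[[met]], b$species)[ids],
         after = stats::setNames(a[[met]], a$species)[ids])
  }
  species_tab <- do.call(rbind, lapply(sp_metrics, function(met) {
    d <- sp[sp$guild == guild_of[[met]], , drop = FALSE]
    per_net <- lapply(split(d, d$network_id), function(dd) pair_species(dd, met))
    mean_changes <- vapply(per_net, function(p) {
      keep <- !is.na(p$before) & !is.na(p$after)
      if (!any(keep)) NA_real_ else mean((p$after - p$before)[keep])
    }, 0)
    mean_pcts <- vapply(per_net, function(p) {
      keep <- !is.na(p$before) & !is.na(p$after) & p$before != 0
      if (!any(keep)) NA_real_
      else mean(100 * (p$after - p$before)[keep] / p$before[keep])
    }, 0)
    pooled <- pair_species(d, met)
    keep <- !is.na(pooled$before) & !is.na(pooled$after)
    pooled_change <- (pooled$after - pooled$before)[keep]
    wt <- wilcoxon_one_tailed(pooled$before[keep], pooled$after[keep],
                              METRIC_DIRECTIONS[[met]])
    sp_t <- spearman_one_tailed(pooled$before[keep], pooled$after[keep],
                                "positive")
    data.frame(
      metric = met, guild = guild_of[[met]],
      direction = METRIC_DIRECTIONS[[met]],
      n_species = sum(keep),
      mean_change_absolute = mean(mean_changes, na.rm = TRUE),
      mean_change_percent = mean(mean_pcts, na.rm = TRUE),
      range_networks_low = min(mean_changes, na.rm = TRUE),
      range_networks_high = max(mean_changes, na.rm = TRUE),
      range_species_low = min(pooled_change),
      range_species_high = max(pooled_change),
      cv_percent = if (mean(pooled_change) != 0)
        100 * stats::sd(pooled_change) / abs(mean(pooled_change))
        else NA_real_,
      wilcoxon_p = wt$p_value,
      spearman_rho = sp_t$rho,
      spearman_p = sp_t$p_value,
      stringsAsFactors = FALSE)
  }))

  ## per-network species-level Wilcoxon grid
  per_net_tab <- do.call(rbind, lapply(sp_metrics, function(met) {
    d <- sp[sp$guild == guild_of[[met]], , drop = FALSE]
    do.call(rbind, lapply(split(d, d$network_id), function(dd) {
      p <- pair_species(dd, met)
      keep <- !is.na(p$before) & !is.na(p$after)
      wt <- wilcoxon_one_tailed(p$before[keep], p$after[keep],
                                METRIC_DIRECTIONS[[met]])
      data.frame(network_id = dd$network_id[1L], metric = met,
                 direction = METRIC_DIRECTIONS[[met]],
                 n_species = sum(keep), wilcoxon_p = wt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_net_tab) <- NULL

  moran <- do.call(rbind, lapply(
    list(network_level = net_tab, species_level = species_tab),
    function(tab) {
      p <- tab$wilcoxon_p[!is.na(tab$wilcoxon_p)]
      data.frame(N = length(p), K = sum(p < alpha), alpha = alpha,
                 moran_p = if (length(p))
                   moran_probability(length(p), sum(p < alpha), alpha)
                 else NA_real_)
    }))
  moran <- cbind(data.frame(level = rownames(moran),
                            stringsAsFactors = FALSE), moran)
  rownames(moran) <- NULL

  structure(list(network_level = net_tab, species_level = species_tab,
                 per_network = per_net_tab, moran = moran, alpha = alpha,
                 states = states),
            class = "comparison_tables")
}

#' @export
print.comparison_tables <- function(x, ...) {
  cat("Comparison of states", x$states[1L], "->", x$states[2L], "\n\n")
  cat("Network-level changes:\n")
  print(x$network_level, digits = 3, row.names = FALSE)
  cat("\nSpecies-level changes (mean of per-network means):\n")
  print(x$species_level, digits = 3, row.names = FALSE)
  cat("\nMultiple-test summary (Bernoulli process):\n")
  print(x$moran, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname build_comparison_tables
#' @param tables A `comparison_tables` object.
#' @param dir Output directory (created if needed).
#' @export
write_comparison_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$network_level,
                   file.path(dir, "network_level_changes.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$species_level,
                   file.path(dir, "species_level_changes.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$per_network,
                   file.path(dir, "per_network_significance.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$moran, file.path(dir, "moran_summary.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
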