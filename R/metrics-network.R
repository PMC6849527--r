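## Network-level structure metrics for quantitative bipartite networks.
## All metrics operate on the "active" matrix: species whose marginal total
## is zero (species dropped by pruning) are excluded, except from the size
## bookkeeping where they are simply not counted.

active_matrix <- function(net) {
  w <- net$weights
  w[rowSums(w) > 0L, colSums(w) > 0L, drop = FALSE]
}

shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Network size
#'
#' Total number of species in the network: plants with a positive
#' interaction total plus birds with a positive total. Species that lost all
#' their links during pruning do not count towards size.
#'
#' @param net A [labeled_network].
#' @return Integer species count.
#' @export
network_size <- function(net) {
  sum(rowSums(net$weights) > 0L) + sum(colSums(net$weights) > 0L)
}

#' Weighted connectance
#'
#' Quantitative linkage density divided by network size. Linkage density is
#' the marginal-weighted mean effective number of partners,
#' \deqn{LD = \frac{1}{2m}\Big(\sum_j A_j n_j + \sum_i A_i n_i\Big),}
#' where \eqn{n_k = \exp(H_k)} is the exponential of the Shannon entropy
#' (natural log) of species \eqn{k}'s interaction vector and \eqn{m} the
#' grand total. For a uniformly filled matrix of any shape the result is 0.5.
#'
#' @param net A [labeled_network].
#' @return Weighted connectance, or `NA` if the network has no interactions.
#' @export
weighted_connectance <- function(net) {
  w <- active_matrix(net)
  m <- sum(w)
  if (m == 0) return(NA_real_)
  n_row <- apply(w, 1L, function(x) exp(shannon(x)))
  n_col <- apply(w, 2L, function(x) exp(shannon(x)))
  ld <- (sum(colSums(w) * n_col) + sum(rowSums(w) * n_row)) / (2 * m)
  ld / (nrow(w) + ncol(w))
}

#' Weighted nestedness (WNODF)
#'
#' Weighted nestedness based on overlap and decreasing fill, in \[0, 100\].
#' Rows and columns are ranked by decreasing marginal total; for each pair
#' with strictly decreasing totals (richer `u`, poorer `v`) the paired score
#' is \eqn{100\,|\{j: 0 < w_{vj} < w_{uj}\}| / |\{j: w_{vj} > 0\}|}, and
#' pairs with equal marginal totals score 0. WNODF is the mean over all row
#' pairs and column pairs. This implementation ranks by marginal totals
#' throughout (the tested convention; implementations ranking by binary fill
#' differ on matrices where fill and total orderings disagree).
#'
#' @param net A [labeled_network].
#' @return WNODF in \[0, 100\], or `NA` for degenerate shapes (fewer than
#'   two active rows or columns).
#' @export
weighted_nodf <- function(net) {
  w <- active_matrix(net)
  if (nrow(w) < 2L || ncol(w) < 2L) return(NA_real_)
  pair_scores <- function(mat) {  # rows of mat are compared
    tot <- rowSums(mat)
    n <- nrow(mat)
    s <- numeric(0L)
    for (u in seq_len(n - 1L)) for (v in (u + 1L):n) {
      ri <- if (tot[u] >= tot[v]) u else v; pi <- u + v - ri
      if (tot[ri] == tot[pi]) { s <- c(s, 0); next }
      rich <- mat[ri, ]; poor <- mat[pi, ]
      s <- c(s, 100 * sum(poor > 0 & poor < rich) / sum(poor > 0))
    }
    s
  }
  mean(c(pair_scores(w), pair_scores(t(w))))
}

#' Network-level specialization H2'
#'
#' Standardized two-dimensional Shannon entropy of the interaction matrix,
#' ranging from 0 (partners used in proportion to availability, no
#' specialization) to 1 (complete specialization). With \eqn{p_{ij} =
#' a_{ij}/m}, \eqn{H_2 = -\sum p_{ij}\ln p_{ij}} and
#' \deqn{H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min}).}
#' \eqn{H_{2max}} is the entropy of the continuous marginal product
#' distribution \eqn{p_i q_j} (the maximum given marginals); \eqn{H_{2min}}
#' comes from a greedy integer packing that repeatedly allocates
#' \eqn{\min(r_i, c_j)} to the cell of the currently largest row and column
#' remainders, concentrating each total on as few cells as the marginals
#' allow. The ratio is clamped to \[0, 1\]; because \eqn{H_{2max}} is
#' continuous and the packing greedy, unclamped values can fall slightly
#' outside on small integer matrices.
#'
#' @param net A [labeled_network].
#' @return H2' in \[0, 1\], or `NA` if the network has no interactions.
#' @export
h2_prime <- function(net) {
  w <- active_matrix(net)
  m <- sum(w)
  if (m == 0) return(NA_real_)
  h2 <- shannon(w)
  h2max <- shannon(rowSums(w)) + shannon(colSums(w))
  h2min <- h2_min_greedy(rowSums(w), colSums(w))
  if (h2max - h2min < 1e-12) return(0)
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

## minimum-entropy packing given integer marginals: greedy allocation
## (exact fits first, then largest-remainder pairs) polished by 2x2 pivot
## moves; the entropy is concave over the transportation polytope, so the
## minimum sits at a vertex and endpoint moves walk between vertices
h2_min_greedy <- function(r, c) {
  m <- sum(r)
  x <- matrix(0, length(r), length(c))
  rr <- r; cc <- c
  while (any(rr > 0)) {
    fit <- which(outer(rr, cc, "==") & rr > 0, arr.ind = TRUE)
    if (nrow(fit) > 0L) { i <- fit[1L, 1L]; j <- fit[1L, 2L] }
    else { i <- which.max(rr); j <- which.max(cc) }
    amt <- min(rr[i], cc[j])
    x[i, j] <- x[i, j] + amt
    rr[i] <- rr[i] - amt; cc[j] <- cc[j] - amt
  }
  ent <- function(x) { p <- x[x > 0] / m; -sum(p * log(p)) }
  best <- ent(x)
  if (length(r) > 1L && length(c) > 1L) repeat {
    improved <- FALSE
    rows <- which(rowSums(x) > 0); cols <- which(colSums(x) > 0)
    for (i in rows) for (i2 in rows) for (j in cols) for (j2 in cols) {
      if (i >= i2 || j == j2) next
      # shift t along the cycle (i,j)+t, (i,j2)-t, (i2,j2)+t, (i2,j)-t
      for (t in c(min(x[i, j2], x[i2, j]), -min(x[i, j], x[i2, j2]))) {
        if (t == 0) next
        y <- x
        y[i, j] <- y[i, j] + t; y[i2, j2] <- y[i2, j2] + t
        y[i, j2] <- y[i, j2] - t; y[i2, j] <- y[i2, j] - t
        e <- ent(y)
        if (e < best - 1e-12) { x <- y; best <- e; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  best
}

#' Barber bipartite modularity
#'
#' Evaluates the weighted Barber modularity of a given module partition:
#' \deqn{Q = \frac{1}{m} \sum_{ij} \Big(a_{ij} - \frac{A_i A_j}{m}\Big)
#'   \,\delta(g_i, h_j),}
#' the within-module excess of interaction weight over the marginal-product
#' expectation.
#'
#' @param net A [labeled_network].
#' @param partition Named vector mapping every species with at least one
#'   link (plants and birds) to a module label.
#' @return Modularity Q (at most 1; 0 for the all-in-one-module partition).
#' @seealso [lpawb_plus()] to search for the best partition.
#' @export
barber_q <- function(net, partition) {
  w <- active_matrix(net)
  species <- c(rownames(w), colnames(w))
  miss <- setdiff(species, names(partition))
  if (length(miss) > 0L)
    stop("partition does not cover species: ", paste(miss, collapse = ", "))
  m <- sum(w)
  b <- w - outer(rowSums(w), colSums(w)) / m
  same <- outer(partition[rownames(w)], partition[colnames(w)], "==")
  sum(b[same]) / m
}

#' Weighted modularity search (LPAwb+)
#'
#' Two-phase stochastic search maximizing weighted Barber modularity:
#' (1) label propagation — every plant starts in its own module and plants
#' and birds are alternately reassigned, guild-wise, to the module that
#' maximizes Q (a species opens a fresh singleton module when every existing
#' module would lower Q); (2) agglomeration — module pairs are merged while
#' any merge increases Q, after which propagation resumes. The search stops
#' when a full phase improves Q by less than `tol` or after `max_sweeps`
#' sweeps. With `repeats > 1` the search restarts from random initial
#' partitions and the best Q wins; given `seed` the result is deterministic.
#'
#' @param net A [labeled_network].
#' @param seed Optional integer seed for the stochastic restarts.
#' @param repeats Number of restarts (default 1, mirroring a single run of
#'   the algorithm; increase to probe the stochastic spread).
#' @param tol Minimum Q gain treated as an improvement.
#' @param max_sweeps Cap on propagation sweeps per restart.
#' @return List with `partition` (named module labels for all species with
#'   links), `q`, `repeats` and `seed`.
#' @export
lpawb_plus <- function(net, seed = NULL, repeats = 1L, tol = 1e-10,
                       max_sweeps = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  w <- active_matrix(net)
  m <- sum(w)
  if (m == 0) stop("network has no interactions")
  b <- w - outer(rowSums(w), colSums(w)) / m
  nr <- nrow(b); nc <- ncol(b)

  qval <- function(rl, cl) sum(b[outer(rl, cl, "==")]) / m

  ## guild-wise block reassignment of column labels given row labels;
  ## returns labels drawn from rl, or fresh singletons where no module helps
  assign_side <- function(bmat, from_labels, fresh_prefix) {
    s <- rowsum(bmat, from_labels)            # module x species-to-assign
    arg <- apply(s, 2L, which.max)
    best <- s[cbind(arg, seq_len(ncol(s)))]
    lab <- rownames(s)[arg]
    fresh <- best <= 0
    lab[fresh] <- paste0(fresh_prefix, seq_len(ncol(s)))[fresh]
    lab
  }

  one_run <- function(rl) {
    cl <- assign_side(b, rl, "f.")
    q <- qval(rl, cl)
    sweeps <- 0L
    repeat {
      repeat {   # alternate block maximization; Q is non-decreasing
        rl2 <- assign_side(t(b), cl, "g.")
        cl2 <- assign_side(b, rl2, "f.")
        q2 <- qval(rl2, cl2)
        sweeps <- sweeps + 1L
        if (q2 > q + tol && sweeps < max_sweeps) { rl <- rl2; cl <- cl2; q <- q2 }
        else break
      }
      ## agglomeration: cross-module gains W[a,b] + W[b,a]
      merged <- FALSE
      repeat {
        labs <- unique(c(rl, cl))
        if (length(labs) < 2L) break
        g <- matrix(0, length(labs), length(labs),
                    dimnames = list(labs, labs))
        e <- rowsum(b, rl)                       # row-labels present x col
        cross <- t(rowsum(t(e), cl))             # row-labels x col-labels
        g[rownames(cross), colnames(cross)] <- cross
        gain <- g + t(g)
        diag(gain) <- -Inf
        k <- arrayInd(which.max(gain), dim(gain))
        if (gain[k] / m <= tol) break
        a <- labs[k[1L]]; z <- labs[k[2L]]
        rl[rl == z] <- a; cl[cl == z] <- a
        q <- q + gain[k] / m
        merged <- TRUE
      }
      if (!merged || sweeps >= max_sweeps) break
      ## after merging, propagation may improve further
      q_before <- q
      rl2 <- assign_side(t(b), cl, "g.")
      cl2 <- assign_side(b, rl2, "f.")
      if (qval(rl2, cl2) <= q_before + tol) break
    }
    list(rl = rl, cl = cl, q = q)
  }

  best <- NULL
  for (rep in seq_len(repeats)) {
    rl0 <- if (rep == 1L) paste0("m", seq_len(nr))
           else paste0("m", sample.int(nr, nr, replace = TRUE))
    fit <- one_run(rl0)
    if (is.null(best) || fit$q > best$q) best <- fit
  }
  partition <- c(stats::setNames(best$rl, rownames(w)),
                 stats::setNames(best$cl, colnames(w)))
  ## relabel modules 1..k in order of appearance
  partition <- stats::setNames(
    as.character(match(partition, unique(partition))), names(partition))
  list(partition = partition, q = best$q, repeats = repeats, seed = seed)
}

#' Tidy network-level metric report
#'
#' Computes all network-level metrics for one network state and returns them
#' in the tidy long format `network_id,state,metric,value,seed`.
#'
#' @param net A [labeled_network].
#' @param state Label of the network state (e.g. `"original"`,
#'   `"pruned_all"`, `"pruned_predation"`).
#' @param seed Seed passed to the modularity search and recorded in the
#'   report.
#' @param lpa_repeats Restarts for [lpawb_plus()].
#' @return Data frame with one row per metric (`size`,
#'   `weighted_connectance`, `weighted_nodf`, `h2_prime`, `modularity_q`).
#' @export
network_metrics <- function(net, state = "original", seed = 1L,
                            lpa_repeats = 1L) {
  mod <- lpawb_plus(net, seed = seed, repeats = lpa_repeats)
  data.frame(
    network_id = net$network_id,
    state = state,
    metric = c("size", "weighted_connectance", "weighted_nodf", "h2_prime",
               "modularity_q"),
    value = c(network_size(net), weighted_connectance(net),
              weighted_nodf(net), h2_prime(net), mod$q),
    seed = seed,
    stringsAsFactors = FALSE)
}

#' @rdname network_metrics
#' @param report Data frame produced by `network_metrics()` (rows may be
#'   concatenated across networks and states).
#' @param path Output CSV path.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
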