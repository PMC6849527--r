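## Species-level metrics. Degree and interaction frequency keep their zeros
## for species that lost all links (excluding them would underestimate mean
## changes); d' and species strength are undefined (NA) for such species.

species_vector <- function(net, species) {
  w <- net$weights
  if (species %in% rownames(w)) list(x = w[species, ], guild = "plant")
  else if (species %in% colnames(w)) list(x = w[, species], guild = "bird")
  else stop("unknown species: ", species)
}

#' Species degree
#'
#' Number of partner species a given species interacts with (count of
#' nonzero cells in its row or column). Zero is a legitimate value after
#' pruning.
#'
#' @param net A [labeled_network].
#' @param species Species id (plant or bird).
#' @return Integer degree.
#' @export
species_degree <- function(net, species) {
  sum(species_vector(net, species)$x > 0L)
}

#' Species interaction frequency
#'
#' Marginal total of a species: the summed visit counts of all its links.
#'
#' @inheritParams species_degree
#' @return Integer total frequency.
#' @export
interaction_frequency <- function(net, species) {
  sum(species_vector(net, species)$x)
}

#' Species-level specialization d'
#'
#' Kullback-Leibler deviation of a species' partner use from partner
#' availability, standardized to \[0, 1\]. With \eqn{p'_j = a_{ij}/A_i} and
#' availability \eqn{q_j = A_j/m} (marginals of the current network state),
#' \eqn{d = \sum_j p'_j \ln(p'_j/q_j)}; then
#' \eqn{d' = (d - d_{min})/(d_{max} - d_{min})}, clamped to \[0, 1\].
#' The extrema honour the integer nature of counts: \eqn{d_{max}} puts the
#' whole total on the rarest partner; \eqn{d_{min}} is found by
#' largest-remainder apportionment proportional to availability followed by
#' single-unit descent (exact, because the objective is separable convex
#' over the integer simplex). A species with a single available partner has
#' no freedom and gets d' = 0; a species with zero total gets `NA`.
#'
#' @inheritParams species_degree
#' @return d' in \[0, 1\], or `NA` for a species with no links.
#' @export
d_prime <- function(net, species) {
  sv <- species_vector(net, species)
  a <- sv$x
  tot <- sum(a)
  if (tot == 0L) return(NA_real_)
  w <- active_matrix(net)
  q <- if (sv$guild == "plant") colSums(w) / sum(w) else rowSums(w) / sum(w)
  a <- a[names(q)]                      # availability over active partners
  d_obs <- kl_div(a / tot, q)
  if (length(q) < 2L) return(0)
  d_max <- -log(min(q))
  d_min <- kl_div(apportion_min_kl(tot, q) / tot, q)
  if (d_max - d_min < 1e-12) return(0)
  min(1, max(0, (d_obs - d_min) / (d_max - d_min)))
}

kl_div <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

## integer allocation of `tot` units over cells minimizing KL divergence to q:
## largest-remainder start, then steepest single-unit moves (global optimum
## for a separable convex objective on the integer simplex)
apportion_min_kl <- function(tot, q) {
  n <- length(q)
  x <- floor(tot * q)
  rem <- tot - sum(x)
  if (rem > 0) {
    extra <- order(tot * q - x, decreasing = TRUE)[seq_len(rem)]
    x[extra] <- x[extra] + 1
  }
  f <- function(x) kl_div(x / tot, q)
  repeat {
    cur <- f(x)
    best <- cur; bu <- bv <- 0L
    for (u in which(x > 0)) for (v in seq_len(n)) {
      if (u == v) next
      y <- x; y[u] <- y[u] - 1; y[v] <- y[v] + 1
      fy <- f(y)
      if (fy < best - 1e-12) { best <- fy; bu <- u; bv <- v }
    }
    if (bu == 0L) break
    x[bu] <- x[bu] - 1; x[bv] <- x[bv] + 1
  }
  x
}

#' Frugivore species strength
#'
#' Sum over plant species of the fraction of each plant's interactions the
#' bird accounts for: \eqn{\sum_i a_{ij}/A_i}. Across all birds the strengths
#' add up to the number of plant species with links, since every plant's
#' dependencies sum to one.
#'
#' @param net A [labeled_network].
#' @param bird Bird species id.
#' @return Strength, or `NA` for a bird with no links.
#' @export
species_strength <- function(net, bird) {
  w <- net$weights
  if (!bird %in% colnames(w)) stop("unknown species: ", bird)
  if (sum(w[, bird]) == 0L) return(NA_real_)
  a_i <- rowSums(w)
  keep <- a_i > 0L
  sum(w[keep, bird] / a_i[keep])
}

#' Species-level metric report
#'
#' Computes degree, interaction frequency, d' and (for birds) species
#' strength for every species of a network state. Species with no links in
#' the state keep degree 0 and frequency 0 but get `NA` for d' and strength.
#'
#' @param net A [labeled_network].
#' @param state State label recorded in the report.
#' @return Data frame with columns
#'   `network_id,state,guild,species,degree,frequency,d_prime,strength`.
#' @export
species_metrics <- function(net, state = "original") {
  plants <- rownames(net$weights); birds <- colnames(net$weights)
  df <- data.frame(
    network_id = net$network_id, state = state,
    guild = c(rep("plant", length(plants)), rep("bird", length(birds))),
    species = c(plants, birds), stringsAsFactors = FALSE)
  df$degree <- vapply(df$species, function(s) species_degree(net, s), 0L)
  df$frequency <- vapply(df$species, function(s) interaction_frequency(net, s), 0L)
  df$d_prime <- vapply(df$species, function(s) d_prime(net, s), 0)
  df$strength <- NA_real_
  df$strength[df$guild == "bird"] <-
    vapply(birds, function(s) species_strength(net, s), 0)
  rownames(df) <- NULL
  df
}

#' @rdname species_metrics
#' @param report Data frame from `species_metrics()` (possibly row-bound
#'   across networks and states).
#' @param path Output CSV path; missing values are written as empty fields.
#' @export
write_species_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
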