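# Independent brute-force oracles. These deliberately share no code with the
# package implementation: direct loops, exhaustive enumeration and closed
# forms only.

# all non-negative integer vectors of length k summing to s
compositions_of <- function(s, k) {
  if (k == 1L) return(matrix(s, 1))
  out <- NULL
  for (first in 0:s) {
    rest <- compositions_of(s - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# all integer matrices with the given row and column totals
tables_with_margins <- function(r, c) {
  out <- list()
  recurse <- function(rows_done, cols_left) {
    if (rows_done == length(r)) {
      if (all(cols_left == 0)) out[[length(out) + 1L]] <<- mat
      return(invisible())
    }
    rowcands <- compositions_of(r[rows_done + 1L], length(c))
    for (i in seq_len(nrow(rowcands))) {
      row <- rowcands[i, ]
      if (all(row <= cols_left)) {
        mat[rows_done + 1L, ] <<- row
        recurse(rows_done + 1L, cols_left - row)
      }
    }
  }
  mat <- matrix(0L, length(r), length(c))
  recurse(0L, c)
  out
}

entropy_of <- function(m) {
  p <- m[m > 0] / sum(m)
  -sum(p * log(p))
}

# exhaustive minimum two-dimensional entropy over tables with given margins
oracle_h2min <- function(r, c) {
  min(vapply(tables_with_margins(r, c), entropy_of, 0))
}

# exhaustive d extrema over all integer allocations of `tot` across cells
oracle_d_extrema <- function(tot, q) {
  xs <- compositions_of(tot, length(q))
  d <- apply(xs, 1, function(x) {
    p <- x[x > 0] / tot
    sum(p * log(p / q[x > 0]))
  })
  c(min = min(d), max = max(d))
}

# Barber modularity evaluated cell by cell, independent of the package code
oracle_q <- function(w, row_labels, col_labels) {
  m <- sum(w)
  q <- 0
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w)))
    if (row_labels[i] == col_labels[j])
      q <- q + w[i, j] - sum(w[i, ]) * sum(w[, j]) / m
  q / m
}

# all set partitions of n items as label vectors (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (lab in seq_len(next_label))
      recurse(c(labels, lab), max(next_label, lab + 1L))
  }
  recurse(integer(0), 1L)
  out
}

# exhaustive maximum Barber modularity over all partitions of the species
oracle_max_q <- function(w) {
  n <- nrow(w) + ncol(w)
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- oracle_q(w, p[seq_len(nrow(w))], p[nrow(w) + seq_len(ncol(w))])
    if (q > best) best <- q
  }
  best
}

# weighted NODF from its definition: explicit pair loops on the raw matrix
oracle_wnodf <- function(w) {
  score_pairs <- function(mat) {
    tot <- rowSums(mat)
    ss <- c()
    for (u in seq_len(nrow(mat))) for (v in seq_len(nrow(mat))) {
      if (u >= v) next
      hi <- which.max(c(tot[u], tot[v]))
      ru <- mat[c(u, v)[hi], ]; rv <- mat[c(u, v)[3 - hi], ]
      ss <- c(ss, if (tot[u] == tot[v]) 0
              else 100 * sum(rv > 0 & rv < ru) / sum(rv > 0))
    }
    ss
  }
  mean(c(score_pairs(w), score_pairs(t(w))))
}

# exact one-tailed Wilcoxon p by enumerating all 2^n sign assignments
oracle_wilcoxon <- function(before, after, direction) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  if (direction == "increase") mean(ws >= w_obs - 1e-12)
  else mean(ws <= w_obs + 1e-12)
}

# canonical form of a matrix under independent row/column permutations
canonical_form <- function(w) {
  perms_r <- perms_list(nrow(w)); perms_c <- perms_list(ncol(w))
  best <- NULL
  for (pr in perms_r) for (pc in perms_c) {
    v <- as.vector(w[pr, pc, drop = FALSE])
    key <- paste(v, collapse = ",")
    if (is.null(best) || key < best) best <- key
  }
  best
}

perms_list <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_list(n - 1L)) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# all matrices up to max_r x max_c with the given maximum total, positive
# marginals, deduplicated under row/column permutations (the metrics under
# test are permutation invariant)
enumerate_canonical_matrices <- function(max_total = 8L, max_r = 3L,
                                         max_c = 3L) {
  mats <- list()
  for (r in seq_len(max_r)) for (cc in seq_len(max_c)) {
    pr <- perms_list(r); pc <- perms_list(cc)
    seen <- new.env(parent = emptyenv())
    for (tot in seq_len(max_total)) {
      xs <- compositions_of(tot, r * cc)
      for (i in seq_len(nrow(xs))) {
        w <- matrix(xs[i, ], r, cc)
        if (any(rowSums(w) == 0) || any(colSums(w) == 0)) next
        best <- NULL
        for (p1 in pr) for (p2 in pc) {
          key <- paste(w[p1, p2, drop = FALSE], collapse = ",")
          if (is.null(best) || key < best) best <- key
        }
        if (!is.null(seen[[best]])) next
        seen[[best]] <- TRUE
        storage.mode(w) <- "integer"
        dimnames(w) <- list(paste0("p", seq_len(r)), paste0("b", seq_len(cc)))
        mats[[length(mats) + 1L]] <- w
      }
    }
  }
  mats
}
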