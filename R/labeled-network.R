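#' dispnet: from frugivore visitation networks to seed-dispersal networks
#'
#' Quantitative bipartite plant-frugivore networks record animal foraging
#' visits, but a visit is not necessarily a seed-dispersal event: frugivores
#' may swallow fruits whole and disperse viable seeds (mutualists), peck pulp
#' without moving seeds (pulp peckers) or destroy seeds (seed predators).
#' dispnet labels every link of a visitation network with its functional
#' outcome, prunes the non-mutualistic links, and quantifies how network- and
#' species-level structure changes, with quantitative null-model correction,
#' a topological coextinction model and paired one-tailed nonparametric tests.
#'
#' @keywords internal
#' @importFrom stats rlnorm rpois rbinom runif sd cor rnorm quantile
#' @importFrom utils read.csv write.csv read.delim write.table combn
"_PACKAGE"

#' Interaction outcome categories
#'
#' The three functional outcomes a bird-plant link can take, and the
#' single-letter codes used in the adjacency-format outcome layer
#' (`D` = seed_dispersal, `P` = pulp_pecking, `S` = seed_predation,
#' `-` = no link).
#'
#' @format Character vector of length 3.
#' @export
OUTCOME_LEVELS <- c("seed_dispersal", "pulp_pecking", "seed_predation")

OUTCOME_CODES <- c(seed_dispersal = "D", pulp_pecking = "P",
                   seed_predation = "S")

NONMUTUALISTIC <- c("pulp_pecking", "seed_predation")

#' Construct a labelled quantitative bipartite network
#'
#' A labelled network stores a plants-by-birds matrix of non-negative integer
#' visit counts together with one functional outcome label per nonzero cell
#' and the provenance of each label (`direct` natural-history record or
#' `inferred` from congeners / similar fruits).
#'
#' @param weights Integer matrix, plants as rows, birds as columns, with
#'   unique row and column names. All entries must be non-negative integers
#'   and the grand total must be positive.
#' @param outcomes Character matrix of the same shape: one of
#'   `r paste(OUTCOME_LEVELS, collapse = ", ")` for every nonzero cell,
#'   `NA` for zero cells. A single string recycles to all nonzero cells.
#' @param provenance Character matrix (`"direct"` or `"inferred"`), same
#'   shape; a single string recycles. Default `"direct"`.
#' @param network_id Identifier for the network.
#'
#' @return An object of class `labeled_network`: a list with elements
#'   `network_id`, `weights`, `outcomes`, `provenance`.
#' @examples
#' w <- matrix(c(4, 0, 1, 3), 2, 2, dimnames = list(c("P1", "P2"), c("B1", "B2")))
#' net <- labeled_network(w, outcomes = "seed_dispersal")
#' net
#' @export
labeled_network <- function(weights, outcomes, provenance = "direct",
                            network_id = "net") {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("weights must have row (plant) and column (bird) names")
  if (anyDuplicated(rownames(weights)) || anyDuplicated(colnames(weights)))
    stop("species ids must be unique within each guild")
  if (any(is.na(weights)) || any(weights < 0) ||
      any(weights != round(weights)))
    stop("weights must be non-negative integers")
  storage.mode(weights) <- "integer"
  if (sum(weights) <= 0L) stop("network has no interactions (total = 0)")

  expand <- function(x, what) {
    if (length(x) == 1L && !is.matrix(x)) {
      m <- matrix(NA_character_, nrow(weights), ncol(weights),
                  dimnames = dimnames(weights))
      m[weights > 0L] <- x
      m
    } else {
      x <- as.matrix(x)
      if (!all(dim(x) == dim(weights)))
        stop(what, " matrix must match the shape of weights")
      dimnames(x) <- dimnames(weights)
      x
    }
  }
  outcomes <- expand(outcomes, "outcomes")
  provenance <- expand(provenance, "provenance")
  outcomes[weights == 0L] <- NA_character_
  provenance[weights == 0L] <- NA_character_

  bad <- weights > 0L & (is.na(outcomes) | !(outcomes %in% OUTCOME_LEVELS))
  if (any(bad))
    stop("every nonzero cell needs one outcome label in {",
         paste(OUTCOME_LEVELS, collapse = ", "), "}; first offending cell: ",
         rownames(weights)[row(weights)[bad][1]], " x ",
         colnames(weights)[col(weights)[bad][1]])
  badp <- weights > 0L & !(provenance %in% c("direct", "inferred"))
  if (any(badp)) stop("provenance must be 'direct' or 'inferred'")

  structure(list(network_id = network_id, weights = weights,
                 outcomes = outcomes, provenance = provenance),
            class = "labeled_network")
}

#' @export
print.labeled_network <- function(x, ...) {
  w <- x$weights
  tab <- table(factor(x$outcomes[w > 0L], levels = OUTCOME_LEVELS))
  cat("Labelled visitation network '", x$network_id, "'\n", sep = "")
  cat(sprintf("  %d plants x %d birds, %d links, total frequency %d\n",
              nrow(w), ncol(w), sum(w > 0L), sum(w)))
  cat(sprintf("  links: %d seed dispersal, %d pulp pecking, %d seed predation\n",
              tab[1], tab[2], tab[3]))
  ninf <- sum(x$provenance[w > 0L] == "inferred", na.rm = TRUE)
  if (ninf > 0) cat(sprintf("  %d link label(s) inferred\n", ninf))
  invisible(x)
}

#' @export
as.matrix.labeled_network <- function(x, ...) x$weights

#' @rdname labeled_network
#' @param net A `labeled_network`.
#' @export
plant_totals <- function(net) rowSums(net$weights)

#' @rdname labeled_network
#' @export
bird_totals <- function(net) colSums(net$weights)

#' @rdname labeled_network
#' @export
total_frequency <- function(net) sum(net$weights)

#' @rdname labeled_network
#' @export
n_links <- function(net) sum(net$weights > 0L)

## internal: wrap a bare count matrix (e.g. a null-model sample) so that the
## metric functions, which only look at weights, can be applied to it
as_unlabeled_network <- function(w, network_id = "sample") {
  if (is.null(rownames(w))) rownames(w) <- paste0("p", seq_len(nrow(w)))
  if (is.null(colnames(w))) colnames(w) <- paste0("b", seq_len(ncol(w)))
  labeled_network(w, outcomes = "seed_dispersal", network_id = network_id)
}

#' Convert visitation rates to integer visit counts
#'
#' Networks sampled as visitation rates are converted to visit counts by
#' multiplying the rate observed on a plant species by the time spent
#' sampling that species and rounding to the nearest whole number
#' (halves round up, so the conversion is deterministic).
#'
#' @param rate Non-negative visitation rate(s), visits per unit time.
#' @param sampling_time Positive sampling duration(s), same time unit.
#' @return Integer visit count(s).
#' @examples
#' rate_to_counts(0.5, 10)  # 5
#' rate_to_counts(0.25, 10) # 2.5 rounds up to 3
#' @export
rate_to_counts <- function(rate, sampling_time) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(sampling_time <= 0)) stop("sampling_time must be positive")
  as.integer(floor(rate * sampling_time + 0.5))
}

#' Read labelled networks from an edge-list CSV
#'
#' The edge list has header columns
#' `network_id,plant,bird,count,outcome,provenance`, one row per observed
#' link. Duplicate (plant, bird) rows within a network are summed; they must
#' agree on the outcome label, otherwise reading stops with an error naming
#' the pair (direct records that disagree are a data problem, not something
#' to vote over).
#'
#' @param path Path to the CSV file.
#' @return Named list of [labeled_network] objects, one per `network_id`.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("network_id", "plant", "bird", "count", "outcome", "provenance")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(df$count)) || any(df$count != round(df$count)))
    stop("count must be integer")
  if (any(df$count < 1)) stop("count must be >= 1")
  lapply(split(df, df$network_id)[unique(df$network_id)], function(d) {
    key <- paste(d$plant, d$bird, sep = "\r")
    for (k in unique(key)) {
      lab <- unique(d$outcome[key == k])
      if (length(lab) > 1L)
        stop("conflicting outcome labels for pair ",
             sub("\r", " x ", k), ": ", paste(lab, collapse = " vs "))
    }
    plants <- unique(d$plant); birds <- unique(d$bird)
    w <- matrix(0L, length(plants), length(birds),
                dimnames = list(plants, birds))
    o <- p <- matrix(NA_character_, length(plants), length(birds),
                     dimnames = list(plants, birds))
    for (i in seq_len(nrow(d))) {
      w[d$plant[i], d$bird[i]] <- w[d$plant[i], d$bird[i]] + as.integer(d$count[i])
      o[d$plant[i], d$bird[i]] <- d$outcome[i]
      ## a pair observed both directly and by inference counts as direct
      prev <- p[d$plant[i], d$bird[i]]
      p[d$plant[i], d$bird[i]] <-
        if (!is.na(prev) && "direct" %in% c(prev, d$provenance[i])) "direct"
        else d$provenance[i]
    }
    labeled_network(w, o, p, network_id = d$network_id[1])
  })
}

#' Write labelled networks to an edge-list CSV
#'
#' @param nets A `labeled_network` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(nets, path) {
  if (inherits(nets, "labeled_network")) nets <- list(nets)
  rows <- do.call(rbind, lapply(nets, function(net) {
    idx <- which(net$weights > 0L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(network_id = net$network_id,
               plant = rownames(net$weights)[idx[, 1L]],
               bird = colnames(net$weights)[idx[, 2L]],
               count = net$weights[idx],
               outcome = net$outcomes[idx],
               provenance = net$provenance[idx],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the adjacency-matrix interchange format
#'
#' A network is stored as two parallel TSV files: a count matrix (first
#' column plant ids, header row bird ids, integer cells) and an outcome
#' matrix of the same shape with the categorical codes `D` (seed dispersal),
#' `P` (pulp pecking), `S` (seed predation) and `-` (no link).
#'
#' @param counts_path,outcomes_path Paths of the two TSV layers.
#' @param net A `labeled_network`.
#' @param network_id Identifier given to the network on reading.
#' @return `read_adjacency()` returns a [labeled_network];
#'   `write_adjacency()` returns `counts_path` invisibly.
#' @export
read_adjacency <- function(counts_path, outcomes_path, network_id = "net") {
  w <- as.matrix(utils::read.delim(counts_path, row.names = 1L,
                                   check.names = FALSE))
  oc <- as.matrix(utils::read.delim(outcomes_path, row.names = 1L,
                                    check.names = FALSE,
                                    colClasses = "character"))
  code2lab <- c(D = "seed_dispersal", P = "pulp_pecking", S = "seed_predation")
  o <- matrix(code2lab[oc], nrow(oc), ncol(oc), dimnames = dimnames(w))
  labeled_network(w, o, network_id = network_id)
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(net, counts_path, outcomes_path) {
  utils::write.table(net$weights, counts_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  oc <- matrix("-", nrow(net$weights), ncol(net$weights),
               dimnames = dimnames(net$weights))
  nz <- net$weights > 0L
  oc[nz] <- OUTCOME_CODES[net$outcomes[nz]]
  utils::write.table(oc, outcomes_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(counts_path)
}

#' Read a plant-trait table
#'
#' Columns: `plant,genus,fruit_type,fruit_size_class,seed_size_class`
#' (size classes ordinal). One record per plant id.
#'
#' @param path Path to the traits CSV.
#' @return A data frame, one row per plant.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant", "genus", "fruit_type", "fruit_size_class",
            "seed_size_class")
  if (!all(need %in% names(tr)))
    stop("traits table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tr$plant)) stop("one record per plant id required")
  tr
}

#' Infer the outcome of an unobserved bird-plant interaction
#'
#' When a pairwise interaction lacks a direct natural-history record, its
#' functional outcome is inferred from the same bird's recorded interactions
#' with (1) congeneric plant species, or failing that (2) plant species whose
#' fruits are of the same type and seed-size class. Within a rule, conflicts
#' are resolved by majority vote; a residual tie is broken in favour of the
#' less mutualistic outcome (seed_predation over pulp_pecking over
#' seed_dispersal), a deliberately conservative stance about crediting
#' dispersal. Rule (1) takes precedence over rule (2). If neither rule fires
#' the interaction is `"unclassified"` (a value, not an error).
#'
#' @param bird,plant Species ids of the unobserved pair.
#' @param known Data frame of labelled records with columns
#'   `bird`, `plant`, `outcome`.
#' @param traits Plant-trait table as returned by [read_traits()].
#' @return List with elements `outcome` and `provenance` (`"inferred"`, or
#'   `NA` when unclassified).
#' @export
infer_outcome <- function(bird, plant, known, traits) {
  if (any(known$bird == bird & known$plant == plant))
    stop("pair already has a direct record; nothing to infer")
  trow <- traits[traits$plant == plant, , drop = FALSE]
  if (nrow(trow) == 0L) stop("no traits available for plant ", plant)

  vote <- function(labels) {
    if (length(labels) == 0L) return(NULL)
    tab <- table(labels)
    top <- names(tab)[tab == max(tab)]
    ## severity order breaks residual ties
    for (lab in c("seed_predation", "pulp_pecking", "seed_dispersal"))
      if (lab %in% top) return(lab)
  }

  rec <- known[known$bird == bird, , drop = FALSE]
  rec <- merge(rec, traits, by = "plant")
  out <- vote(rec$outcome[rec$genus == trow$genus])                    # rule 1
  if (is.null(out))
    out <- vote(rec$outcome[rec$fruit_type == trow$fruit_type &        # rule 2
                            rec$seed_size_class == trow$seed_size_class])
  if (is.null(out))
    return(list(outcome = "unclassified", provenance = NA_character_))
  list(outcome = out, provenance = "inferred")
}

#' Prune non-mutualistic links from a labelled network
#'
#' Removes the links whose functional outcome is not seed dispersal, either
#' all of them (`"all_nonmutualistic"`: pulp pecking and seed predation) or
#' only the truly antagonistic ones (`"predation_only"`). Species whose total
#' drops to zero are kept in the matrix (several species-level metrics retain
#' their zero degree/frequency) but are reported in the dropped lists; the
#' network-level metric functions exclude them.
#'
#' @param net A [labeled_network].
#' @param mode `"all_nonmutualistic"` (default) or `"predation_only"`.
#' @return An object of class `prune_result`: list with `pruned`
#'   (a [labeled_network]), `dropped_plants` and `dropped_birds` (ids whose
#'   post-prune total is zero).
#' @examples
#' w <- matrix(c(2, 1, 1, 0), 2, 2, dimnames = list(c("P1","P2"), c("B1","B2")))
#' o <- matrix(c("seed_dispersal", "seed_predation", "pulp_pecking", NA), 2, 2)
#' prune(labeled_network(w, o), "all_nonmutualistic")
#' @export
prune <- function(net, mode = c("all_nonmutualistic", "predation_only")) {
  mode <- match.arg(mode)
  drop_labels <- if (mode == "all_nonmutualistic") NONMUTUALISTIC
                 else "seed_predation"
  w <- net$weights; o <- net$outcomes; p <- net$provenance
  kill <- !is.na(o) & o %in% drop_labels
  w[kill] <- 0L
  o[kill] <- NA_character_
  p[kill] <- NA_character_
  if (sum(w) == 0L)
    stop("pruning removed every interaction; nothing left to analyse")
  pruned <- labeled_network(w, o, p, network_id = net$network_id)
  structure(list(pruned = pruned,
                 dropped_plants = rownames(w)[rowSums(w) == 0L],
                 dropped_birds = colnames(w)[colSums(w) == 0L],
                 mode = mode),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("Pruned network (mode: ", x$mode, ")\n", sep = "")
  print(x$pruned)
  cat(sprintf("  species losing all links: %d plants, %d birds\n",
              length(x$dropped_plants), length(x$dropped_birds)))
  invisible(x)
}
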