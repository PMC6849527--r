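## Seeded generator of labelled visitation networks with the statistical
## structure the analysis assumes: lognormal species abundances, link
## intensity proportional to abundance products (hence skewed counts and a
## nested mutualistic backbone), bird roles mixing pure dispersers, pulp
## peckers, seed predators and mixed-role birds, seed-size/bill-size trait
## matching for the granivores, and damped visit frequencies on
## non-mutualistic links so that they matter more in qualitative than in
## quantitative terms.

#' Configuration of the synthetic network generator
#'
#' @param n_networks Number of networks in an ensemble.
#' @param n_plants,n_birds Species counts per network.
#' @param abund_meanlog Lognormal abundance mean-log (both guilds).
#' @param plant_sdlog,bird_sdlog Lognormal abundance spread per guild. The
#'   bird side is the more skewed one (a few hub frugivores dominate the
#'   visit counts); fruit-crop sizes vary less extremely.
#' @param guild_mix Named fractions (summing to 1) of bird roles:
#'   `disperser`, `pulp_pecker`, `seed_predator`, `mixed`. The default keeps
#'   roughly a third of the birds without any seed-dispersal link.
#' @param mean_visits Mean of the Poisson visit intensity over cells (the
#'   abundance product is normalized to this mean), before damping.
#' @param niche_sdlog Lognormal standard deviation of the interaction-
#'   specific intensity noise (pairwise niche/phenology matching); 0 makes
#'   the intensity a pure rank-one abundance product dominated by a single
#'   hub bird.
#' @param nonmut_abundance_coupling Exponent in \[0, 1\] tying
#'   non-mutualistic foraging intensity to fruit-crop abundance. Dispersers
#'   track fruit abundance fully (exponent 1); granivores and pulp peckers,
#'   for which fleshy fruit is a side resource chosen by seed and pulp
#'   traits, track it only weakly. The non-mutualistic plant-side factor is
#'   rescaled to the same mean as the mutualistic one, so the coupling
#'   shifts where non-mutualists forage without changing how much.
#' @param nonmut_niche Factor in (0, 1] scaling the non-mutualistic visit
#'   intensity, giving pulp peckers and seed predators a narrower
#'   fleshy-fruit niche (lower degree) than legitimate dispersers, for whom
#'   fruit is the primary resource.
#' @param damping Factor in (0, 1] thinning the visit count of
#'   non-mutualistic links beyond the first visit; values below 1 make the
#'   non-mutualistic frequency share fall below the link share.
#' @param link_share_range Target envelope for the realized share of links
#'   that are non-mutualistic (used for validation, not enforcement).
#' @param predator_bill_range Range of the seed-size threshold below which
#'   a pure seed predator can crack and eat seeds.
#' @param mixed_gape_range Range of the seed-size threshold of mixed-role
#'   birds: seeds at least this large and hard pass the gut intact (the
#'   bird disperses them), smaller weaker seeds are destroyed.
#' @param overdispersion Optional negative-binomial overdispersion of the
#'   visit counts (0 = Poisson).
#' @param resample_cap Attempts before giving up on a degenerate draw.
#' @param seed Master RNG seed of the ensemble.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_networks = 7L, n_plants = 20L, n_birds = 25L,
                             abund_meanlog = 0, plant_sdlog = 1,
                             bird_sdlog = 2,
                             guild_mix = c(disperser = 0.52,
                                           pulp_pecker = 0.18,
                                           seed_predator = 0.18,
                                           mixed = 0.12),
                             mean_visits = 4,
                             niche_sdlog = 1,
                             nonmut_abundance_coupling = 0.4,
                             nonmut_niche = 0.45,
                             damping = 0.12,
                             link_share_range = c(0.21, 0.48),
                             predator_bill_range = c(0.3, 1),
                             mixed_gape_range = c(0.25, 0.75),
                             overdispersion = 0,
                             resample_cap = 20L,
                             seed = 1L) {
  if (abs(sum(guild_mix) - 1) > 1e-8) stop("guild_mix fractions must sum to 1")
  if (damping <= 0 || damping > 1) stop("damping must lie in (0, 1]")
  if (n_networks < 1L || n_plants < 1L || n_birds < 1L)
    stop("all counts must be >= 1")
  structure(as.list(environment()), class = "synthetic_config")
}

## largest-remainder integer apportionment of n birds over role fractions,
## guaranteeing >= 1 pure non-mutualist whenever the mix asks for any
role_counts <- function(guild_mix, n_birds) {
  x <- floor(guild_mix * n_birds)
  rem <- n_birds - sum(x)
  if (rem > 0) {
    extra <- order(guild_mix * n_birds - x, decreasing = TRUE)[seq_len(rem)]
    x[extra] <- x[extra] + 1
  }
  pure_nm <- c("pulp_pecker", "seed_predator")
  if (sum(guild_mix[pure_nm]) > 0 && sum(x[pure_nm]) == 0) {
    donor <- names(which.max(x[c("disperser", "mixed")]))
    taker <- pure_nm[which.max(guild_mix[pure_nm])]
    x[donor] <- x[donor] - 1; x[taker] <- x[taker] + 1
  }
  x
}

#' Generate one labelled synthetic visitation network
#'
#' Draws lognormal abundances for both guilds, Poisson (optionally
#' negative-binomial) visit counts with intensity proportional to the
#' abundance product, assigns each bird a role from the configured mix and
#' labels every link accordingly. Seed predators only interact with plants
#' whose seeds are small enough for their bill; mixed-role birds disperse
#' large hard seeds and destroy small weak ones, so their outcome differs
#' between plant species. Counts on non-mutualistic links are thinned
#' beyond the first visit by the damping factor. Species that end up
#' without links are given a single visit to their highest-intensity
#' admissible partner, so every listed species takes part in the network.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the same seed reproduces the network exactly.
#' @param network_id Identifier of the generated network.
#' @return A [labeled_network].
#' @export
generate_network <- function(config, seed = config$seed,
                             network_id = "synthetic") {
  set.seed(seed)
  P <- config$n_plants; A <- config$n_birds
  for (attempt in seq_len(config$resample_cap)) {
    plant_ab <- stats::rlnorm(P, config$abund_meanlog, config$plant_sdlog)
    bird_ab <- stats::rlnorm(A, config$abund_meanlog, config$bird_sdlog)
    seed_size <- stats::runif(P)

    counts <- role_counts(config$guild_mix, A)
    role <- sample(rep(names(counts), counts))
    bill <- stats::runif(A, config$predator_bill_range[1L],
                         config$predator_bill_range[2L])
    gape <- stats::runif(A, config$mixed_gape_range[1L],
                         config$mixed_gape_range[2L])

    ## outcome of cell (i, j) were the link to exist
    outcome <- matrix(NA_character_, P, A)
    feasible <- matrix(TRUE, P, A)
    for (j in seq_len(A)) {
      outcome[, j] <- switch(role[j],
        disperser = "seed_dispersal",
        pulp_pecker = "pulp_pecking",
        seed_predator = "seed_predation",
        mixed = ifelse(seed_size >= gape[j], "seed_dispersal",
                       "seed_predation"))
      if (role[j] == "seed_predator") {
        ok <- seed_size <= bill[j]
        if (!any(ok)) ok[which.min(seed_size)] <- TRUE
        feasible[, j] <- ok
      }
    }

    ## visit intensity: abundance product times pairwise niche matching;
    ## non-mutualistic foraging does not track fruit-crop size, so those
    ## cells get a flat plant-side factor (fleshy fruit is a side resource
    ## for granivores and pulp peckers)
    eps <- matrix(stats::rlnorm(P * A, 0, config$niche_sdlog), P, A)
    lam <- outer(plant_ab, bird_ab) * eps
    nm_cell <- outcome != "seed_dispersal"
    pf <- plant_ab^config$nonmut_abundance_coupling
    pf <- pf / mean(pf) * mean(plant_ab) * config$nonmut_niche
    nm_lam <- outer(pf, bird_ab) * eps
    lam[nm_cell] <- nm_lam[nm_cell]
    lam <- lam / mean(lam) * config$mean_visits
    lam[!feasible] <- 0
    y <- if (config$overdispersion > 0)
      matrix(stats::rnbinom(P * A, mu = lam,
                            size = 1 / config$overdispersion), P, A)
    else matrix(stats::rpois(P * A, lam), P, A)
    ## damp visit frequency (not link existence) on non-mutualistic links
    nm <- y > 0L & outcome != "seed_dispersal"
    y[nm] <- 1L + stats::rbinom(sum(nm), y[nm] - 1L, config$damping)

    ## connect any species left without links via its best admissible cell
    for (i in which(rowSums(y) == 0L)) {
      j <- which.max(lam[i, ] + ifelse(feasible[i, ], 0, -Inf))
      y[i, j] <- 1L
    }
    for (j in which(colSums(y) == 0L)) {
      i <- which.max(lam[, j] * feasible[, j])
      if (!feasible[i, j]) i <- which.min(seed_size)
      y[i, j] <- 1L
    }
    if (sum(y) == 0L) next

    dimnames(y) <- list(sprintf("plant_%02d", seq_len(P)),
                        sprintf("bird_%02d", seq_len(A)))
    outcome[y == 0L] <- NA_character_
    dimnames(outcome) <- dimnames(y)
    return(labeled_network(y, outcome, provenance = "direct",
                           network_id = network_id))
  }
  stop("could not generate a non-degenerate network in ",
       config$resample_cap, " attempts")
}

#' Generate a seeded ensemble of synthetic networks
#'
#' Derives one sub-seed per network from the master seed of the
#' configuration and generates `n_networks` labelled networks plus a
#' manifest recording the configuration echo and every sub-seed, so any
#' network can be regenerated in isolation.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_ensemble`: list with `networks`
#'   (named list of [labeled_network]) and `manifest`.
#' @export
generate_ensemble <- function(config) {
  set.seed(config$seed)
  sub_seeds <- sample.int(2^31 - 2L, config$n_networks)
  ids <- sprintf("S%d", seq_len(config$n_networks))
  networks <- lapply(seq_len(config$n_networks), function(k)
    generate_network(config, seed = sub_seeds[k], network_id = ids[k]))
  names(networks) <- ids
  manifest <- list(
    config = config[setdiff(names(unclass(config)), "")],
    master_seed = config$seed,
    sub_seeds = stats::setNames(as.list(sub_seeds), ids))
  structure(list(networks = networks, manifest = manifest),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("Synthetic ensemble of %d networks (master seed %d)\n",
              length(x$networks), x$manifest$master_seed))
  for (net in x$networks)
    cat(sprintf("  %s: %d links, total %d, non-mutualistic link share %.2f\n",
                net$network_id, n_links(net), total_frequency(net),
                nonmutualistic_shares(net)["link_share"]))
  invisible(x)
}

#' Realized non-mutualistic shares of a network
#'
#' Fraction of links and of total interaction frequency carried by
#' pulp-pecking and seed-predation links.
#'
#' @param net A [labeled_network].
#' @return Named vector `link_share`, `frequency_share`.
#' @export
nonmutualistic_shares <- function(net) {
  nz <- net$weights > 0L
  nm <- nz & net$outcomes %in% NONMUTUALISTIC
  c(link_share = sum(nm) / sum(nz),
    frequency_share = sum(net$weights[nm]) / sum(net$weights))
}

#' @rdname generate_ensemble
#' @param ensemble A `synthetic_ensemble`.
#' @param dir Output directory; writes the standard edge-list CSV
#'   (`networks.csv`) and a JSON manifest (`manifest.json`).
#' @export
write_synthetic_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(ensemble$networks, file.path(dir, "networks.csv"))
  jsonlite::write_json(ensemble$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
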