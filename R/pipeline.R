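## Orchestration of the full analysis: classify/load -> prune -> metrics
## (raw and delta-corrected under the null models) -> coextinction ->
## paired comparison tables, with every seed logged so a rerun with the
## same configuration is bit-identical.

#' Configuration of a full analysis run
#'
#' @param input Path to an edge-list CSV of labelled networks, or `NULL`
#'   to analyse synthetic networks.
#' @param traits Optional path to a plant-trait CSV (kept with the run for
#'   provenance; outcome inference happens upstream of the edge list).
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param prune_modes Character subset of
#'   `c("all_nonmutualistic", "predation_only")`; at least one.
#' @param null_models Character subset of
#'   `c("patefield", "quasiswap_count")`; may be empty to skip
#'   delta-correction.
#' @param n_null Null-ensemble size per network, state and model.
#' @param threshold Coextinction failure threshold (fraction of frequency
#'   lost).
#' @param lpa_repeats Restarts of the modularity search.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, traits = NULL,
                       synthetic = synthetic_config(),
                       prune_modes = "all_nonmutualistic",
                       null_models = c("patefield", "quasiswap_count"),
                       n_null = 1000L, threshold = 0.75, lpa_repeats = 1L,
                       seed = 1L, out_dir = NULL) {
  prune_modes <- match.arg(prune_modes,
                           c("all_nonmutualistic", "predation_only"),
                           several.ok = TRUE)
  if (length(prune_modes) < 1L) stop("need at least one prune mode")
  if (length(null_models) > 0L)
    null_models <- match.arg(null_models,
                             c("patefield", "quasiswap_count"),
                             several.ok = TRUE)
  if (n_null < 1L) stop("ensemble size must be >= 1")
  structure(as.list(environment()), class = "run_config")
}

state_label <- c(all_nonmutualistic = "pruned_all",
                 predation_only = "pruned_predation")

## network + species metrics (incl. robustness / resilience) for one state
state_metrics <- function(net, state, seed, lpa_repeats, threshold) {
  netm <- network_metrics(net, state, seed = seed, lpa_repeats = lpa_repeats)
  coex <- simulate_coextinction(net, failure_threshold = threshold)
  netm <- rbind(netm, data.frame(network_id = net$network_id, state = state,
                                 metric = "robustness",
                                 value = robustness(coex), seed = seed))
  spm <- species_metrics(net, state)
  res <- resilience_75(coex)
  spm$resilience_75 <- NA_real_
  hit <- spm$guild == "plant" & spm$species %in% names(res)
  spm$resilience_75[hit] <- res[spm$species[hit]]
  list(network = netm, species = spm, coextinction = coex)
}

#' Run the full analysis
#'
#' Executes every stage on the input (or synthetic) networks: pruning under
#' the requested modes, raw network- and species-level metrics per state,
#' delta-transformed network metrics under the requested null models,
#' coextinction curves, and the before/after comparison tables with
#' one-tailed tests and a multiple-test summary. Any stage failure aborts
#' with the stage and network named. With an output directory set, all
#' tables are written as CSVs together with a log recording every seed;
#' rerunning the same configuration reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `networks`, `network_report`,
#'   `species_report`, `delta_report`, `comparisons`, `coextinction`,
#'   `seeds`, `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("dispnet run, master seed %d", config$seed),
                 sprintf("package version %s",
                         as.character(utils::packageVersion("dispnet"))))
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for network '%s': %s",
                   what, id, conditionMessage(e)), call. = FALSE))
  }

  networks <- if (!is.null(config$input)) {
    stage("read", config$input, read_edge_list(config$input))
  } else {
    syn <- config$synthetic
    syn$seed <- config$seed
    stage("simulate", "ensemble", generate_ensemble(syn)$networks)
  }
  log_lines <- c(log_lines, sprintf("%d networks: %s", length(networks),
                                    paste(names(networks), collapse = ", ")))

  ## derive one seed stream for all stochastic stages
  set.seed(config$seed)
  seed_of <- function() sample.int(2^31 - 2L, 1L)

  network_report <- NULL; species_report <- NULL; delta_report <- NULL
  coex_out <- list()
  for (net in networks) {
    id <- net$network_id
    states <- list(original = net)
    for (mode in config$prune_modes)
      states[[state_label[[mode]]]] <-
        stage("prune", id, prune(net, mode))$pruned
    for (sname in names(states)) {
      sd_metrics <- seed_of()
      sm <- stage(paste0("metrics:", sname), id,
                  state_metrics(states[[sname]], sname, sd_metrics,
                                config$lpa_repeats, config$threshold))
      network_report <- rbind(network_report, sm$network)
      species_report <- rbind(species_report, sm$species)
      coex_out[[paste(id, sname, sep = ".")]] <- sm$coextinction
      log_lines <- c(log_lines,
                     sprintf("metrics %s/%s seed %d", id, sname, sd_metrics))
      for (model in config$null_models) {
        sd_null <- seed_of()
        ens <- stage(paste0("nulls:", model), id,
                     null_ensemble(states[[sname]], model,
                                   n_samples = config$n_null,
                                   seed = sd_null))
        lpa_seed0 <- seed_of()
        fns <- list(
          weighted_connectance = function(n) weighted_connectance(n),
          weighted_nodf = function(n) weighted_nodf(n),
          h2_prime = function(n) h2_prime(n),
          modularity_q = function(n, k)
            lpawb_plus(n, seed = (lpa_seed0 + k) %% (2^31 - 1L),
                       repeats = config$lpa_repeats)$q,
          robustness = function(n) robustness(simulate_coextinction(
            n, failure_threshold = config$threshold)))
        for (metric in names(fns)) {
          dm <- stage(paste0("delta:", metric), id,
                      delta_transform(fns[[metric]], states[[sname]], ens))
          delta_report <- rbind(delta_report, data.frame(
            network_id = id, state = sname, null_model = model,
            metric = metric, observed = dm$observed,
            null_mean = dm$null_mean, delta = dm$delta,
            n_samples = dm$n_used, seed = sd_null,
            stringsAsFactors = FALSE))
        }
        log_lines <- c(log_lines,
                       sprintf("nulls %s/%s/%s seed %d (lpa stream %d)",
                               id, sname, model, sd_null, lpa_seed0))
      }
    }
  }

  comparisons <- list()
  if (length(networks) >= 2L) {
    for (mode in config$prune_modes) {
      after <- state_label[[mode]]
      comparisons[[after]] <- stage("compare", after,
        build_comparison_tables(network_report, species_report,
                                before_state = "original",
                                after_state = after))
      ## delta-corrected network-level comparisons per null model
      for (model in config$null_models) {
        dr <- delta_report[delta_report$null_model == model, ]
        dtab <- data.frame(network_id = dr$network_id, state = dr$state,
                           metric = dr$metric, value = dr$delta,
                           seed = dr$seed, stringsAsFactors = FALSE)
        comparisons[[paste(after, model, sep = ".")]] <- stage(
          "compare-delta", model,
          build_comparison_tables(dtab, species_report,
                                  before_state = "original",
                                  after_state = after))
      }
    }
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- list(networks = networks, network_report = network_report,
              species_report = species_report, delta_report = delta_report,
              comparisons = comparisons, coextinction = coex_out,
              seeds = config$seed, log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metric_report(network_report,
                        file.path(config$out_dir, "network_metrics.csv"))
    write_species_report(species_report,
                         file.path(config$out_dir, "species_metrics.csv"))
    if (!is.null(delta_report))
      utils::write.csv(delta_report,
                       file.path(config$out_dir, "delta_metrics.csv"),
                       row.names = FALSE, na = "")
    for (nm in names(comparisons))
      write_comparison_tables(comparisons[[nm]],
                              file.path(config$out_dir, paste0("compare_", nm)))
    for (nm in names(coex_out))
      write_coextinction_curve(coex_out[[nm]],
                               file.path(config$out_dir,
                                         paste0("coextinction_", nm, ".csv")))
    ## wall time stays out of the log file so reruns are bit-identical
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  out$log <- c(out$log, sprintf("elapsed %.1f s", elapsed))
  invisible(out)
}
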