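#' Pipeline run configuration
#'
#' Bundles every protocol constant of the multistability pipeline. The
#' defaults reproduce the reference protocol scale: gamma-band frequencies
#' (25-75 Hz), global coupling 1000, 1 ms Euler steps, 2000 iterations with a
#' 100-step burn-in, 200 frequency combinations of 100 runs each, cluster
#' counts evaluated up to 6, and 15 rewired null networks with 40 frequency
#' combinations each. All sub-seeds are derived deterministically from the
#' master seed, so any single simulation is replayable in isolation.
#'
#' @param network either a `structural_network`, a
#'   [synthetic_network_spec()], or a list with `weights_path`/`lengths_path`
#'   for [read_network()].
#' @param band_hz intrinsic frequency band (Hz).
#' @param k_global global coupling scaling factor.
#' @param dt Euler step (s).
#' @param n_steps,burn_in iteration counts.
#' @param n_systems,n_runs survey scale for the real network.
#' @param k_max maximum cluster count.
#' @param n_reference gap-statistic Monte Carlo references.
#' @param n_null_networks,n_null_systems null-ensemble scale.
#' @param swaps_per_edge rewiring intensity of the null generator.
#' @param normalise_by_n,delay_divisor,mode,rule,index_resolution see
#'   [build_system()], [assess_multistability()].
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(network = synthetic_network_spec(),
                       band_hz = c(25, 75), k_global = 1000, dt = 0.001,
                       n_steps = 2000, burn_in = 100,
                       n_systems = 200, n_runs = 100, k_max = 6,
                       n_reference = 50, n_null_networks = 15,
                       n_null_systems = 40, swaps_per_edge = 10,
                       normalise_by_n = FALSE, delay_divisor = 20,
                       mode = "phase", rule = "firstSEmax",
                       index_resolution = 0.01, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_systems >= 1, cfg$n_runs >= 2, cfg$k_max >= 2,
            cfg$n_null_networks >= 0, cfg$n_steps > cfg$burn_in)
  structure(cfg, class = "run_config")
}

#' Smoke-scale configuration
#'
#' A small, strongly modular fixture (8 nodes, 2 modules) surveyed at reduced
#' scale — 20 systems of 20 runs, 3 null networks of 10 systems — so the full
#' pipeline completes in minutes on one CPU while preserving every stage of
#' the protocol.
#'
#' @param seed master seed.
#' @return a `run_config`.
#' @export
smoke_config <- function(seed = 1L) {
  run_config(
    network = synthetic_network_spec(n_nodes = 8, n_modules = 2,
                                     p_within = 1.0, p_between = 0.15,
                                     weight_meanlog = log(0.1),
                                     between_weight_factor = 0.3,
                                     seed = seed),
    n_systems = 20, n_runs = 20, n_null_networks = 3, n_null_systems = 10,
    n_reference = 25, seed = seed)
}

resolve_network <- function(network, seed) {
  if (inherits(network, "structural_network")) return(network)
  if (inherits(network, "synthetic_network_spec")) return(generate_network(network))
  if (is.list(network) && !is.null(network$weights_path)) {
    return(read_network(network$weights_path, network$lengths_path,
                        header = isTRUE(network$header),
                        json_path = network$json_path))
  }
  stop("network must be a structural_network, a synthetic_network_spec, ",
       "or a list with weights_path/lengths_path")
}

#' Run the full multistability pipeline
#'
#' Chains every stage: resolve or generate the structural network, build the
#' rewired null ensemble, survey the real network and each null, pool the
#' null state counts, compare distributions with a KS test, form the
#' real-minus-null contrast matrix, and compute the structure-function
#' correlation. All numeric artifacts are written to `out_dir` as delimited
#' text / CSV / JSON together with a manifest of the configuration and
#' derived seeds; re-running with the same configuration reproduces them.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param verbose print per-stage progress?
#' @return invisibly, a list with `net`, `nulls`, `real_survey`,
#'   `null_surveys`, `null_distribution`, `ks`, `contrast`,
#'   `structure_function_r` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = interactive()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  seeds <- derive_seeds(config$seed, 3L + config$n_null_networks * 2L)
  net <- resolve_network(config$network, seeds[1L])

  say("surveying real network (", config$n_systems, " systems x ",
      config$n_runs, " runs)")
  survey_args <- config[c("band_hz", "k_global", "dt", "normalise_by_n",
                          "delay_divisor", "n_steps", "burn_in", "k_max",
                          "n_reference", "mode", "rule", "index_resolution")]
  real <- do.call(survey_network,
                  c(list(net = net, n_systems = config$n_systems,
                         n_runs = config$n_runs, seed = seeds[2L]),
                    survey_args))

  nulls <- list()
  null_surveys <- list()
  if (config$n_null_networks > 0) {
    for (b in seq_len(config$n_null_networks)) {
      say("null network ", b, "/", config$n_null_networks)
      nulls[[b]] <- randomize_network(net, config$swaps_per_edge,
                                      seed = seeds[2L + 2L * b])
      null_surveys[[b]] <- do.call(
        survey_network,
        c(list(net = nulls[[b]], n_systems = config$n_null_systems,
               n_runs = config$n_runs, seed = seeds[3L + 2L * b]),
          survey_args))
    }
  }

  null_ks <- unlist(lapply(null_surveys,
                           function(s) s$distribution$samples))
  null_distribution <- if (length(null_ks)) {
    state_count_distribution(null_ks, config$k_max)
  } else NULL
  ks <- if (!is.null(null_distribution)) {
    ks_compare(real$distribution, null_distribution)
  } else NULL
  contrast <- if (length(null_surveys)) {
    contrast_matrix(real$results,
                    unlist(lapply(null_surveys, `[[`, "results"),
                           recursive = FALSE))
  } else NULL
  sf_r <- structure_function_correlation(real$avg_sync, net$weights)

  manifest <- list(
    package_version = as.character(utils::packageVersion("strobosync")),
    config = config_as_manifest(config),
    derived_seeds = seeds)

  out <- list(net = net, nulls = nulls, real_survey = real,
              null_surveys = null_surveys,
              null_distribution = null_distribution, ks = ks,
              contrast = contrast, structure_function_r = sf_r,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, config, out_dir)
  invisible(out)
}

config_as_manifest <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$network, "synthetic_network_spec")) {
    cfg$network <- c(list(kind = "synthetic"), unclass(cfg$network))
  } else if (inherits(cfg$network, "structural_network")) {
    cfg$network <- list(kind = "in-memory", n_nodes = cfg$network$n_nodes)
  } else {
    cfg$network <- c(list(kind = "files"), cfg$network)
  }
  cfg
}

write_pipeline_artifacts <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_network(out$net, p("network_weights.csv"), p("network_lengths.csv"),
                json_path = p("network_meta.json"),
                provenance = list(seed = config$seed))
  counts <- data.frame(k = as.integer(names(out$real_survey$distribution$counts)),
                       real = as.integer(out$real_survey$distribution$counts))
  if (!is.null(out$null_distribution)) {
    counts$null_pooled <- as.integer(out$null_distribution$counts)
  }
  utils::write.csv(counts, p("state_counts.csv"), row.names = FALSE)
  write_matrix_file(out$real_survey$avg_sync, p("avg_sync.csv"))
  if (!is.null(out$contrast)) {
    write_matrix_file(out$contrast, p("contrast_matrix.csv"))
  }
  summary <- list(
    n_nodes = out$net$n_nodes,
    non_multistable_fraction_real =
      non_multistable_fraction(out$real_survey$distribution),
    structure_function_r = out$structure_function_r)
  if (!is.null(out$ks)) {
    summary$ks_statistic <- out$ks$statistic
    summary$ks_p_value <- out$ks$p_value
    summary$null_non_multistable_fraction <-
      non_multistable_fraction(out$null_distribution)
    summary$contrast_aggregation <- attr(out$contrast, "aggregation")
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}
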