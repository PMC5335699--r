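#' State-count distribution over a set of dynamical systems
#'
#' @param ks integer vector of per-system optimal cluster counts.
#' @param k_max largest cluster count evaluated.
#' @return a `state_count_distribution`: list with `counts` (named 1..k_max),
#'   `samples` (the per-system k values) and `n_systems`.
#' @export
state_count_distribution <- function(ks, k_max = 6) {
  ks <- as.integer(ks)
  if (!length(ks)) stop("empty sample of state counts")
  if (any(ks < 1L | ks > k_max)) stop("state counts outside 1..", k_max)
  counts <- tabulate(ks, nbins = k_max)
  names(counts) <- seq_len(k_max)
  structure(list(counts = counts, samples = ks, n_systems = length(ks)),
            class = "state_count_distribution")
}

#' @export
print.state_count_distribution <- function(x, ...) {
  cat("state_count_distribution over", x$n_systems, "systems\n")
  print(x$counts)
  cat("  non-multistable (k = 1):",
      sprintf("%.1f%%", 100 * x$counts[1L] / x$n_systems), "\n")
  invisible(x)
}

#' Fraction of systems without multistability
#' @param dist a `state_count_distribution`.
#' @return proportion of systems with a single stable state.
#' @export
non_multistable_fraction <- function(dist) {
  unname(dist$counts[1L] / dist$n_systems)
}

#' Survey the multistability of a network across frequency combinations
#'
#' Samples `n_systems` intrinsic-frequency vectors from the band, builds one
#' dynamical system per vector on the given network, and assesses each with
#' [assess_multistability()]. The reference protocol uses 200 systems of 100
#' runs each (20,000 simulations per network) and 40 systems per randomised
#' null network. The survey also accumulates the grand-average pairwise
#' synchronisation matrix over all runs of all systems.
#'
#' @param net a `structural_network`.
#' @param n_systems number of frequency combinations to assess.
#' @param n_runs random initialisations per system.
#' @param band_hz intrinsic frequency band (Hz).
#' @param k_global,dt,normalise_by_n,delay_divisor see [build_system()].
#' @param n_steps,burn_in,k_max,n_reference,mode,rule,index_resolution
#'   per-system protocol parameters, see [assess_multistability()].
#' @param seed master seed; per-system seeds are derived deterministically.
#' @return a `network_survey`: list with `distribution`
#'   (a [state_count_distribution()]), `results` (per-system
#'   `multistability_result`s), `avg_sync` (N x N grand-average
#'   synchronisation matrix, zero diagonal) and `net`.
#' @export
survey_network <- function(net, n_systems = 200, n_runs = 100,
                           band_hz = c(25, 75), k_global = 1000, dt = 0.001,
                           normalise_by_n = FALSE, delay_divisor = 20,
                           n_steps = 2000, burn_in = 100, k_max = 6,
                           n_reference = 50, mode = "phase",
                           rule = "firstSEmax", index_resolution = 0.01,
                           seed = NULL) {
  if (n_systems < 1) stop("n_systems must be at least 1")
  seeds <- matrix(derive_seeds(seed %||% 0L, 2L * n_systems), ncol = 2L)
  results <- vector("list", n_systems)
  pat_sum <- numeric(n_pairs(net$n_nodes))
  n_pat <- 0L
  for (s in seq_len(n_systems)) {
    freqs <- sample_frequencies(net$n_nodes, band_hz, seed = seeds[s, 1L])
    sys <- build_system(net, freqs, k_global = k_global, dt = dt,
                        normalise_by_n = normalise_by_n,
                        delay_divisor = delay_divisor)
    results[[s]] <- assess_multistability(
      sys, n_runs = n_runs, k_max = k_max, n_reference = n_reference,
      seed = seeds[s, 2L], n_steps = n_steps, burn_in = burn_in,
      mode = mode, rule = rule, index_resolution = index_resolution)
    pat_sum <- pat_sum + colSums(unclass(results[[s]]$ensemble))
    n_pat <- n_pat + n_runs
  }
  ks <- vapply(results, function(r) r$optimal_k, 1L)
  avg <- pattern_to_matrix(pat_sum / n_pat, net$n_nodes)
  structure(
    list(distribution = state_count_distribution(ks, k_max),
         results = results, avg_sync = avg, net = net),
    class = "network_survey"
  )
}

#' @export
print.network_survey <- function(x, ...) {
  cat("network_survey of", x$net$n_nodes, "-node network,",
      x$distribution$n_systems, "systems\n")
  print(x$distribution$counts)
  invisible(x)
}

#' Two-sided two-sample Kolmogorov-Smirnov comparison of state counts
#'
#' Compares two distributions of per-system stable-state counts with the
#' asymptotic two-sided two-sample KS test. The samples are discrete
#' (k in 1..6) and heavily tied, so the asymptotic p-value is used.
#'
#' @param d1,d2 `state_count_distribution`s (or plain integer sample
#'   vectors).
#' @return a `ks_comparison`: list with `statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_compare <- function(d1, d2) {
  x <- if (inherits(d1, "state_count_distribution")) d1$samples else as.numeric(d1)
  y <- if (inherits(d2, "state_count_distribution")) d2$samples else as.numeric(d2)
  if (!length(x) || !length(y)) stop("empty sample in KS comparison")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n1 = length(x), n2 = length(y)),
            class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat("two-sided two-sample KS: D =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4), " (n =", x$n1, "vs", x$n2, ")\n")
  invisible(x)
}

#' Average pattern-correlation matrix of a set of systems
#'
#' @param results list of `multistability_result`s with equal run counts.
#' @return R x R matrix, the element-wise mean of the sorted
#'   pattern-correlation matrices.
#' @export
average_pattern_correlation <- function(results) {
  if (!length(results)) stop("empty result list")
  dims <- vapply(results, function(r) nrow(r$pattern_correlation), 1L)
  if (length(unique(dims)) != 1L) {
    stop("pattern-correlation matrices differ in size: ",
         paste(unique(dims), collapse = ", "))
  }
  Reduce(`+`, lapply(results, function(r) r$pattern_correlation)) /
    length(results)
}

#' Contrast matrix: real-network minus null-network pattern correlation
#'
#' Subtracts the average pattern-correlation matrix of the null (rewired)
#' surveys from that of the real network. Multistability specific to the real
#' network shows as an aggregation of high values near the main diagonal
#' (runs are sorted by cluster, so within-state correlation concentrates
#' there). A scalar diagnostic — the mean off-diagonal entry within a band of
#' `bandwidth` runs around the diagonal — is attached as attribute
#' `aggregation`; this summary is a convenience of this package, the
#' underlying comparison being visual in origin.
#'
#' @param real_results list of `multistability_result`s for the real network.
#' @param null_results list of `multistability_result`s pooled over nulls.
#' @param bandwidth near-diagonal band half-width in runs; default R/10.
#' @return R x R contrast matrix with attribute `aggregation`.
#' @export
contrast_matrix <- function(real_results, null_results, bandwidth = NULL) {
  m_real <- average_pattern_correlation(real_results)
  m_null <- average_pattern_correlation(null_results)
  if (!all(dim(m_real) == dim(m_null))) {
    stop("dimension mismatch: real ", nrow(m_real), "x", ncol(m_real),
         " vs null ", nrow(m_null), "x", ncol(m_null))
  }
  ctr <- m_real - m_null
  r <- nrow(ctr)
  bw <- bandwidth %||% max(1L, round(r / 10))
  off <- abs(row(ctr) - col(ctr))
  attr(ctr, "aggregation") <- mean(ctr[off > 0 & off <= bw])
  ctr
}

#' Structure-function coupling
#'
#' Pearson correlation between the grand-average synchronisation matrix and
#' the structural weight (GFA) matrix, computed over upper-triangle entries.
#'
#' @param avg_sync symmetric N x N average synchronisation matrix, zero
#'   diagonal.
#' @param weights symmetric N x N structural weight matrix, zero diagonal.
#' @return Pearson correlation coefficient.
#' @export
structure_function_correlation <- function(avg_sync, weights) {
  if (!all(dim(avg_sync) == dim(weights))) {
    stop("dimension mismatch between synchronisation and weight matrices")
  }
  ut <- upper.tri(avg_sync)
  x <- avg_sync[ut]
  y <- weights[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  stats::cor(x, y)
}
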