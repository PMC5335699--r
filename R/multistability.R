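#' Ensemble of synchronisation patterns from random initial conditions
#'
#' Simulates one dynamical system repeatedly from independently seeded random
#' initial phases and stacks the resulting synchronisation patterns row-wise.
#' Because the dynamics are noise free, the pattern reached is a deterministic
#' function of the initial condition: distinct rows witness distinct
#' attracting synchronisation states.
#'
#' @param system a `dynamical_system`.
#' @param n_runs number of random initialisations (100 in the reference
#'   protocol).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param n_steps,burn_in passed to [simulate_phases()].
#' @param mode passed to [sync_pattern()].
#' @return a `pattern_ensemble`: R x P matrix (P = N(N-1)/2) with attributes
#'   `run_seeds` and `n_nodes`.
#' @export
run_ensemble <- function(system, n_runs = 100, seed = NULL,
                         n_steps = 2000, burn_in = 100,
                         mode = c("phase", "signal")) {
  mode <- match.arg(mode)
  if (n_runs < 2) stop("n_runs must be at least 2")
  n <- system$network$n_nodes
  run_seeds <- derive_seeds(seed %||% 0L, n_runs)
  m <- matrix(NA_real_, n_runs, n_pairs(n))
  for (r in seq_len(n_runs)) {
    traj <- tryCatch(
      simulate_phases(system, n_steps = n_steps, seed = run_seeds[r],
                      burn_in = burn_in),
      error = function(e) stop("run ", r, " failed: ", conditionMessage(e)))
    m[r, ] <- sync_pattern(traj, mode = mode)
  }
  structure(m, run_seeds = run_seeds, n_nodes = n, class = "pattern_ensemble")
}

#' Column-wise standardisation
#'
#' Centres each column to mean zero and scales columns of nonzero variance to
#' unit (sample) standard deviation; zero-variance columns become all-zero
#' columns, preserving the column count and pair order. A positive `min_sd`
#' extends the zero-variance rule to columns whose variation is below a
#' resolution floor: standardisation would otherwise amplify measurement
#' noise of near-constant synchronisation indices into apparent cluster
#' structure.
#'
#' @param m numeric matrix with at least 2 rows.
#' @param min_sd columns with sample standard deviation `<= min_sd` are
#'   treated as constant (mapped to zeros). Default 0 (plain standardisation).
#' @return standardised matrix of the same dimension.
#' @export
standardise_columns <- function(m, min_sd = 0) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (nrow(m) < 2) stop("need at least 2 rows to standardise")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s <= min_sd] <- Inf # (near-)constant columns -> centred value / Inf -> 0
  out <- sweep(sweep(m, 2, mu), 2, s, `/`)
  out[, is.infinite(s)] <- 0
  out
}

# Within-cluster error dispersion: sum over clusters of D_r / (2 n_r), with
# D_r the sum of pairwise squared Euclidean distances inside cluster r. For
# squared distances this equals the total within-cluster sum of squares.
within_dispersion <- function(data, labels) {
  tot <- 0
  for (lv in unique(labels)) {
    x <- data[labels == lv, , drop = FALSE]
    if (nrow(x) > 1L) {
      ctr <- colMeans(x)
      tot <- tot + sum(sweep(x, 2, ctr)^2)
    }
  }
  tot
}

kmeans_fit <- function(data, k, nstart = 20) {
  if (k == 1L) {
    return(list(cluster = rep(1L, nrow(data)),
                tot.withinss = within_dispersion(data, rep(1L, nrow(data)))))
  }
  stats::kmeans(data, centers = k, nstart = nstart, iter.max = 100)
}

#' Gap-statistic selection of the k-means cluster count
#'
#' Chooses the number of clusters by comparing the log within-cluster error
#' dispersion `log W_k` of the fitted k-means solutions with its expectation
#' under a structureless reference: `Gap(k) = E*[log W_k] - log W_k`, the
#' expectation estimated by Monte Carlo over `n_reference` datasets drawn
#' uniformly over the per-column range of the data. `W_k` is the sum over
#' clusters of `D_r / (2 n_r)` with `D_r` the within-cluster sum of pairwise
#' squared distances. The default selection is the one-standard-error rule:
#' the smallest k with `Gap(k) >= Gap(k+1) - SE(k+1)`; `rule = "globalmax"`
#' takes the k maximising the gap instead. k is evaluated from 1, so "one
#' cluster" (no multistability) is an explicit outcome.
#'
#' @param data numeric R x P matrix, typically column-standardised.
#' @param k_max largest cluster count evaluated (6 in the reference
#'   protocol; must not exceed R).
#' @param n_reference number of Monte Carlo reference datasets.
#' @param seed RNG seed for the reference draws and k-means restarts.
#' @param nstart k-means restarts per k.
#' @param rule `"firstSEmax"` (one-standard-error, default) or `"globalmax"`.
#' @return list with `optimal_k` and `gap_curve`, a data.frame with columns
#'   `k`, `logW`, `E_logW`, `gap`, `SE`. Degenerate data (all rows identical)
#'   yields `optimal_k = 1` with attribute `degenerate = TRUE`.
#' @export
gap_statistic_k <- function(data, k_max = 6, n_reference = 50, seed = NULL,
                            nstart = 20, rule = c("firstSEmax", "globalmax")) {
  rule <- match.arg(rule)
  data <- as.matrix(data)
  r <- nrow(data)
  if (k_max > r) stop("k_max (", k_max, ") exceeds number of rows (", r, ")")
  if (all(apply(data, 2, function(x) max(x) - min(x)) == 0)) {
    out <- list(optimal_k = 1L, gap_curve = NULL)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ks <- seq_len(k_max)
  with_seed(seed, {
    logW <- vapply(ks, function(k) log(kmeans_fit(data, k, nstart)$tot.withinss), 0)
    lo <- apply(data, 2, min)
    hi <- apply(data, 2, max)
    logWstar <- matrix(NA_real_, n_reference, k_max)
    for (b in seq_len(n_reference)) {
      ref <- matrix(stats::runif(r * ncol(data), min = rep(lo, each = r),
                                 max = rep(hi, each = r)), r, ncol(data))
      logWstar[b, ] <- vapply(
        ks, function(k) log(kmeans_fit(ref, k, nstart)$tot.withinss), 0)
    }
    e_logW <- colMeans(logWstar)
    gap <- e_logW - logW
    se <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / n_reference)
    optimal_k <- if (rule == "globalmax") {
      which.max(gap)
    } else {
      hit <- which(gap[-k_max] >= gap[-1L] - se[-1L])
      if (length(hit)) min(hit) else k_max
    }
    list(optimal_k = as.integer(optimal_k),
         gap_curve = data.frame(k = ks, logW = logW, E_logW = e_logW,
                                gap = gap, SE = se))
  })
}

#' Assess the multistability of a dynamical system
#'
#' The full per-system protocol: simulate `n_runs` randomly initialised runs
#' ([run_ensemble()]), standardise the pattern matrix column-wise, select the
#' cluster count with the gap statistic, refit k-means at the optimum, sort
#' the runs by cluster, and cross-correlate the sorted raw patterns into an
#' R x R Pearson correlation matrix. The system is multistable when at least
#' two pattern clusters are found; a multistable system shows distinct
#' high-correlation blocks along the main diagonal of the pattern-correlation
#' matrix.
#'
#' @param system a `dynamical_system`.
#' @param n_runs random initialisations per system.
#' @param k_max maximum cluster count evaluated.
#' @param n_reference Monte Carlo reference datasets for the gap statistic.
#' @param seed master seed for runs and gap references.
#' @param n_steps,burn_in,mode passed to [run_ensemble()].
#' @param rule gap selection rule, see [gap_statistic_k()].
#' @param index_resolution resolution floor on the index scale: pattern
#'   columns whose across-run standard deviation is below this are treated as
#'   constant before standardisation (see [standardise_columns()]). The
#'   default 0.01 is the sampling resolution of an index estimated from on
#'   the order of 100 stroboscopic wrap events, so runs that reached the same
#'   attractor up to estimation noise count as one state.
#' @return a `multistability_result`: list with `optimal_k`, `labels`
#'   (cluster of each run, original run order), `order` (run permutation
#'   sorting by cluster), `gap_curve`, `pattern_correlation` (R x R, sorted
#'   order), `ensemble`, and logical `multistable`.
#' @export
assess_multistability <- function(system, n_runs = 100, k_max = 6,
                                  n_reference = 50, seed = NULL,
                                  n_steps = 2000, burn_in = 100,
                                  mode = "phase", rule = "firstSEmax",
                                  index_resolution = 0.01) {
  seeds <- derive_seeds(seed %||% 0L, 3L)
  ens <- run_ensemble(system, n_runs = n_runs, seed = seeds[1L],
                      n_steps = n_steps, burn_in = burn_in, mode = mode)
  std <- standardise_columns(ens, min_sd = index_resolution)
  gs <- gap_statistic_k(std, k_max = k_max, n_reference = n_reference,
                        seed = seeds[2L], rule = rule)
  k <- gs$optimal_k
  labels <- if (k == 1L) rep(1L, n_runs) else {
    with_seed(seeds[3L], kmeans_fit(std, k)$cluster)
  }
  ord <- order(labels)
  pc <- row_correlation(unclass(ens)[ord, , drop = FALSE])
  structure(
    list(optimal_k = k, labels = as.integer(labels), order = ord,
         gap_curve = gs$gap_curve, pattern_correlation = pc,
         ensemble = ens, multistable = k >= 2L),
    class = "multistability_result"
  )
}

# Pearson correlation between rows, robust to zero-variance rows: two
# identical constant rows correlate at 1, a constant row against anything
# else at 0 (no linear association measurable).
row_correlation <- function(m) {
  rs <- apply(m, 1, stats::sd)
  rs[is.na(rs)] <- 0 # single-column ensembles: rows have no variance
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(rs == 0)) {
    zv <- which(rs == 0)
    cc[zv, ] <- 0
    cc[, zv] <- 0
    for (a in zv) for (b in zv) {
      if (max(abs(m[a, ] - m[b, ])) < 1e-12) cc[a, b] <- cc[b, a] <- 1
    }
  }
  diag(cc) <- 1
  cc
}

#' @export
print.multistability_result <- function(x, ...) {
  cat("multistability_result: optimal_k =", x$optimal_k,
      if (x$multistable) "(multistable)" else "(single state)", "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a multistability result
#'
#' Writes optimal k, labels and the gap curve as JSON, and the sorted
#' pattern-correlation matrix as delimited text.
#'
#' @param result a `multistability_result`.
#' @param json_path output JSON path.
#' @param correlation_path optional path for the R x R correlation matrix.
#' @return invisibly, `result`.
#' @export
write_multistability <- function(result, json_path, correlation_path = NULL) {
  jsonlite::write_json(
    list(optimal_k = result$optimal_k, multistable = result$multistable,
         labels = result$labels, gap_curve = result$gap_curve),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(correlation_path)) {
    write_matrix_file(result$pattern_correlation, correlation_path)
  }
  invisible(result)
}
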