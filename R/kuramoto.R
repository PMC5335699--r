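#' Sample intrinsic oscillator frequencies
#'
#' Intrinsic node frequencies are drawn uniformly from a band, by default the
#' gamma band (25-75 Hz) associated with global-level cortical computation.
#'
#' @param n number of nodes.
#' @param band_hz length-2 numeric `(low, high)` in Hz, `0 < low <= high`.
#' @param seed integer RNG seed.
#' @return numeric vector of `n` frequencies in Hz.
#' @export
sample_frequencies <- function(n, band_hz = c(25, 75), seed = NULL) {
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] > band_hz[2]) {
    stop("invalid frequency band: need 0 < low <= high, got (",
         paste(band_hz, collapse = ", "), ")")
  }
  with_seed(seed, stats::runif(n, band_hz[1], band_hz[2]))
}

#' Bind a structural network to dynamics parameters
#'
#' Builds the delayed Kuramoto system used throughout: each node n obeys the
#' noise-free Euler update
#' \deqn{\theta_n(t+1) = \theta_n(t) + \omega_n + \sum_p K_{np}
#'   \sin(\theta_p(t - \tau_{np}) - \theta_n(t))}
#' with \eqn{\omega_n = 2\pi f_n \, dt} (rad/step) and integer delays
#' \eqn{\tau_{np} = \mathrm{round}(L_{np} / \texttt{delay\_divisor})} steps.
#' With `dt` = 1 ms the delay rule corresponds to a 20 m/s conduction
#' velocity. The per-edge coupling gain is
#' \eqn{K_{np} = k\, C_{np}\, dt} (optionally divided by N when
#' `normalise_by_n = TRUE`); on the GFA weight scale, the default
#' `k_global = 1000` places the system in an intermediate synchronisation
#' regime where coupling and intrinsic-frequency dispersion are comparable.
#'
#' @param net a `structural_network`.
#' @param freqs_hz intrinsic frequencies, one per node (Hz).
#' @param k_global global coupling scaling factor (dimensionless).
#' @param dt Euler step duration in seconds.
#' @param normalise_by_n divide the coupling gain by N (classical mean-field
#'   normalisation)? Default `FALSE`; see the methods vignette.
#' @param delay_divisor mm of tract per delay step.
#' @return an object of class `dynamical_system` holding the network, `omega`
#'   (rad/step), the coupling matrix `coupling` (rad/step), integer
#'   `delay_steps` and `dt`.
#' @export
build_system <- function(net, freqs_hz, k_global = 1000, dt = 0.001,
                         normalise_by_n = FALSE, delay_divisor = 20) {
  stopifnot(inherits(net, "structural_network"))
  n <- net$n_nodes
  if (length(freqs_hz) != n) {
    stop("freqs_hz has length ", length(freqs_hz), ", expected ", n)
  }
  if (dt <= 0) stop("dt must be positive")
  omega <- 2 * pi * freqs_hz * dt
  coupling <- k_global * net$weights * dt
  if (normalise_by_n) coupling <- coupling / n
  delay_steps <- matrix(as.integer(round(net$lengths / delay_divisor)), n, n)
  delay_steps[net$weights == 0] <- 0L
  diag(delay_steps) <- 0L
  structure(
    list(network = net, omega = omega, freqs_hz = freqs_hz,
         coupling = coupling, delay_steps = delay_steps,
         k_global = k_global, dt = dt, normalise_by_n = normalise_by_n,
         delay_divisor = delay_divisor),
    class = "dynamical_system"
  )
}

#' @export
print.dynamical_system <- function(x, ...) {
  cat("dynamical_system:", x$network$n_nodes, "nodes, k =", x$k_global,
      ", dt =", x$dt, "s, delays", min(x$delay_steps[x$coupling > 0]), "-",
      max(x$delay_steps), "steps\n")
  invisible(x)
}

#' Random initial phases
#'
#' @param n number of nodes.
#' @param seed integer RNG seed.
#' @return `n` phases drawn uniformly on `[0, 2*pi)`.
#' @export
random_phases <- function(n, seed = NULL) {
  with_seed(seed, stats::runif(n, 0, 2 * pi))
}

#' Integrate the delayed Kuramoto system
#'
#' Euler integration of the noise-free delayed Kuramoto update (see
#' [build_system()]). The delay history for t <= 0 is each node's constant
#' initial phase (`history = "constant"`); `history = "random"` fills the
#' history with independent uniform phases instead. Returned phases are
#' unwrapped (cumulative, not reduced mod 2*pi). Identical system and initial
#' phases give an identical trajectory.
#'
#' @param system a `dynamical_system`.
#' @param n_steps number of Euler iterations (default 2000); must exceed the
#'   maximum delay plus `burn_in`.
#' @param init_phases numeric vector of initial phases, or `NULL` to draw
#'   random phases with `seed`.
#' @param seed RNG seed used when `init_phases` is `NULL` (and for a random
#'   history).
#' @param burn_in leading steps flagged as pre-stabilisation transient.
#' @param history `"constant"` or `"random"` pre-t=0 phase history.
#' @return an object of class `phase_trajectory`: list with `phases`
#'   (`n_steps` x N matrix, rad), `init_phases`, `dt`, `burn_in`.
#' @export
simulate_phases <- function(system, n_steps = 2000, init_phases = NULL,
                            seed = NULL, burn_in = 100,
                            history = c("constant", "random")) {
  stopifnot(inherits(system, "dynamical_system"))
  history <- match.arg(history)
  n <- system$network$n_nodes
  if (is.null(init_phases)) init_phases <- random_phases(n, seed)
  if (length(init_phases) != n) {
    stop("init_phases has length ", length(init_phases), ", expected ", n)
  }
  tau <- system$delay_steps
  h <- max(tau)
  if (n_steps <= h + burn_in) {
    stop("n_steps (", n_steps, ") must exceed max delay + burn_in (",
         h + burn_in, ")")
  }
  nrow_buf <- h + 1L + n_steps
  buf <- matrix(0, nrow_buf, n)
  if (history == "constant") {
    buf[seq_len(h + 1L), ] <- rep(init_phases, each = h + 1L)
  } else {
    hist_rows <- with_seed(seed, matrix(stats::runif(h * n, 0, 2 * pi), h, n))
    if (h > 0) buf[seq_len(h), ] <- hist_rows
    buf[h + 1L, ] <- init_phases
  }
  K <- system$coupling
  omega <- system$omega
  # vectorised delayed lookup: element (n,p) of the delayed-phase matrix lives
  # at buffer index (current_row - 1 - tau[n,p]) + nrow_buf*(p-1)
  idx_base <- rep((0:(n - 1L)) * nrow_buf, each = n) - as.vector(tau)
  has_edge <- K > 0
  for (t in seq_len(n_steps)) {
    r <- h + 1L + t
    cur <- buf[r - 1L, ]
    delayed <- matrix(buf[idx_base + (r - 1L)], n, n)
    s <- sin(delayed - cur) # recycles cur down columns: element (n,p) - cur[n]
    nxt <- cur + omega + rowSums(K * s)
    if (!all(is.finite(nxt))) {
      stop("non-finite phase at step ", t, " (nodes ",
           paste(which(!is.finite(nxt)), collapse = ", "), ")")
    }
    buf[r, ] <- nxt
  }
  phases <- buf[(h + 2L):nrow_buf, , drop = FALSE]
  colnames(phases) <- system$network$labels
  structure(
    list(phases = phases, init_phases = init_phases, dt = system$dt,
         burn_in = as.integer(burn_in), n_steps = as.integer(n_steps)),
    class = "phase_trajectory"
  )
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat("phase_trajectory:", nrow(x$phases), "steps x", ncol(x$phases),
      "nodes, dt =", x$dt, "s, burn-in", x$burn_in, "steps\n")
  invisible(x)
}

#' Export a trajectory as delimited text with a JSON header sidecar
#'
#' @param trajectory a `phase_trajectory`.
#' @param path output path for the T x N phase matrix.
#' @param json_path optional sidecar with dt, burn-in and parameters.
#' @param sep field separator.
#' @return invisibly, `trajectory`.
#' @export
write_trajectory <- function(trajectory, path, json_path = NULL, sep = ",") {
  write_matrix_file(trajectory$phases, path, sep)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dt = trajectory$dt, burn_in = trajectory$burn_in,
           n_steps = trajectory$n_steps,
           init_phases = trajectory$init_phases),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(trajectory)
}
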