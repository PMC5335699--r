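#' Instantaneous phase via the analytic signal
#'
#' Maps a real oscillatory signal to its instantaneous phase: the signal is
#' centred, its analytic signal is formed in the frequency domain (negative
#' frequencies zeroed, positive doubled), and the argument of the analytic
#' signal is unwrapped. For `x(t) = sin(theta(t))` with slowly varying
#' instantaneous frequency, the recovered phase differences match the
#' differences of `theta` away from the window edges.
#'
#' @param signal numeric vector of amplitudes.
#' @return numeric vector of unwrapped phases (rad).
#' @export
extract_phase <- function(signal) {
  n <- length(signal)
  if (n < 4L) stop("signal too short for phase extraction")
  x <- signal - mean(signal)
  if (max(abs(x)) == 0) stop("constant signal: instantaneous phase undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  unwrap_phase(Arg(z))
}

# Reference wrap events: instants where the reference completes a full cycle,
# i.e. its unwrapped phase advances by an integer multiple of 2*pi from the
# start of the post-burn-in window. Counting cycles from the window-start
# phase (rather than from absolute zero) makes the event set — and hence the
# index — exactly invariant under a global phase shift. Each crossing is
# located by linear interpolation between the two samples that bracket it;
# `t` is the left sample index, `frac` the sub-step offset, and `level` the
# absolute reference phase at the crossing.
ref_crossings <- function(ref, burn_in = 0L) {
  idx <- (burn_in + 1L):length(ref)
  r0 <- ref[idx[1L]]
  r <- ref[idx] - r0
  tt <- integer(0); frac <- numeric(0); level <- numeric(0)
  m <- floor(r / (2 * pi))
  up <- which(diff(m) >= 1)
  for (t in up) {
    levels <- (m[t] + 1):m[t + 1L]
    lv <- 2 * pi * levels
    f <- (lv - r[t]) / (r[t + 1L] - r[t])
    keep <- f > 0 & f <= 1
    tt <- c(tt, rep.int(t, sum(keep)))
    frac <- c(frac, f[keep])
    level <- c(level, lv[keep] + r0)
  }
  list(t = idx[tt], frac = frac, level = level)
}

# Directional stroboscopic index: the circular mean resultant length of the
# partner's phase relative to the reference, sampled at the reference's
# 2*pi wrap events. With `interpolate = FALSE` the nearest sample is used
# instead of linearly interpolating to the crossing instant.
directional_index <- function(cr, other, interpolate = TRUE) {
  m <- length(cr$t)
  if (m == 0L) {
    stop("no reference wrap events after burn-in; index undefined")
  }
  if (interpolate) {
    oth <- other[cr$t] + cr$frac * (other[cr$t + 1L] - other[cr$t])
    diffs <- oth - cr$level
  } else {
    near <- cr$t + as.integer(cr$frac >= 0.5)
    diffs <- other[near] - cr$level
  }
  Mod(mean(exp(1i * diffs)))
}

#' Stroboscopic pairwise synchronisation index
#'
#' Quantifies phase synchronisation between two oscillators by stroboscopic
#' sampling: every time the reference oscillator completes a cycle (its
#' unwrapped phase crosses a multiple of 2*pi), the concurrent phase of the
#' other oscillator is recorded; the modulus of the average of the
#' corresponding complex unit vectors is the directional index. The two
#' oscillators then reverse roles and the two directional indices are
#' averaged. The index is 1 for any fixed phase lag — including anti-phase
#' locking, which lag-penalising indices miss — and tends to 0 for
#' uncorrelated oscillators whose concurrent phase differences scatter
#' uniformly on the unit circle.
#'
#' @param theta_ref,theta_other unwrapped phase series of equal length (rad).
#' @param burn_in leading samples discarded as pre-stabilisation transient.
#' @param interpolate locate wrap events by linear interpolation (default);
#'   otherwise use the nearest sample.
#' @return symmetric index in `[0, 1]`, with attribute `n_events` giving the
#'   wrap-event counts of the two directions.
#' @export
stroboscopic_index <- function(theta_ref, theta_other, burn_in = 100,
                               interpolate = TRUE) {
  if (length(theta_ref) != length(theta_other)) {
    stop("phase series lengths differ: ", length(theta_ref), " vs ",
         length(theta_other))
  }
  cr1 <- ref_crossings(theta_ref, burn_in)
  cr2 <- ref_crossings(theta_other, burn_in)
  i1 <- directional_index(cr1, theta_other, interpolate)
  i2 <- directional_index(cr2, theta_ref, interpolate)
  structure((i1 + i2) / 2, n_events = c(length(cr1$t), length(cr2$t)))
}

#' Synchronisation pattern of a trajectory
#'
#' Computes the stroboscopic index for every unordered node pair of a
#' trajectory, burn-in discarded, packed in fixed row-major upper-triangle
#' order: (1,2), (1,3), ..., (1,N), (2,3), ... A 34-node trajectory yields
#' 561 pairwise indices. By default indices are computed directly from the
#' Kuramoto phases; `mode = "signal"` renders each node's signal as
#' `sin(theta)` and re-extracts phases through the analytic signal first,
#' replicating an oscilloscope-style pipeline — the two modes agree closely.
#'
#' @param trajectory a `phase_trajectory`.
#' @param mode `"phase"` (direct) or `"signal"` (render and re-extract).
#' @param interpolate see [stroboscopic_index()].
#' @return a `sync_pattern`: numeric vector of length N(N-1)/2 in `[0, 1]`
#'   with attribute `n_nodes`.
#' @export
sync_pattern <- function(trajectory, mode = c("phase", "signal"),
                         interpolate = TRUE) {
  mode <- match.arg(mode)
  ph <- trajectory$phases
  if (mode == "signal") {
    ph <- apply(sin(ph), 2, extract_phase)
  }
  n <- ncol(ph)
  burn <- trajectory$burn_in
  crossings <- lapply(seq_len(n), function(k) ref_crossings(ph[, k], burn))
  po <- pair_order(n)
  out <- numeric(nrow(po))
  for (e in seq_len(nrow(po))) {
    i <- po[e, 1L]; j <- po[e, 2L]
    out[e] <- (directional_index(crossings[[i]], ph[, j], interpolate) +
                 directional_index(crossings[[j]], ph[, i], interpolate)) / 2
  }
  structure(out, n_nodes = n, class = "sync_pattern")
}

#' @export
print.sync_pattern <- function(x, ...) {
  cat("sync_pattern:", length(x), "pairwise indices over",
      attr(x, "n_nodes"), "nodes; mean", signif(mean(unclass(x)), 3), "\n")
  invisible(x)
}

#' Unpack a pattern vector to its symmetric N x N matrix
#'
#' @param pattern a `sync_pattern` (or plain vector with N(N-1)/2 entries).
#' @param n_nodes node count; taken from the pattern attribute if absent.
#' @return symmetric matrix with zero diagonal.
#' @export
pattern_to_matrix <- function(pattern, n_nodes = attr(pattern, "n_nodes")) {
  if (is.null(n_nodes)) stop("n_nodes not supplied and not an attribute")
  if (length(pattern) != n_pairs(n_nodes)) {
    stop("pattern length ", length(pattern), " != N(N-1)/2 = ",
         n_pairs(n_nodes))
  }
  m <- matrix(0, n_nodes, n_nodes)
  po <- pair_order(n_nodes)
  m[po] <- as.numeric(pattern)
  m[po[, 2:1]] <- as.numeric(pattern)
  m
}

#' Average synchronisation matrix of a pattern ensemble
#'
#' Averages pairwise indices over patterns and maps them back to the
#' N x N matrix; auto-correlation (main diagonal) values are set to 0.
#'
#' @param patterns list of `sync_pattern`s (or the rows of an ensemble
#'   matrix), all over the same N.
#' @return symmetric N x N matrix of mean indices, zero diagonal.
#' @export
average_pattern <- function(patterns) {
  if (is.matrix(patterns)) {
    patterns <- lapply(seq_len(nrow(patterns)), function(r) patterns[r, ])
  }
  if (!length(patterns)) stop("empty pattern list")
  len <- lengths(patterns)
  if (length(unique(len)) != 1L) {
    stop("heterogeneous pattern lengths: ", paste(unique(len), collapse = ", "))
  }
  p <- length(patterns[[1L]])
  n <- round((1 + sqrt(1 + 8 * p)) / 2)
  if (n_pairs(n) != p) stop("pattern length ", p, " is not N(N-1)/2 for any N")
  avg <- Reduce(`+`, lapply(patterns, as.numeric)) / length(patterns)
  pattern_to_matrix(avg, n)
}
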