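test_that("analytic-signal phase extraction recovers sinusoid phases", {
  t <- 0:999
  ph <- extract_phase(cos(2 * pi * 0.05 * t))
  freq <- diff(ph)[100:900] / (2 * pi) # instantaneous frequency, cycles/step
  expect_equal(mean(freq), 0.05, tolerance = 1e-3)
  expect_lt(max(abs(freq - 0.05)), 0.005)

  # two sinusoids at a fixed offset phi show phase difference phi
  phi <- 0.8
  p1 <- extract_phase(sin(2 * pi * 0.04 * t))
  p2 <- extract_phase(sin(2 * pi * 0.04 * t + phi))
  expect_equal(mean((p2 - p1)[100:900]), phi, tolerance = 0.01)

  expect_error(extract_phase(rep(1, 100)), "constant")
})

test_that("phase-locked pairs score 1 at any lag, including anti-phase", {
  for (phi in c(0.3, pi / 2, pi, 4.9)) {
    tr <- uniform_trajectory(c(0.3, 0.3), init = c(0, phi))
    idx <- stroboscopic_index(tr$phases[, 1], tr$phases[, 2], burn_in = 100)
    expect_equal(as.numeric(idx), 1, tolerance = 1e-12)
  }
})

test_that("free-running incommensurate pairs score near 0", {
  tr <- uniform_trajectory(c(0.3, 0.3 * sqrt(2)), n_steps = 20000)
  idx <- stroboscopic_index(tr$phases[, 1], tr$phases[, 2], burn_in = 100)
  m <- min(attr(idx, "n_events"))
  expect_gt(m, 500)
  expect_lt(as.numeric(idx), 1 / sqrt(m))
})

test_that("symmetric stroboscopic samples cancel to a zero directional index", {
  cr <- list(t = 1:8, frac = rep(1, 8), level = 2 * pi * (1:8))
  other <- numeric(10)
  other[2:9] <- 2 * pi * (1:8) + rep(c(0, pi / 2, pi, 3 * pi / 2), 2)
  # directional index evaluates the partner at the wrap instants t + frac
  got <- strobosync:::directional_index(cr, other, interpolate = TRUE)
  expect_equal(got, 0, tolerance = 1e-12)
})

test_that("index matches a brute-force oracle on irregular phase pairs", {
  # independent enumeration of wrap events and explicit complex averaging
  oracle <- function(ref, oth, burn_in) {
    one_dir <- function(ref, oth) {
      ref <- ref[(burn_in + 1):length(ref)]
      oth <- oth[(burn_in + 1):length(oth)]
      rel <- ref - ref[1] # cycles counted from the window-start phase
      zs <- complex(0)
      for (t in seq_len(length(ref) - 1)) {
        for (mlt in seq(ceiling(min(rel) / (2 * pi)),
                        floor(max(rel) / (2 * pi)))) {
          lv <- 2 * pi * mlt
          if (rel[t] < lv && rel[t + 1] >= lv) {
            f <- (lv - rel[t]) / (rel[t + 1] - rel[t])
            zs <- c(zs, exp(1i * ((oth[t] + f * (oth[t + 1] - oth[t])) -
                                    (lv + ref[1]))))
          }
        }
      }
      Mod(mean(zs))
    }
    (one_dir(ref, oth) + one_dir(oth, ref)) / 2
  }
  set.seed(31)
  for (rep in 1:5) {
    ref <- cumsum(runif(400, 0.05, 0.5))
    oth <- cumsum(runif(400, 0.05, 0.5))
    got <- stroboscopic_index(ref, oth, burn_in = 20)
    expect_equal(as.numeric(got), oracle(ref, oth, 20), tolerance = 1e-12)
  }
})

test_that("index is symmetric in its arguments and bounded", {
  set.seed(77)
  ref <- cumsum(runif(500, 0.1, 0.4))
  oth <- cumsum(runif(500, 0.1, 0.4))
  a <- stroboscopic_index(ref, oth, burn_in = 50)
  b <- stroboscopic_index(oth, ref, burn_in = 50)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-14)
  expect_gte(as.numeric(a), 0)
  expect_lte(as.numeric(a), 1)
  expect_error(stroboscopic_index(ref, oth[-1]), "lengths differ")
})

test_that("sync_pattern packs all pairs and handles locked trajectories", {
  net <- fixture_net_8()
  sys <- build_system(net, sample_frequencies(8, seed = 2))
  tr <- simulate_phases(sys, seed = 3)
  sp <- sync_pattern(tr)
  expect_length(sp, 28)
  expect_true(all(sp >= 0 & sp <= 1))

  # a globally locked trajectory (identical frequencies, strong coupling)
  locked <- uniform_trajectory(rep(0.3, 4), init = c(0, 1, 2, 3))
  lp <- sync_pattern(locked)
  expect_equal(as.numeric(lp), rep(1, 6), tolerance = 1e-12)

  # the index of a node with itself is 1 (auto-correlation diagnostic)
  self <- stroboscopic_index(tr$phases[, 1], tr$phases[, 1], burn_in = 100)
  expect_equal(as.numeric(self), 1, tolerance = 1e-12)
})

test_that("direct-phase and rendered-signal pathways agree", {
  net <- fixture_net_34()
  sys <- build_system(net, sample_frequencies(34, seed = 6))
  tr <- simulate_phases(sys, seed = 7)
  direct <- sync_pattern(tr, mode = "phase")
  hilbert <- sync_pattern(tr, mode = "signal")
  expect_lt(max(abs(unclass(direct) - unclass(hilbert))), 0.02)
})

test_that("average_pattern maps means back to a zero-diagonal matrix", {
  p1 <- structure(rep(0, 6), n_nodes = 4, class = "sync_pattern")
  p2 <- structure(rep(1, 6), n_nodes = 4, class = "sync_pattern")
  avg <- average_pattern(list(p1, p2))
  expect_equal(diag(avg), rep(0, 4))
  expect_equal(avg[upper.tri(avg)], rep(0.5, 6))
  expect_identical(avg, t(avg))

  single <- structure(1:6 / 10, n_nodes = 4, class = "sync_pattern")
  expect_equal(average_pattern(list(single)), pattern_to_matrix(single))
  expect_error(average_pattern(list(p1, structure(rep(1, 10), n_nodes = 5))),
               "heterogeneous")
})
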