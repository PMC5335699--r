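test_that("frequency sampling respects the band and the seed", {
  f <- sample_frequencies(34, c(25, 75), seed = 1)
  expect_length(f, 34)
  expect_true(all(f >= 25 & f <= 75))
  expect_identical(f, sample_frequencies(34, c(25, 75), seed = 1))
  expect_equal(sample_frequencies(5, c(50, 50), seed = 2), rep(50, 5))
  expect_error(sample_frequencies(5, c(75, 25)), "band")
  expect_error(sample_frequencies(5, c(0, 25)), "band")
})

test_that("unit conversion and delay quantisation follow the protocol", {
  w <- matrix(c(0, 0.1, 0.1, 0), 2)
  mk <- function(len) {
    l <- matrix(c(0, len, len, 0), 2)
    build_system(structural_network(w, l), c(50, 50))
  }
  sys <- mk(50)
  expect_equal(sys$omega, rep(0.1 * pi, 2))
  expect_equal(sys$delay_steps[1, 2], 2) # 50/20 = 2.5 rounds to even
  expect_equal(mk(49)$delay_steps[1, 2], 2)
  expect_equal(mk(51)$delay_steps[1, 2], 3)
  # absent edges contribute neither delay nor coupling
  w3 <- matrix(0, 3, 3); w3[1, 2] <- w3[2, 1] <- 0.1; w3[2, 3] <- w3[3, 2] <- 0.1
  l3 <- w3 * 400
  sys3 <- build_system(structural_network(w3, l3), rep(50, 3))
  expect_equal(sys3$delay_steps[1, 3], 0)
  expect_equal(sys3$coupling[1, 3], 0)
})

test_that("uncoupled oscillators recover their frequencies exactly", {
  net <- fixture_net_8()
  f <- sample_frequencies(8, seed = 3)
  sys <- build_system(net, f, k_global = 0)
  tr <- simulate_phases(sys, n_steps = 500, seed = 4)
  increments <- (tr$phases[500, ] - tr$phases[1, ]) / 499
  expect_equal(unname(increments), unname(sys$omega), tolerance = 1e-12)
})

test_that("two identical oscillators lock to the zero-lag fixed point", {
  w <- matrix(c(0, 0.1, 0.1, 0), 2)
  l <- matrix(c(0, 10, 10, 0), 2) # 10 mm -> zero delay after rounding
  net <- structural_network(w, l)
  sys <- build_system(net, c(50, 50), k_global = 1000)
  expect_equal(max(sys$delay_steps), 0)
  tr <- simulate_phases(sys, n_steps = 2000, init_phases = c(0, 1.5))
  delta <- tr$phases[, 1] - tr$phases[, 2]
  # phase difference contracts towards the delta = 0 fixed point of the map
  expect_lt(abs(delta[2000]), 1e-8)
  expect_true(all(abs(delta[-1]) <= abs(delta[-2000]) + 1e-12))
  # at the fixed point both nodes advance at the common omega
  expect_equal(unname(tr$phases[2000, 1] - tr$phases[1999, 1]), sys$omega[1],
               tolerance = 1e-6)
})

test_that("a global phase shift translates the trajectory rigidly", {
  net <- fixture_net_8()
  sys <- build_system(net, sample_frequencies(8, seed = 5))
  init <- random_phases(8, seed = 6)
  tr1 <- simulate_phases(sys, n_steps = 800, init_phases = init)
  tr2 <- simulate_phases(sys, n_steps = 800, init_phases = init + 1.234)
  expect_equal(tr2$phases, tr1$phases + 1.234, tolerance = 1e-9)
  s1 <- sync_pattern(tr1)
  s2 <- sync_pattern(tr2)
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-9)
})

test_that("simulation is deterministic and validates its inputs", {
  net <- fixture_net_8()
  sys <- build_system(net, sample_frequencies(8, seed = 7))
  a <- simulate_phases(sys, n_steps = 300, seed = 8)
  b <- simulate_phases(sys, n_steps = 300, seed = 8)
  expect_identical(a$phases, b$phases)
  expect_error(simulate_phases(sys, n_steps = 50, seed = 1, burn_in = 100),
               "exceed")
  expect_error(build_system(net, c(50, 50)), "length")
})

test_that("default-scale trajectories are stationary after burn-in", {
  net <- fixture_net_34()
  sys <- build_system(net, sample_frequencies(34, seed = 1))
  tr <- simulate_phases(sys, n_steps = 3900, seed = 4)
  half1 <- structure(list(phases = tr$phases[1:2000, ], burn_in = 100L,
                          dt = sys$dt), class = "phase_trajectory")
  half2 <- structure(list(phases = tr$phases[2001:3900, ], burn_in = 0L,
                          dt = sys$dt), class = "phase_trajectory")
  d <- abs(unclass(sync_pattern(half1)) - unclass(sync_pattern(half2)))
  expect_lt(max(d), 0.02)
})
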