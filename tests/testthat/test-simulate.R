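# Synthetic-data generators: determinism, zero-temperature limits,
# equipartition, Boltzmann consistency and the pulling-center schedule.

test_that("Langevin dynamics is seed-deterministic and stays put at T = 0", {
  h <- harmonicPotential(k = 2, center = 0.5)
  cold <- thermostatParams(temperature = 0, seed = 4, steps = 500)
  tr <- simulateLangevin(h, cold, start = 0.5)
  expect_true(all(tr@coords[, 1] == 0.5))
  expect_equal(length(tr@times), 501L)        # start frame + one per step
  warm <- thermostatParams(temperature = 300, seed = 9, steps = 2000)
  t1 <- simulateLangevin(h, warm, start = 0)
  t2 <- simulateLangevin(h, warm, start = 0)
  expect_identical(t1@coords, t2@coords)
  expect_identical(t1@energies, t2@energies)
})

test_that("harmonic-well Langevin variance satisfies equipartition within 5%", {
  k <- 2
  tr <- simulateLangevin(harmonicPotential(k = k),
                         thermostatParams(temperature = 300, friction = 1,
                                          timeStep = 0.01, seed = 21,
                                          steps = 1000000L),
                         start = 0)
  expect_equal(var(tr@coords[, 1]), kBoltzmann * 300 / k, tolerance = 0.05)
})

test_that("a flat-bottom restraint containing the support leaves frames identical", {
  h <- harmonicPotential(k = 5)
  params <- thermostatParams(temperature = 300, seed = 13, steps = 20000)
  free <- simulateLangevin(h, params, start = 0)
  wide <- flatBottomRestraint("rc1", -50, 50, stiffness = 100)
  held <- simulateLangevin(h, params, start = 0, restraints = list(wide))
  expect_identical(free@coords, held@coords)
})

test_that("the integrator reports divergence with the failing step", {
  stiff <- harmonicPotential(k = 1e4)
  bad <- thermostatParams(temperature = 300, friction = 1, timeStep = 0.01,
                          seed = 1, steps = 1000)   # dt*k/gamma = 100: unstable
  expect_error(simulateLangevin(stiff, bad, start = 1), "unstable at step")
})

test_that("Metropolis sampling matches the closed-form harmonic marginal", {
  k <- 2
  tb <- boltzmannSamples(harmonicPotential(k = k), temperature = 300, n = 1e5,
                         seed = 5, stepSd = 1.3)
  x <- rcValues(tb)[, 1]
  sigma <- sqrt(kBoltzmann * 300 / k)
  ks <- suppressWarnings(ks.test(x, "pnorm", mean = 0, sd = sigma))
  expect_gt(ks$p.value, 0.01)
  # energies column is the exact potential at the coordinates
  expect_equal(sampleEnergies(tb), evalPotential(harmonicPotential(k = k), x))
  expect_equal(nSamples(boltzmannSamples(harmonicPotential(), n = 1, seed = 2)), 1L)
  expect_error(boltzmannSamples(harmonicPotential(), temperature = -10, n = 5),
               "positive")
  t1 <- boltzmannSamples(harmonicPotential(), n = 500, seed = 77)
  t2 <- boltzmannSamples(harmonicPotential(), n = 500, seed = 77)
  expect_identical(rcValues(t1), rcValues(t2))
})

test_that("negative log-histogram of 1D Boltzmann samples recovers the potential", {
  k <- 2
  h <- harmonicPotential(k = k)
  tb <- boltzmannSamples(h, temperature = 300, n = 1e6, seed = 6, stepSd = 1.3)
  x <- rcValues(tb)[, 1]
  breaks <- seq(min(x), max(x), length.out = 81)
  cnt <- hist(x, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- cnt >= 500
  fe <- -kBoltzmann * 300 * log(cnt[keep])
  u <- evalPotential(h, centers[keep])
  dev <- (fe - mean(fe)) - (u - mean(u))     # additive constant removed
  expect_lt(max(abs(dev)), 0.3)
})

test_that("pulling-center schedule follows hold / constant velocity / hold", {
  flat <- polynomialPotential(0)
  # the reference separation protocol: 2.5 A/ns over 13 ns moves 32.5 A
  params <- thermostatParams(temperature = 0, friction = 5, timeStep = 0.5,
                             seed = 1, steps = 1L)
  tr <- simulateSMD(flat, params, spring = 5, startCenter = 0, velocity = 2.5,
                    duration = 13, hold = 0.1, stride = 200)
  expect_equal(max(tr@center) - tr@center[1], 32.5)
  expect_equal(max(tr@times), 13.2, tolerance = 1e-9)
  # holds are flat at both ends
  expect_true(all(tr@center[tr@times <= 0.1 + 1e-12] == 0))
  expect_true(all(tr@center[tr@times >= 13.1 - 1e-12] == 32.5))
  # zero velocity keeps the center constant
  still <- simulateSMD(flat, params, spring = 5, startCenter = 2, velocity = 0,
                       duration = 1, stride = 100)
  expect_true(all(still@center == 2))
  # stiff spring, T = 0, flat potential: the coordinate tracks the center
  tight <- simulateSMD(flat, thermostatParams(temperature = 0, friction = 100,
                                              timeStep = 0.0005, seed = 1,
                                              steps = 1L),
                       spring = 1e4, startCenter = 0, velocity = 1,
                       duration = 0.5, stride = 100)
  lag <- tight@center - tight@coord
  expect_lt(max(abs(lag)), 1e-3)
  # determinism
  warm <- thermostatParams(temperature = 300, friction = 5, timeStep = 0.01,
                           seed = 31, steps = 1L)
  s1 <- simulateSMD(harmonicPotential(), warm, 50, 0, 2, 0.1, stride = 5)
  s2 <- simulateSMD(harmonicPotential(), warm, 50, 0, 2, 0.1, stride = 5)
  expect_identical(s1@coord, s2@coord)
})

test_that("two-state distance series obeys its generator contract", {
  const <- twoStateDistanceSeries(2.5, 7.9, noiseSd = 0, totalFrames = 100, seed = 1)
  expect_true(all(const@distances == 2.5))
  step <- twoStateDistanceSeries(2.5, 7.9, noiseSd = 0, switchTimes = 51,
                                 totalFrames = 100, seed = 1)
  expect_true(all(step@distances[1:50] == 2.5))
  expect_true(all(step@distances[51:100] == 7.9))
  # per-segment means recover the state means within 3 sd / sqrt(n)
  noisy <- twoStateDistanceSeries(2.5, 7.9, noiseSd = 0.3, switchTimes = 5001,
                                  totalFrames = 10000, seed = 8)
  tol <- 3 * 0.3 / sqrt(5000)
  expect_lt(abs(mean(noisy@distances[1:5000]) - 2.5), tol)
  expect_lt(abs(mean(noisy@distances[5001:10000]) - 7.9), tol)
  a1 <- twoStateDistanceSeries(3, 8, 0.2, c(10, 60), 100, seed = 3)
  a2 <- twoStateDistanceSeries(3, 8, 0.2, c(10, 60), 100, seed = 3)
  expect_identical(a1@distances, a2@distances)
})
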