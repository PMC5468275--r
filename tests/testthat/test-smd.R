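# Pulling forces, accumulated work and the Jarzynski estimator.

# hand-built trace with a prescribed coordinate lag behind a linear ramp
mkTrace <- function(times_ns, coord, center0, velocity, hold, ramp, spring) {
  center <- felscape:::.centerSchedule(times_ns, center0, velocity, hold, ramp)
  new("SMDTrace", times = times_ns, coord = coord, center = center,
      spring = spring, velocity = velocity, holdDuration = hold,
      rampDuration = ramp)
}

test_that("pulling force is spring times lag", {
  t <- seq(0, 1, by = 0.01)
  ramp <- mkTrace(t, coord = felscape:::.centerSchedule(t, 0, 2, 0, 1),
                  center0 = 0, velocity = 2, hold = 0, ramp = 1, spring = 5)
  expect_true(all(pullingForce(ramp) == 0))
  lag1 <- mkTrace(t, coord = felscape:::.centerSchedule(t, 0, 2, 0, 1) - 1,
                  center0 = 0, velocity = 2, hold = 0, ramp = 1, spring = 5)
  expect_true(all(pullingForce(lag1) == 5))
  lagSeq <- mkTrace(c(0, 1, 2), coord = c(0, 0.5, 1), center0 = 0, velocity = 1,
                    hold = 0, ramp = 2, spring = 2)
  expect_equal(pullingForce(lagSeq), c(0, 1, 2))
})

test_that("accumulated work integrates force over center displacement", {
  t <- seq(0, 1, by = 0.001)
  # zero force: zero work
  zero <- mkTrace(t, coord = felscape:::.centerSchedule(t, 0, 3, 0, 1),
                  center0 = 0, velocity = 3, hold = 0, ramp = 1, spring = 10)
  expect_true(all(accumulateWork(zero)@work == 0))
  # constant force f over displacement d: W = f * d, trapezoid exact
  lag <- mkTrace(t, coord = felscape:::.centerSchedule(t, 0, 3, 0, 1) - 0.4,
                 center0 = 0, velocity = 3, hold = 0, ramp = 1, spring = 10)
  w <- accumulateWork(lag)
  expect_equal(w@work[length(w@work)], 10 * 0.4 * 3, tolerance = 1e-12)
  # holds contribute zero work
  t2 <- seq(0, 1.2, by = 0.001)
  held <- mkTrace(t2, coord = felscape:::.centerSchedule(t2, 0, 3, 0.1, 1) - 0.4,
                  center0 = 0, velocity = 3, hold = 0.1, ramp = 1, spring = 10)
  wh <- accumulateWork(held)
  inHold <- t2 <= 0.1 + 1e-12
  expect_true(all(wh@work[inHold] == 0))
  # additivity: splitting at any frame and summing reproduces the total
  set.seed(9)
  coordN <- felscape:::.centerSchedule(t, 0, 3, 0, 1) - runif(length(t), 0, 0.5)
  noisy <- mkTrace(t, coordN, 0, 3, 0, 1, spring = 7)
  wn <- accumulateWork(noisy)@work
  for (cut in c(2, 500, 999)) {
    f <- pullingForce(noisy); ctr <- noisy@center
    w1 <- sum(0.5 * (f[2:cut] + f[1:(cut - 1)]) * diff(ctr[1:cut]))
    w2 <- sum(0.5 * (f[(cut + 1):length(f)] + f[cut:(length(f) - 1)]) *
                diff(ctr[cut:length(f)]))
    expect_equal(w1 + w2, wn[length(wn)], tolerance = 1e-10)
  }
})

test_that("Jarzynski estimate obeys its closed forms and invariants", {
  kbt <- kBoltzmann * 300
  t <- seq(0, 1, by = 0.01)
  mkWork <- function(lagf) accumulateWork(
    mkTrace(t, felscape:::.centerSchedule(t, 0, 2, 0, 1) - lagf(t),
            0, 2, 0, 1, spring = 3))
  # identical trajectories: dG equals that work profile; zero-width CI
  ws <- replicate(4, mkWork(function(tt) 0.3), simplify = FALSE)
  res <- jarzynskiEstimate(ws, 300)
  expect_equal(res@dg, felscape:::.workOnGrid(ws[[1]], res@displacement))
  expect_equal(res@dg[1], 0)
  # single trajectory: dG == W
  one <- jarzynskiEstimate(ws[[1]], 300)
  expect_equal(one@dg, felscape:::.workOnGrid(ws[[1]], one@displacement))
  # two-term closed form: works {0, kbt log 4} -> dG = kbt log(1.6)
  wA <- new("WorkSeries", displacement = c(0, 1), work = c(0, 0))
  wB <- new("WorkSeries", displacement = c(0, 1), work = c(0, kbt * log(4)))
  r2 <- jarzynskiEstimate(list(wA, wB), 300, spacing = 1)
  expect_equal(r2@dg[2], kbt * log(1.6), tolerance = 1e-12)
  # Jensen bound and order invariance on random ensembles
  set.seed(33)
  for (r in 1:10) {
    ens <- lapply(1:6, function(i) mkWork(function(tt) runif(1, 0, 0.5) * tt))
    rr <- jarzynskiEstimate(ens, 300)
    mw <- meanWorkProfile(ens)
    expect_true(all(rr@dg <= mw$meanWork + 1e-9))
    rp <- jarzynskiEstimate(rev(ens), 300)
    expect_equal(rp@dg, rr@dg, tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are deterministic, contain the estimate and tighten with N", {
  t <- seq(0, 1, by = 0.01)
  mkWork <- function(seed) {
    set.seed(seed)
    lag <- 0.2 + 0.1 * abs(rnorm(1))
    accumulateWork(mkTrace(t, felscape:::.centerSchedule(t, 0, 2, 0, 1) - lag,
                           0, 2, 0, 1, spring = 3))
  }
  ens <- lapply(1:12, mkWork)
  b1 <- jarzynskiBootstrap(ens, 300, replicates = 100, seed = 5)
  b2 <- jarzynskiBootstrap(ens, 300, replicates = 100, seed = 5)
  expect_identical(b1@ciLow, b2@ciLow)
  expect_true(all(b1@ciLow <= b1@dg + 1e-9 & b1@dg <= b1@ciHigh + 1e-9))
  # identical trajectories: zero-width interval
  same <- replicate(5, mkWork(1), simplify = FALSE)
  bs <- jarzynskiBootstrap(same, 300, replicates = 50, seed = 2)
  expect_equal(bs@ciHigh - bs@ciLow, rep(0, length(bs@ciLow)))
  # width shrinks with ensemble size
  ensBig <- lapply(1:48, mkWork)
  bBig <- jarzynskiBootstrap(ensBig, 300, replicates = 100, seed = 5)
  last <- length(b1@ciLow)
  expect_lt(bBig@ciHigh[last] - bBig@ciLow[last], b1@ciHigh[last] - b1@ciLow[last])
})

test_that("pulling in a flat potential yields zero free-energy change", {
  flat <- polynomialPotential(0)
  params <- function(seed) thermostatParams(temperature = 300, friction = 1,
                                            timeStep = 0.01, seed = seed, steps = 1L)
  ens <- lapply(1:50, function(i)
    accumulateWork(simulateSMD(flat, params(i), spring = 50, startCenter = 0,
                               velocity = 2, duration = 1, stride = 5)))
  res <- jarzynskiEstimate(ens, 300)
  sdBoot <- jarzynskiBootstrapSD(ens, 300, replicates = 100, seed = 3)
  last <- length(res@dg)
  expect_lt(abs(res@dg[last]), 3 * sdBoot[last])
})

test_that("the mean-work gap closes towards the quasi-static limit", {
  h <- harmonicPotential(k = 2)
  pull <- function(v, seed) accumulateWork(
    simulateSMD(h, thermostatParams(temperature = 300, friction = 20,
                                    timeStep = 0.005, seed = seed, steps = 1L),
                spring = 200, startCenter = 0, velocity = v, duration = 1.5 / v,
                stride = 10))
  gaps <- vapply(c(6, 1.5, 0.375), function(v) {
    ens <- lapply(1:20, function(i) pull(v, 1000 * v + i))
    res <- jarzynskiEstimate(ens, 300)
    mw <- meanWorkProfile(ens)
    last <- length(res@dg)
    mw$meanWork[last] - res@dg[last]
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("condition comparison returns pointwise and final differences", {
  grid <- seq(0, 2, by = 0.1)
  mkRes <- function(dg) new("JarzynskiResult", displacement = grid, dg = dg,
                            ciLow = rep(NA_real_, length(grid)),
                            ciHigh = rep(NA_real_, length(grid)),
                            nTraj = 5L, temperature = 300)
  a <- mkRes(grid^2)
  expect_equal(compareConditions(a, a)$ddg, rep(0, length(grid)))
  # conditions offset by a constant beyond the origin (both profiles keep
  # the exact dG(0) = 0 anchor)
  b <- mkRes(grid^2 + 3 * (grid > 0))
  cmp <- compareConditions(b, a)
  expect_equal(cmp$ddg[-1], rep(3, length(grid) - 1))
  expect_equal(cmp$final, 3)
  short <- new("JarzynskiResult", displacement = grid[1:5], dg = grid[1:5],
               ciLow = rep(NA_real_, 5), ciHigh = rep(NA_real_, 5),
               nTraj = 2L, temperature = 300)
  expect_error(compareConditions(a, short), "grids")
})
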