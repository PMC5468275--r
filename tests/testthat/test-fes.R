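# Free-energy estimation: binning conventions, the per-bin partition
# function, LOESS smoothing against a dense oracle, window tails and the
# bootstrap error map.

test_that("binning follows the half-open convention with edge ties upward", {
  tb <- energySampleTable(rc1 = c(0, 0, 2, 2), rc2 = c(0, 2, 0, 2),
                          energy = rep(1, 4))
  g <- gridSpec(c(0, 0), c(2, 2), c(2, 2))
  b <- binSamples(tb, g)
  expect_equal(as.numeric(b$occupancy), c(1, 1, 1, 1))
  expect_identical(b$outOfRange, 0L)
  # a row exactly on the interior edge (x = 1) goes to the higher bin
  edge <- energySampleTable(rc1 = 1, rc2 = 0.5, energy = 0)
  be <- binSamples(edge, g)
  expect_equal(which(be$occupancy == 1, arr.ind = TRUE)[1, ], c(row = 2, col = 1))
  # out-of-range rows are dropped with a warning and counted
  oob <- energySampleTable(rc1 = c(0.5, 9), rc2 = c(0.5, 0.5), energy = c(0, 0))
  expect_warning(bo <- binSamples(oob, g), "out-of-range")
  expect_identical(bo$outOfRange, 1L)
  expect_error(suppressWarnings(
    binSamples(energySampleTable(rc1 = 9, rc2 = 9, energy = 0), g)), "outside")
  # occupancy accounts for every in-range row
  set.seed(3)
  big <- energySampleTable(rc1 = runif(5000, -1, 3), rc2 = runif(5000, -1, 3),
                           energy = rnorm(5000))
  expect_warning(bb <- binSamples(big, g))
  expect_equal(sum(bb$occupancy) + bb$outOfRange, 5000L)
})

test_that("per-bin free energy obeys its closed forms, bounds and limits", {
  kbt <- kBoltzmann * 300
  expect_equal(binFreeEnergy(rep(2.5, 10), 300), 2.5)
  # {0, very large}: mean Boltzmann factor 1/2
  expect_equal(binFreeEnergy(c(0, 1e6), 300), kbt * log(2))
  # stable for spreads of hundreds of kcal/mol and order-invariant
  e <- c(700, 0.3, 505, 0.1, 650)
  expect_true(is.finite(binFreeEnergy(e, 300)))
  expect_identical(binFreeEnergy(e, 300), binFreeEnergy(rev(e), 300))
  # bounds E_min <= dG <= E_min + kBT log N, over random ensembles
  set.seed(7)
  for (r in 1:50) {
    en <- rnorm(sample(1:40, 1), sd = 3)
    v <- binFreeEnergy(en, 300)
    expect_gte(v, min(en) - 1e-12)
    expect_lte(v, min(en) + kbt * log(length(en)) + 1e-12)
  }
  # high-temperature limit: arithmetic mean within 1%
  en <- c(0.2, 1.1, 0.7, 2.0)
  expect_equal(binFreeEnergy(en, 1e7), mean(en), tolerance = 0.01)
  expect_error(binFreeEnergy(numeric(0), 300), "at least one")
})

test_that("LOESS smoothing reproduces polynomials and matches the dense oracle", {
  set.seed(15)
  x <- sort(runif(40, 0, 3))
  lin <- 2 - 0.5 * x
  expect_equal(loessSmooth(x, lin, span = 0.4, degree = 1L), lin, tolerance = 1e-9)
  quad <- 1 + x - 0.3 * x^2
  expect_equal(loessSmooth(x, quad, span = 0.5, degree = 2L), quad, tolerance = 1e-9)
  # independent brute-force local regression, 1D and 2D
  y <- sin(2 * x) + rnorm(40, sd = 0.1)
  expect_equal(loessSmooth(x, y, span = 0.5, degree = 1L),
               bruteLocalRegression(x, y, 0.5, 1L), tolerance = 1e-8)
  x2 <- cbind(runif(60), runif(60))
  y2 <- cos(3 * x2[, 1]) * x2[, 2] + rnorm(60, sd = 0.05)
  expect_equal(loessSmooth(x2, y2, span = 0.45, degree = 2L),
               bruteLocalRegression(x2, y2, 0.45, 2L), tolerance = 1e-8)
  expect_error(loessSmooth(1:4, 1:4, span = 0.3, degree = 2L), "too few")
})

test_that("surface estimation is shift- and permutation-invariant and zero-referenced", {
  mb <- muellerBrownPotential()
  tb <- boltzmannSamples(mb, n = 20000, seed = 12, stepSd = 0.15)
  g <- defaultGrid(tb, bins = 24)
  s1 <- estimateFes2d(tb, g)
  expect_equal(min(dgValues(s1), na.rm = TRUE), 0)
  expect_equal(sum(occupancy(s1)) + s1@outOfRange, nSamples(tb))
  # energy shift drops out after zero-referencing
  shifted <- energySampleTable(rc1 = rcValues(tb)[, 1], rc2 = rcValues(tb)[, 2],
                               energy = sampleEnergies(tb) + 123.456)
  s2 <- estimateFes2d(shifted, g)
  expect_equal(dgValues(s2), dgValues(s1), tolerance = 1e-9)
  # row order is irrelevant
  set.seed(2)
  perm <- sample(nSamples(tb))
  s3 <- estimateFes2d(energySampleTable(rc1 = rcValues(tb)[perm, 1],
                                        rc2 = rcValues(tb)[perm, 2],
                                        energy = sampleEnergies(tb)[perm]), g)
  expect_equal(dgValues(s3), dgValues(s1), tolerance = 1e-12)
  # single occupied bin with smoothing disabled: value 0, rest missing
  one <- energySampleTable(rc1 = rep(0.05, 3), rc2 = rep(0.05, 3),
                           energy = c(1, 2, 3))
  g1 <- gridSpec(c(0, 0), c(1, 1), c(4, 4))
  s4 <- estimateFes2d(one, g1, smooth = NULL)
  expect_equal(sum(is.finite(dgValues(s4))), 1L)
  expect_equal(dgValues(s4)[1, 1], 0)
})

test_that("1D profile recovers the double-well barrier and degenerate cases", {
  dw <- doubleWellPotential(height = 3)
  tb <- boltzmannSamples(dw, n = 2e5, seed = 2, stepSd = 0.4)
  pr <- estimateProfile1d(tb)
  expect_equal(profileBarrier(pr)$barrier, 3, tolerance = 0.5)
  # constant-energy samples: flat profile at 0
  flat <- energySampleTable(rc1 = seq(0, 1, length.out = 200),
                            energy = rep(4.2, 200))
  pf <- estimateProfile1d(flat, gridSpec(0, 1, 10), smooth = NULL)
  expect_equal(pf@dg, rep(0, length(pf@dg)), tolerance = 1e-9)
  # permutation invariance
  set.seed(5)
  perm <- sample(nSamples(tb))
  pr2 <- estimateProfile1d(energySampleTable(rc1 = rcValues(tb)[perm, 1],
                                             energy = sampleEnergies(tb)[perm]))
  expect_equal(pr2@dg, pr@dg, tolerance = 1e-12)
})

test_that("estimation error on well-occupied bins does not grow with sample size", {
  # convergence is judged on a fixed bin set (the bins already well
  # occupied in the smaller run) so that the larger run is not penalized
  # for newly qualifying, harder outskirt bins
  mb <- muellerBrownPotential()
  g <- NULL; occRef <- NULL
  maxErr <- vapply(c(1e5, 1e6), function(n) {
    tb <- boltzmannSamples(mb, n = n, seed = 7, stepSd = 0.15)
    if (is.null(g)) g <<- defaultGrid(tb)
    s <- suppressWarnings(estimateFes2d(tb, g))
    if (is.null(occRef)) occRef <<- occupancy(s) >= 200
    ij <- which(occRef, arr.ind = TRUE)
    u <- evalPotential(mb, cbind(binCenters(g, 1)[ij[, 1]], binCenters(g, 2)[ij[, 2]]))
    est <- dgValues(s)[occRef]
    dev <- est - (u - mean(u) + mean(est))
    max(abs(dev))
  }, numeric(1))
  expect_lte(maxErr[2], maxErr[1] + 1e-9)
})

test_that("window-tail selection keeps exactly the final tail of each window", {
  w10 <- data.frame(time = (1:10) * 0.5, value = 1:10)
  kept <- windowTailSelection(list(w10), tail = 0.5)[[1]]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$value, 10)
  # tail equal to the full window is the identity
  all10 <- windowTailSelection(list(w10), tail = 5)[[1]]
  expect_equal(all10$value, 1:10)
  expect_error(windowTailSelection(list(w10), tail = 9), "longer than window")
  # default tail is 10% of the window duration
  def <- windowTailSelection(list(w10))[[1]]
  expect_equal(nrow(def), 1L)
  # the reference bookkeeping: 5 ps windows at 0.5 fs, 0.5 ps tails
  win <- data.frame(time = (1:10000) * 5e-4)
  expect_equal(nrow(windowTailSelection(list(win), tail = 0.5)[[1]]), 1000L)
})

test_that("bootstrap error maps are seed-deterministic with the documented scalings", {
  # zero-variance bins: SD exactly 0 without smoothing, numerically 0 with it
  tb <- energySampleTable(rc1 = rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 60),
                          energy = rep(c(1, 2, 1.5, 0.5, 2.5), each = 60))
  g <- gridSpec(0, 1, 5)
  s0 <- bootstrapSurface(tb, g, smooth = NULL, replicates = 20, seed = 3)
  expect_true(all(s0@bootstrapSD == 0))
  s0s <- bootstrapSurface(tb, g, smooth = loessParams(span = 1, degree = 1),
                          replicates = 20, seed = 3)
  expect_lt(max(s0s@bootstrapSD), 1e-9)
  # determinism
  mkTable <- function() {
    set.seed(41)
    energySampleTable(rc1 = runif(600), energy = rnorm(600, sd = 0.5))
  }
  b1 <- bootstrapSurface(mkTable(), g, smooth = NULL, replicates = 30, seed = 9)
  b2 <- bootstrapSurface(mkTable(), g, smooth = NULL, replicates = 30, seed = 9)
  expect_identical(b1@bootstrapSD, b2@bootstrapSD)
  # replicating every row m times shrinks the SD roughly like 1/sqrt(m)
  base <- mkTable()
  m <- 9L
  rep9 <- energySampleTable(rc1 = rep(rcValues(base)[, 1], m),
                            energy = rep(sampleEnergies(base), m))
  sd1 <- bootstrapSurface(base, g, smooth = NULL, replicates = 80, seed = 5)@bootstrapSD
  sd9 <- bootstrapSurface(rep9, g, smooth = NULL, replicates = 80, seed = 5)@bootstrapSD
  ratio <- mean(sd1 / sd9, na.rm = TRUE)
  expect_gt(ratio, 2)     # ideal sqrt(9) = 3
  expect_lt(ratio, 4.5)
})
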