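# Free-energy surface / profile estimation: uniform-grid binning, per-bin
# partition functions, LOESS smoothing and bootstrap error maps.
#
# The per-bin estimator is the bin-mean of Boltzmann factors,
#   dG_bin = E_min - kB T log( mean_i exp(-(E_i - E_min)/kB T) ),
# which normalizes by the bin count and is therefore insensitive to
# steering-induced sampling density along the reaction coordinates.

#' Uniform grid specification
#'
#' @param lower,upper per-axis bounds (Angstrom).
#' @param bins per-axis bin counts (>= 2); recycled to the number of axes.
#' @return a \linkS4class{GridSpec}.
#' @export
gridSpec <- function(lower, upper, bins) {
  d <- length(lower)
  new("GridSpec", lower = as.numeric(lower), upper = as.numeric(upper),
      bins = as.integer(rep_len(bins, d)))
}

#' Default grid covering a sample table
#'
#' Bounds are the sample range; bin counts default to 48 per axis for 2D
#' tables and 100 for 1D ones.
#'
#' @param table an \linkS4class{EnergySampleTable}.
#' @param bins per-axis bin counts; \code{NULL} for the defaults.
#' @export
defaultGrid <- function(table, bins = NULL) {
  rc <- rcValues(table)
  d <- ncol(rc)
  if (is.null(bins)) bins <- if (d == 2L) 48L else 100L
  gridSpec(apply(rc, 2, min), apply(rc, 2, max), bins)
}

# per-axis bin index with the half-open convention: [lo, hi) except the
# last bin which is closed; values exactly on an interior edge go upward.
# Out-of-range values get NA.
.axisBin <- function(x, lo, hi, nb) {
  w <- (hi - lo) / nb
  i <- floor((x - lo) / w) + 1L
  i[x == hi] <- nb
  i[x < lo | x > hi] <- NA_integer_
  as.integer(i)
}

#' Assign samples to grid bins
#'
#' Every in-range row is assigned to exactly one bin (half-open convention,
#' last bin closed, edge ties upward).  Out-of-range rows are dropped with
#' a warning and counted.
#'
#' @param table an \linkS4class{EnergySampleTable}.
#' @param grid a \linkS4class{GridSpec} matching the table dimensionality.
#' @return list with \code{index} (per-row linear bin index, NA when out of
#'   range), \code{occupancy} (per-bin counts, vector or matrix),
#'   \code{outOfRange} (dropped row count).
#' @export
binSamples <- function(table, grid) {
  stopifnot(is(table, "EnergySampleTable"), is(grid, "GridSpec"))
  rc <- rcValues(table)
  d <- ncol(rc)
  if (length(grid@bins) != d)
    stop("grid dimensionality does not match the sample table", call. = FALSE)
  if (nrow(rc) == 0L) stop("sample table is empty", call. = FALSE)
  idx <- .axisBin(rc[, 1], grid@lower[1], grid@upper[1], grid@bins[1])
  if (d == 2L) {
    j <- .axisBin(rc[, 2], grid@lower[2], grid@upper[2], grid@bins[2])
    lin <- idx + (j - 1L) * grid@bins[1]
    lin[is.na(idx) | is.na(j)] <- NA_integer_
  } else {
    lin <- idx
  }
  oob <- sum(is.na(lin))
  if (oob == length(lin))
    stop("all samples fall outside the grid", call. = FALSE)
  if (oob > 0)
    warning(sprintf("%d out-of-range sample(s) dropped", oob), call. = FALSE)
  nbin <- prod(grid@bins)
  occ <- tabulate(lin[!is.na(lin)], nbins = nbin)
  if (d == 2L) occ <- matrix(occ, nrow = grid@bins[1], ncol = grid@bins[2])
  list(index = lin, occupancy = occ, outOfRange = as.integer(oob))
}

#' Per-bin free energy from sampled energies
#'
#' The partition-function estimate for one group of sampled energies:
#' \eqn{E_{min} - k_B T \log( \frac{1}{N}\sum_i e^{-(E_i - E_{min})/k_B T} )},
#' computed with a log-sum-exp shift so that energy spreads of hundreds of
#' kcal/mol stay finite.  The result always lies in
#' \eqn{[E_{min},\; E_{min} + k_B T \log N]} and tends to the arithmetic
#' mean of the energies as T grows.
#'
#' @param energies sampled energies (kcal/mol); at least one.
#' @param temperature temperature (K).
#' @return free energy (kcal/mol).
#' @export
binFreeEnergy <- function(energies, temperature = 300) {
  if (!length(energies)) stop("at least one energy is required", call. = FALSE)
  kbt <- .kBT(temperature)
  emin <- min(energies)
  emin - kbt * log(mean(exp(-(energies - emin) / kbt)))
}

#' LOESS smoothing parameters
#'
#' @param span neighbourhood fraction in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#' @export
loessParams <- function(span = 0.25, degree = 2L) {
  stopifnot(span > 0, span <= 1, degree %in% 1:2)
  list(span = as.numeric(span), degree = as.integer(degree))
}

#' Local polynomial (LOESS) smoothing
#'
#' Tri-cube distance weighting within the span-nearest neighbours, local
#' weighted least squares per evaluation point, evaluated at the input
#' points themselves.  Predictors are not normalized (all axes share the
#' Angstrom scale).  A rank-deficient degree-2 fit falls back to degree 1
#' with a warning.
#'
#' @param x numeric vector or n x 2 matrix of predictor points.
#' @param y response values.
#' @param span,degree see \code{\link{loessParams}}.
#' @return fitted values at \code{x}.
#' @export
loessSmooth <- function(x, y, span = 0.25, degree = 2L) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  stopifnot(nrow(x) == length(y))
  fitOnce <- function(deg) {
    df <- data.frame(y = y, x1 = x[, 1])
    fml <- y ~ x1
    if (ncol(x) == 2L) { df$x2 <- x[, 2]; fml <- y ~ x1 + x2 }
    fit <- loess(fml, data = df, span = span, degree = deg,
                 family = "gaussian", normalize = FALSE,
                 control = loess.control(surface = "direct", statistics = "none"))
    as.numeric(fitted(fit))
  }
  minNeeded <- if (degree == 2L) (if (ncol(x) == 2L) 6L else 3L) else ncol(x) + 1L
  if (max(2, floor(span * nrow(x))) < minNeeded || nrow(x) < minNeeded + 1L)
    stop(sprintf("too few points (%d) for a degree-%d local fit at span %.3g",
                 nrow(x), degree, span), call. = FALSE)
  tryCatch(fitOnce(degree), error = function(e) {
    if (degree == 2L) {
      warning("degree-2 local fit failed (", conditionMessage(e),
              "); falling back to degree 1", call. = FALSE)
      fitOnce(1L)
    } else stop(e)
  })
}

# shared core: bin, per-bin dG, smooth over occupied bins, zero-reference
.estimateCore <- function(table, grid, temperature, smooth) {
  b <- binSamples(table, grid)
  energy <- sampleEnergies(table)
  keep <- !is.na(b$index)
  groups <- split(energy[keep], b$index[keep])
  occIdx <- as.integer(names(groups))
  dgRaw <- unname(vapply(groups, binFreeEnergy, numeric(1), temperature = temperature))
  list(bin = b, occIdx = occIdx, dgRaw = dgRaw)
}

#' Estimate a 2D free-energy surface
#'
#' Bins a 2D sample table on a uniform grid, computes the per-bin partition
#' function, smooths the occupied bins with LOESS (fitted and evaluated on
#' occupied bins only; unoccupied bins stay missing, never imputed) and
#' subtracts the global minimum of the smoothed values so the surface
#' minimum is 0.  The raw values are shifted by the same offset so raw and
#' smoothed remain comparable.
#'
#' @param table a 2D \linkS4class{EnergySampleTable}.
#' @param grid a \linkS4class{GridSpec}; \code{NULL} for
#'   \code{\link{defaultGrid}} (48 x 48).
#' @param temperature temperature (K).
#' @param smooth \code{\link{loessParams}} or \code{NULL} to disable
#'   smoothing (smoothed = raw).
#' @return a \linkS4class{FreeEnergySurface}.
#' @export
estimateFes2d <- function(table, grid = NULL, temperature = 300,
                          smooth = loessParams()) {
  stopifnot(is(table, "EnergySampleTable"))
  if (ncol(rcValues(table)) != 2L) stop("estimateFes2d needs a 2D table", call. = FALSE)
  if (is.null(grid)) grid <- defaultGrid(table)
  core <- .estimateCore(table, grid, temperature, smooth)
  nb <- grid@bins
  raw <- matrix(NA_real_, nb[1], nb[2])
  raw[core$occIdx] <- core$dgRaw
  smoothed <- raw
  if (!is.null(smooth) && length(core$occIdx) > 1L) {
    ij <- arrayInd(core$occIdx, nb)
    pts <- cbind(binCenters(grid, 1)[ij[, 1]], binCenters(grid, 2)[ij[, 2]])
    smoothed[core$occIdx] <- loessSmooth(pts, core$dgRaw,
                                         span = smooth$span, degree = smooth$degree)
  }
  off <- min(smoothed, na.rm = TRUE)
  new("FreeEnergySurface", grid = grid, raw = raw - off, smoothed = smoothed - off,
      occupancy = core$bin$occupancy, temperature = as.numeric(temperature),
      bootstrapSD = matrix(numeric(0), 0, 0), outOfRange = core$bin$outOfRange)
}

#' Estimate a 1D free-energy profile
#'
#' One-dimensional analogue of \code{\link{estimateFes2d}}: per-bin
#' partition functions along a uniform 1D grid, LOESS smoothing over
#' occupied bins, zero-referenced at the smoothed minimum.
#'
#' @param table a 1D \linkS4class{EnergySampleTable}.
#' @param grid a \linkS4class{GridSpec}; \code{NULL} for
#'   \code{\link{defaultGrid}} (100 bins).
#' @inheritParams estimateFes2d
#' @return a \linkS4class{FreeEnergyProfile} (only occupied bins are kept).
#' @export
estimateProfile1d <- function(table, grid = NULL, temperature = 300,
                              smooth = loessParams()) {
  stopifnot(is(table, "EnergySampleTable"))
  if (ncol(rcValues(table)) != 1L) stop("estimateProfile1d needs a 1D table", call. = FALSE)
  if (is.null(grid)) grid <- defaultGrid(table)
  core <- .estimateCore(table, grid, temperature, smooth)
  centers <- binCenters(grid, 1)[core$occIdx]
  dgRaw <- core$dgRaw
  dg <- dgRaw
  if (!is.null(smooth) && length(core$occIdx) > 1L)
    dg <- loessSmooth(centers, dgRaw, span = smooth$span, degree = smooth$degree)
  off <- min(dg)
  occ <- core$bin$occupancy[core$occIdx]
  new("FreeEnergyProfile", centers = centers, dg = dg - off, raw = dgRaw - off,
      occupancy = as.numeric(occ), temperature = as.numeric(temperature),
      bootstrapSD = numeric(0))
}

#' Keep the final tail of each relaxation window
#'
#' For per-window frame records (each a data.frame with a time column),
#' keeps exactly the frames in the half-open interval
#' \code{(t_end - tail, t_end]} of each window - the converged tail of a
#' constrained relaxation.  The default tail is 10% of the window duration
#' (0.5 ps of a 5 ps relaxation).
#'
#' @param windows list of data.frames, each with a \code{time} column (ps)
#'   and arbitrary further columns.
#' @param tail tail duration (ps); \code{NULL} for 10% of each window's
#'   duration.
#' @return list of data.frames, reduced to the tail frames.
#' @export
windowTailSelection <- function(windows, tail = NULL) {
  stopifnot(is.list(windows), length(windows) >= 1)
  lapply(windows, function(w) {
    if (!is.data.frame(w) || !"time" %in% names(w) || nrow(w) == 0L)
      stop("each window must be a nonempty data.frame with a 'time' column",
           call. = FALSE)
    t <- w$time
    dtbar <- if (length(t) > 1) stats::median(diff(t)) else 0
    duration <- max(t) - min(t) + dtbar   # each frame represents one period
    tl <- if (is.null(tail)) 0.1 * duration else tail
    if (tl > duration + dtbar / 2 + 1e-12)
      stop(sprintf("tail (%.4g ps) longer than window (%.4g ps)", tl, duration),
           call. = FALSE)
    eps <- 1e-9 * max(1, abs(max(t)))
    w[t > max(t) - tl + eps, , drop = FALSE]
  })
}

#' Bootstrap error map for a surface or profile
#'
#' Resamples the table rows with replacement, reruns the full estimation
#' pipeline per replicate and returns the per-bin standard deviation over
#' replicates (the field's standard error analysis; default 100 replicates).
#' Bins occupied in fewer than two replicates get NA.
#'
#' @inheritParams estimateFes2d
#' @param replicates number of bootstrap replicates (>= 2).
#' @param seed RNG seed (resampling is seed-deterministic).
#' @return the input surface/profile object with its \code{bootstrapSD}
#'   slot filled.
#' @export
bootstrapSurface <- function(table, grid = NULL, temperature = 300,
                             smooth = loessParams(), replicates = 100L, seed = 1L) {
  stopifnot(is(table, "EnergySampleTable"))
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  d <- ncol(rcValues(table))
  if (is.null(grid)) grid <- defaultGrid(table)
  est <- if (d == 2L) function(tb) dgValues(estimateFes2d(tb, grid, temperature, smooth))
         else function(tb) {
           p <- estimateProfile1d(tb, grid, temperature, smooth)
           v <- rep(NA_real_, grid@bins[1])
           v[match(p@centers, binCenters(grid, 1))] <- p@dg
           v
         }
  point <- if (d == 2L) estimateFes2d(table, grid, temperature, smooth)
           else estimateProfile1d(table, grid, temperature, smooth)
  n <- nSamples(table)
  rc <- rcValues(table); energy <- sampleEnergies(table)
  set.seed(seed)
  reps <- vapply(seq_len(replicates), function(r) {
    ii <- sample.int(n, n, replace = TRUE)
    tb <- new("EnergySampleTable", rc = rc[ii, , drop = FALSE], energy = energy[ii])
    suppressWarnings(as.numeric(est(tb)))
  }, numeric(prod(grid@bins)))
  cnt <- rowSums(!is.na(reps))
  sdv <- apply(reps, 1, sd, na.rm = TRUE)
  sdv[cnt < 2] <- NA_real_
  if (d == 2L) {
    point@bootstrapSD <- matrix(sdv, grid@bins[1], grid@bins[2])
  } else {
    point@bootstrapSD <- sdv[match(point@centers, binCenters(grid, 1))]
  }
  point
}
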