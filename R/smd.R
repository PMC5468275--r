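# Steered-pulling work reconstruction and Jarzynski free-energy estimation.
#
# Work is the external work done by the moving restraint, the line integral
# of the pulling force over the *center* displacement (trapezoidal over
# recorded frames); holds contribute zero work because the center does not
# move.  The Jarzynski estimator is the log-sum-exp-stabilized exponential
# work average, resampled onto a common displacement grid.

#' Pulling force along a steered trace
#'
#' \eqn{F(t) = k (c(t) - x(t))}: positive when the system lags behind the
#' advancing restraint center.
#'
#' @param trace an \linkS4class{SMDTrace}.
#' @return per-frame force (kcal/mol/A).
#' @export
pullingForce <- function(trace) {
  stopifnot(is(trace, "SMDTrace"))
  trace@spring * (trace@center - trace@coord)
}

#' Accumulated external work along a steered trace
#'
#' \eqn{W(s) = \int_0^s F \, dc}, trapezoidal over the recorded frames, as
#' a function of restraint-center displacement from the start.
#'
#' @param trace an \linkS4class{SMDTrace}.
#' @return a \linkS4class{WorkSeries}.
#' @export
accumulateWork <- function(trace) {
  f <- pullingForce(trace)
  dc <- diff(trace@center)
  w <- c(0, cumsum(0.5 * (f[-1] + f[-length(f)]) * dc))
  new("WorkSeries", displacement = trace@center - trace@center[1], work = w)
}

# interpolate one work series onto a displacement grid; during holds the
# displacement repeats but the work is constant there, so ties are harmless
.workOnGrid <- function(ws, grid) {
  approx(ws@displacement, ws@work, xout = grid, ties = max, rule = 2)$y
}

.commonGrid <- function(works, spacing) {
  maxd <- min(vapply(works, function(w) max(w@displacement), numeric(1)))
  if (maxd <= 0) stop("trajectories have no common positive displacement", call. = FALSE)
  grid <- seq(0, maxd, by = spacing)
  if (maxd - grid[length(grid)] > 1e-9) grid <- c(grid, maxd)
  grid
}

#' Jarzynski free-energy difference estimate
#'
#' \eqn{\Delta G(s) = -k_B T \log \frac{1}{N} \sum_i e^{-W_i(s)/k_B T}},
#' log-sum-exp stabilized, over an ensemble of work series resampled by
#' linear interpolation onto a common displacement grid.  With a single
#' trajectory the estimate equals that trajectory's work; for any ensemble
#' \eqn{\Delta G(s) \le \langle W(s) \rangle} (Jensen's inequality) and
#' \eqn{\Delta G(0) = 0} exactly.
#'
#' @param works list of \linkS4class{WorkSeries} (or a single one).
#' @param temperature temperature (K).
#' @param spacing common-grid spacing (Angstrom).
#' @return a \linkS4class{JarzynskiResult} (CI slots NA; see
#'   \code{\link{jarzynskiBootstrap}}).
#' @export
jarzynskiEstimate <- function(works, temperature = 300, spacing = 0.1) {
  if (is(works, "WorkSeries")) works <- list(works)
  stopifnot(length(works) >= 1, all(vapply(works, is, logical(1), "WorkSeries")))
  kbt <- .kBT(temperature)
  grid <- .commonGrid(works, spacing)
  W <- vapply(works, .workOnGrid, numeric(length(grid)), grid = grid)
  W <- matrix(W, nrow = length(grid))
  dg <- .jarzLse(W, kbt)
  new("JarzynskiResult", displacement = grid, dg = dg,
      ciLow = rep(NA_real_, length(grid)), ciHigh = rep(NA_real_, length(grid)),
      nTraj = length(works), temperature = as.numeric(temperature))
}

# rows = grid points, cols = trajectories
.jarzLse <- function(W, kbt) {
  wmin <- apply(W, 1, min)
  wmin - kbt * log(rowMeans(exp(-(W - wmin) / kbt)))
}

#' Bootstrap confidence band for a Jarzynski estimate
#'
#' Resamples trajectories with replacement and reports the percentile
#' 2.5%/97.5% interval of the estimator at every displacement
#' (seed-deterministic).
#'
#' @inheritParams jarzynskiEstimate
#' @param replicates bootstrap replicates.
#' @param seed RNG seed.
#' @return a \linkS4class{JarzynskiResult} with the CI slots filled.
#' @export
jarzynskiBootstrap <- function(works, temperature = 300, replicates = 200L,
                               seed = 1L, spacing = 0.1) {
  stopifnot(length(works) >= 2)
  kbt <- .kBT(temperature)
  res <- jarzynskiEstimate(works, temperature, spacing)
  grid <- res@displacement
  W <- vapply(works, .workOnGrid, numeric(length(grid)), grid = grid)
  n <- length(works)
  set.seed(seed)
  boot <- vapply(seq_len(replicates), function(r) {
    .jarzLse(W[, sample.int(n, n, replace = TRUE), drop = FALSE], kbt)
  }, numeric(length(grid)))
  res@ciLow <- apply(boot, 1, quantile, probs = 0.025, names = FALSE)
  res@ciHigh <- apply(boot, 1, quantile, probs = 0.975, names = FALSE)
  res
}

#' Bootstrap standard deviation of a Jarzynski estimate
#'
#' Companion to \code{\link{jarzynskiBootstrap}}: the per-displacement
#' standard deviation of the estimator over trajectory resamples.
#'
#' @inheritParams jarzynskiBootstrap
#' @return numeric vector, one SD (kcal/mol) per displacement grid point.
#' @export
jarzynskiBootstrapSD <- function(works, temperature = 300, replicates = 200L,
                                 seed = 1L, spacing = 0.1) {
  stopifnot(length(works) >= 2)
  kbt <- .kBT(temperature)
  grid <- .commonGrid(works, spacing)
  W <- vapply(works, .workOnGrid, numeric(length(grid)), grid = grid)
  n <- length(works)
  set.seed(seed)
  boot <- vapply(seq_len(replicates), function(r) {
    .jarzLse(W[, sample.int(n, n, replace = TRUE), drop = FALSE], kbt)
  }, numeric(length(grid)))
  apply(boot, 1, sd)
}

#' Mean-work profile of an ensemble
#'
#' The arithmetic mean of the work over trajectories on the common
#' displacement grid; its gap above the Jarzynski estimate is the
#' dissipation diagnostic (it closes in the quasi-static limit).
#'
#' @inheritParams jarzynskiEstimate
#' @return list with \code{displacement} and \code{meanWork}.
#' @export
meanWorkProfile <- function(works, spacing = 0.1) {
  if (is(works, "WorkSeries")) works <- list(works)
  grid <- .commonGrid(works, spacing)
  W <- vapply(works, .workOnGrid, numeric(length(grid)), grid = grid)
  W <- matrix(W, nrow = length(grid))
  list(displacement = grid, meanWork = rowMeans(W))
}

#' Compare two Jarzynski results
#'
#' Pointwise difference A - B on their (identical) displacement grid, plus
#' the scalar difference at the final common displacement - the
#' head-separation \eqn{\Delta\Delta G} readout.
#'
#' @param resA,resB \linkS4class{JarzynskiResult} objects on the same grid.
#' @return list with \code{displacement}, \code{ddg} (profile) and
#'   \code{final} (scalar at the last displacement).
#' @export
compareConditions <- function(resA, resB) {
  stopifnot(is(resA, "JarzynskiResult"), is(resB, "JarzynskiResult"))
  if (length(resA@displacement) != length(resB@displacement) ||
      max(abs(resA@displacement - resB@displacement)) > 1e-9)
    stop("displacement grids do not match", call. = FALSE)
  ddg <- resA@dg - resB@dg
  list(displacement = resA@displacement, ddg = ddg, final = ddg[length(ddg)])
}
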