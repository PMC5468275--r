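# Trajectory time-series statistics: threshold occupancy, stabilized
# distances and optimal-superposition RMSD.

#' Distance series constructor
#'
#' @param times frame times (ns), strictly increasing.
#' @param distances distances (Angstrom, >= 0).
#' @param label observable label.
#' @export
distanceSeries <- function(times, distances, label = "distance") {
  new("DistanceSeries", times = as.numeric(times),
      distances = as.numeric(distances), label = label)
}

#' Fraction of time below a distance cutoff
#'
#' Percentage of frames whose distance is at or below the cutoff (the
#' cutoff itself counts as occupied).  The default cutoff of 3.5 Angstrom
#' is the heavy-atom hydrogen-bond criterion used to call a geometry
#' "compatible with an active arrangement"; because published occupancy
#' percentages rarely state their cutoff, it is an explicit parameter and
#' \code{\link{occupancySensitivity}} reports a sweep.
#'
#' @param series a \linkS4class{DistanceSeries} or numeric vector.
#' @param cutoff distance cutoff (Angstrom), inclusive.
#' @return percentage in [0, 100].
#' @export
occupancyFraction <- function(series, cutoff = 3.5) {
  d <- if (is(series, "DistanceSeries")) series@distances else as.numeric(series)
  if (!length(d)) stop("series is empty", call. = FALSE)
  100 * mean(d <= cutoff)
}

#' Occupancy over a range of cutoffs
#'
#' @inheritParams occupancyFraction
#' @param cutoffs cutoffs to sweep (Angstrom); default 3.0 to 4.0.
#' @return data.frame with columns \code{cutoff} and \code{percent}.
#' @export
occupancySensitivity <- function(series, cutoffs = seq(3.0, 4.0, by = 0.25)) {
  data.frame(cutoff = cutoffs,
             percent = vapply(cutoffs, function(ct) occupancyFraction(series, ct),
                              numeric(1)))
}

#' Stabilized value of a distance series
#'
#' Mean and SD over the final window of the series - the "stabilized at"
#' readout for a distance that has settled.  The default window is the
#' final 20% of the time span.
#'
#' @param series a \linkS4class{DistanceSeries}.
#' @param window window length (ns); \code{NULL} for 20% of the span.
#' @return named numeric \code{c(mean = , sd = , n = )}.
#' @export
stabilizedValue <- function(series, window = NULL) {
  stopifnot(is(series, "DistanceSeries"))
  t <- series@times
  span <- max(t) - min(t)
  if (is.null(window)) window <- 0.2 * span
  if (window > span + 1e-12)
    stop(sprintf("window (%.4g ns) exceeds the series span (%.4g ns)", window, span),
         call. = FALSE)
  keep <- t >= max(t) - window - 1e-12
  d <- series@distances[keep]
  c(mean = mean(d), sd = if (length(d) > 1) sd(d) else 0, n = length(d))
}

#' Optimal-superposition RMSD of two point sets
#'
#' Least-squares rigid superposition (rotation + translation, determinant
#' forced to +1 so no reflection) of \code{mobile} onto \code{reference},
#' then the root-mean-square deviation.  Point correspondence is by row
#' order.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3,
#'   matched row order.
#' @return RMSD (Angstrom).
#' @export
superposeRmsd <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions", call. = FALSE)
  if (nrow(mobile) < 3L)
    stop("at least 3 points are required for superposition", call. = FALSE)
  if (ncol(mobile) != 3L) stop("points must be 3-dimensional", call. = FALSE)
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  H <- crossprod(mc, rc)
  usv <- svd(H)
  if (usv$d[1] > 0 && usv$d[2] / usv$d[1] < 1e-8)
    warning("near-degenerate (collinear) configuration: rotation is ill-determined",
            call. = FALSE)
  s <- sign(det(usv$v %*% t(usv$u)))
  if (s == 0) s <- 1
  R <- usv$v %*% diag(c(1, 1, s)) %*% t(usv$u)
  aligned <- mc %*% t(R)
  sqrt(mean(rowSums((aligned - rc)^2)))
}

#' Coordinate frame set constructor
#'
#' @param frames list of n x 3 coordinate matrices (Angstrom), identical
#'   point count and ordering.
#' @param labels point labels (one per row); defaults to \code{p1, p2, ...}.
#' @param reference index of the reference frame (default first).
#' @export
coordinateFrameSet <- function(frames, labels = NULL, reference = 1L) {
  frames <- lapply(frames, as.matrix)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(frames[[1]])))
  new("CoordinateFrameSet", frames = frames, labels = labels,
      reference = as.integer(reference))
}

#' Per-frame superposition RMSD series
#'
#' RMSD of every frame's selected points against the reference frame's,
#' after optimal rigid superposition per frame; rigid-body motion of the
#' selection therefore contributes nothing.
#'
#' @param frames a \linkS4class{CoordinateFrameSet}.
#' @param selection character vector of point labels (default: all).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdSeries <- function(frames, selection = NULL) {
  stopifnot(is(frames, "CoordinateFrameSet"))
  if (is.null(selection)) selection <- frames@labels
  idx <- match(selection, frames@labels)
  if (anyNA(idx))
    stop("unknown labels: ", paste(selection[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (!length(idx)) stop("selection is empty", call. = FALSE)
  ref <- frames@frames[[frames@reference]][idx, , drop = FALSE]
  vapply(frames@frames, function(f)
    superposeRmsd(f[idx, , drop = FALSE], ref), numeric(1))
}
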