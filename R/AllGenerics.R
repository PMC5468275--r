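# Generics, accessors and show methods.

#' Evaluate a model potential
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param x coordinates: a numeric vector (n points for a 1D potential, or a
#'   single point for a 2D one) or an n x d matrix.
#' @return numeric vector of energies (kcal/mol).
#' @export
setGeneric("evalPotential", function(spec, x) standardGeneric("evalPotential"))

#' Gradient of a model potential
#'
#' @inheritParams evalPotential
#' @return n x d matrix of gradients (kcal/mol/A).
#' @export
setGeneric("potentialGradient", function(spec, x) standardGeneric("potentialGradient"))

#' Flat-bottom restraint energy
#'
#' Zero inside the flat region, half-harmonic wall outside; continuous and
#' once-differentiable at the walls.
#'
#' @param restraint a \linkS4class{FlatBottomRestraint}.
#' @param value observable value(s) (Angstrom or degrees).
#' @return restraint energy (kcal/mol), vectorized over \code{value}.
#' @export
setGeneric("restraintEnergy", function(restraint, value) standardGeneric("restraintEnergy"))

#' Number of samples in a table
#' @param x an \linkS4class{EnergySampleTable}.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Reaction-coordinate values
#' @param x an \linkS4class{EnergySampleTable}.
#' @return n x d matrix of reaction-coordinate values (Angstrom).
#' @export
setGeneric("rcValues", function(x) standardGeneric("rcValues"))

#' Per-sample energies
#' @param x an \linkS4class{EnergySampleTable}.
#' @export
setGeneric("sampleEnergies", function(x) standardGeneric("sampleEnergies"))

#' Free-energy values of a surface or profile
#' @param x a \linkS4class{FreeEnergySurface} or \linkS4class{FreeEnergyProfile}.
#' @param which \code{"smoothed"} (default) or \code{"raw"}.
#' @export
setGeneric("dgValues", function(x, which = "smoothed") standardGeneric("dgValues"))

#' Per-bin occupancy
#' @param x a \linkS4class{FreeEnergySurface} or \linkS4class{FreeEnergyProfile}.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' Estimation temperature (K)
#' @param x a surface, profile or Jarzynski result.
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' Bin centers of a grid axis
#' @param grid a \linkS4class{GridSpec}.
#' @param axis axis index (1 or 2).
#' @export
setGeneric("binCenters", function(grid, axis = 1L) standardGeneric("binCenters"))

setMethod("nSamples", "EnergySampleTable", function(x) nrow(x@rc))
setMethod("rcValues", "EnergySampleTable", function(x) x@rc)
setMethod("sampleEnergies", "EnergySampleTable", function(x) x@energy)

setMethod("dgValues", "FreeEnergySurface", function(x, which = "smoothed") {
  which <- match.arg(which, c("smoothed", "raw"))
  if (which == "smoothed") x@smoothed else x@raw
})
setMethod("dgValues", "FreeEnergyProfile", function(x, which = "smoothed") {
  which <- match.arg(which, c("smoothed", "raw"))
  if (which == "smoothed" || !length(x@raw)) x@dg else x@raw
})
setMethod("occupancy", "FreeEnergySurface", function(x) x@occupancy)
setMethod("occupancy", "FreeEnergyProfile", function(x) x@occupancy)
setMethod("temperature", "FreeEnergySurface", function(x) x@temperature)
setMethod("temperature", "FreeEnergyProfile", function(x) x@temperature)
setMethod("temperature", "JarzynskiResult", function(x) x@temperature)

setMethod("binCenters", "GridSpec", function(grid, axis = 1L) {
  axis <- as.integer(axis)
  if (axis < 1L || axis > length(grid@bins)) stop("axis out of range", call. = FALSE)
  w <- (grid@upper[axis] - grid@lower[axis]) / grid@bins[axis]
  grid@lower[axis] + w * (seq_len(grid@bins[axis]) - 0.5)
})

#' @export
#' @describeIn EnergySampleTable-class coerce to a data.frame with columns
#'   rc1(, rc2) and energy.
as.data.frame.EnergySampleTable <- function(x, ...) {
  df <- as.data.frame(x@rc)
  df$energy <- x@energy
  df
}

setMethod("show", "PotentialSpec", function(object) {
  cat(sprintf("PotentialSpec: %s (%dD)\n", object@family, object@dimension))
  for (nm in names(object@params))
    cat(sprintf("  %s: %s\n", nm, paste(signif(object@params[[nm]], 6), collapse = ", ")))
})

setMethod("show", "EnergySampleTable", function(object) {
  cat(sprintf("EnergySampleTable: %d samples, %dD reaction coordinate\n",
              nrow(object@rc), ncol(object@rc)))
  cat(sprintf("  energy range: [%.3f, %.3f] kcal/mol\n",
              min(object@energy), max(object@energy)))
})

setMethod("show", "FreeEnergySurface", function(object) {
  occ <- sum(is.finite(object@raw))
  cat(sprintf("FreeEnergySurface: %dx%d grid, %d occupied bins, T = %g K\n",
              object@grid@bins[1], object@grid@bins[2], occ, object@temperature))
  if (occ) cat(sprintf("  smoothed range: [0, %.3f] kcal/mol\n",
                       max(object@smoothed[is.finite(object@smoothed)])))
  if (length(object@bootstrapSD)) cat("  bootstrap SD: available\n")
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat(sprintf("FreeEnergyProfile: %d points over [%.3f, %.3f] A\n",
              length(object@centers), min(object@centers), max(object@centers)))
  cat(sprintf("  dg range: [%.3f, %.3f] kcal/mol\n", min(object@dg), max(object@dg)))
})

setMethod("show", "PathResult", function(object) {
  cat(sprintf("PathResult: %d nodes, barrier %.3f kcal/mol (%d-connectivity)\n",
              nrow(object@nodes), object@barrier, object@connectivity))
  cat(sprintf("  main TS at path index %d; %d intermediate TS\n",
              object@tsMain, length(object@tsIntermediate)))
})

setMethod("show", "SMDTrace", function(object) {
  cat(sprintf("SMDTrace: %d frames over %.4g ns (v = %g A/ns, k = %g kcal/mol/A^2, hold %g ns)\n",
              length(object@times), max(object@times), object@velocity,
              object@spring, object@holdDuration))
})

setMethod("show", "JarzynskiResult", function(object) {
  cat(sprintf("JarzynskiResult: %d trajectories, displacement 0..%.2f A, T = %g K\n",
              object@nTraj, max(object@displacement), object@temperature))
  cat(sprintf("  dG at final displacement: %.3f kcal/mol\n",
              object@dg[length(object@dg)]))
})

setMethod("show", "DistanceSeries", function(object) {
  cat(sprintf("DistanceSeries '%s': %d frames over %.4g ns, mean %.2f A\n",
              object@label, length(object@times), diff(range(object@times)),
              mean(object@distances)))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  for (nm in names(object@values))
    cat(sprintf("  %s: %s\n", nm, paste(format(object@values[[nm]]), collapse = ", ")))
})
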