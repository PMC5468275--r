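# Flat-bottom restraints: free movement within [lower, upper], half-harmonic
# walls outside.  Used both as standalone energy terms and inside the
# Langevin integrator (where the observable must name a simulated
# coordinate, "rc1" or "rc2").

#' Construct a flat-bottom restraint
#'
#' @param observable name of the restrained observable; use \code{"rc1"} or
#'   \code{"rc2"} for restraints applied during simulation.
#' @param lower,upper bounds of the flat (zero-energy) region (Angstrom or
#'   degrees).
#' @param stiffness wall stiffness (kcal/mol per unit squared).
#' @return a \linkS4class{FlatBottomRestraint}.
#' @examples
#' r <- flatBottomRestraint("rc1", 0, 3.5, stiffness = 10)
#' restraintEnergy(r, 4.5)  # 0.5 * 10 * 1^2 = 5
#' @export
flatBottomRestraint <- function(observable = "rc1", lower, upper, stiffness = 10) {
  new("FlatBottomRestraint", observable = observable,
      lower = as.numeric(lower), upper = as.numeric(upper),
      stiffness = as.numeric(stiffness))
}

#' @rdname restraintEnergy
#' @export
setMethod("restraintEnergy", "FlatBottomRestraint", function(restraint, value) {
  lo <- restraint@lower; hi <- restraint@upper; k <- restraint@stiffness
  excess <- pmax(lo - value, 0) + pmax(value - hi, 0)
  0.5 * k * excess^2
})

#' Flat-bottom restraint force
#'
#' Minus the derivative of \code{\link{restraintEnergy}} with respect to the
#' observable: zero inside the flat region, linear outside.
#'
#' @inheritParams restraintEnergy
#' @return force (kcal/mol per unit), vectorized.
#' @export
restraintForce <- function(restraint, value) {
  lo <- restraint@lower; hi <- restraint@upper; k <- restraint@stiffness
  -k * (pmin(value - lo, 0) + pmax(value - hi, 0))
}

# restraint list -> matrix rows (coord index, lower, upper, k) for C++
.restraintMatrix <- function(restraints, dimension) {
  if (!length(restraints)) return(matrix(numeric(0), ncol = 4))
  rows <- lapply(restraints, function(r) {
    if (!is(r, "FlatBottomRestraint"))
      stop("restraints must be FlatBottomRestraint objects", call. = FALSE)
    idx <- match(r@observable, c("rc1", "rc2"))
    if (is.na(idx) || idx > dimension)
      stop(sprintf("restraint observable '%s' does not name a simulated coordinate",
                   r@observable), call. = FALSE)
    c(idx, r@lower, r@upper, r@stiffness)
  })
  do.call(rbind, rows)
}
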