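# Analytic model potentials: constructors, evaluation and gradients.
# These stand in for the energy function of an atomistic engine and act as
# the exact ground truth against which every estimator is tested.

# family -> C++ code, and packing of params into the flat vector the
# compiled kernels expect
.famCode <- c(harmonic = 1L, double_well = 2L, mueller_brown = 3L, polynomial = 4L)

.cppPack <- function(spec) {
  p <- spec@params
  par <- switch(spec@family,
    harmonic      = c(p$k, p$center),
    double_well   = c(p$height, p$halfSeparation),
    mueller_brown = c(p$A, p$a, p$b, p$c, p$x0, p$y0),
    polynomial    = p$coefficients)
  list(fam = .famCode[[spec@family]], par = as.numeric(par))
}

#' Harmonic potential
#'
#' \eqn{U(x) = \sum_i k_i (x_i - c_i)^2 / 2}, 1D or 2D.
#'
#' @param k spring constant(s) (kcal/mol/A^2), recycled to the dimension of
#'   \code{center}.
#' @param center minimum position(s) (Angstrom); its length sets the
#'   dimensionality.
#' @return a \linkS4class{PotentialSpec}.
#' @examples
#' evalPotential(harmonicPotential(k = 2), 1.5)  # 2.25
#' @export
harmonicPotential <- function(k = 1, center = 0) {
  d <- length(center)
  new("PotentialSpec", family = "harmonic",
      params = list(k = rep_len(as.numeric(k), d), center = as.numeric(center)),
      dimension = as.integer(d))
}

#' Symmetric double-well potential
#'
#' \eqn{U(x) = h ((x/a)^2 - 1)^2}: minima at \eqn{\pm a} with \eqn{U = 0},
#' barrier of height \eqn{h} at the origin.
#'
#' @param height barrier height h (kcal/mol).
#' @param halfSeparation half-distance a between the wells (Angstrom).
#' @export
doubleWellPotential <- function(height = 3, halfSeparation = 1) {
  stopifnot(height > 0, halfSeparation > 0)
  new("PotentialSpec", family = "double_well",
      params = list(height = as.numeric(height),
                    halfSeparation = as.numeric(halfSeparation)),
      dimension = 1L)
}

#' Mueller-Brown potential
#'
#' The standard four-Gaussian 2D model landscape, widely used as a surrogate
#' for reaction free-energy surfaces, with its literature coefficients.
#' Energies are read in kcal/mol, coordinates in Angstrom.
#'
#' @export
muellerBrownPotential <- function() {
  new("PotentialSpec", family = "mueller_brown",
      params = list(A = c(-200, -100, -170, 15),
                    a = c(-1, -1, -6.5, 0.7),
                    b = c(0, 0, 11, 0.6),
                    c = c(-10, -10, -6.5, 0.7),
                    x0 = c(1, 0, -0.5, -1),
                    y0 = c(0, 0.5, 1.5, 1)),
      dimension = 2L)
}

#' Reference global minimum of the Mueller-Brown potential
#'
#' Location and energy of the global minimum of
#' \code{\link{muellerBrownPotential}}, recorded as the module's reference
#' constant after dense grid search with local refinement.
#'
#' @return list with elements \code{x} (coordinates) and \code{energy}.
#' @export
muellerBrownMinimum <- function() {
  list(x = c(-0.558223637, 1.441725842), energy = -146.69951721)
}

#' Polynomial potential (1D)
#'
#' \eqn{U(x) = \sum_j c_j x^j} with user-supplied coefficients
#' \code{c(c0, c1, ...)}.
#'
#' @param coefficients numeric vector of polynomial coefficients, constant
#'   term first.
#' @export
polynomialPotential <- function(coefficients) {
  stopifnot(length(coefficients) >= 1, all(is.finite(coefficients)))
  new("PotentialSpec", family = "polynomial",
      params = list(coefficients = as.numeric(coefficients)), dimension = 1L)
}

# normalize x to an n x d matrix, enforcing the arity contract
.pointMatrix <- function(spec, x) {
  d <- spec@dimension
  if (is.matrix(x)) {
    if (ncol(x) != d)
      stop(sprintf("point arity (%d) does not match potential dimensionality (%d)",
                   ncol(x), d), call. = FALSE)
    return(x)
  }
  x <- as.numeric(x)
  if (d == 1L) return(matrix(x, ncol = 1L))
  if (length(x) != d)
    stop(sprintf("point arity (%d) does not match potential dimensionality (%d)",
                 length(x), d), call. = FALSE)
  matrix(x, ncol = d)
}

#' @rdname evalPotential
#' @export
setMethod("evalPotential", "PotentialSpec", function(spec, x) {
  X <- .pointMatrix(spec, x)
  pk <- .cppPack(spec)
  .cppEvalPotential(pk$fam, pk$par, X)
})

#' @rdname potentialGradient
#' @export
setMethod("potentialGradient", "PotentialSpec", function(spec, x) {
  X <- .pointMatrix(spec, x)
  pk <- .cppPack(spec)
  .cppGradPotential(pk$fam, pk$par, X)
})
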