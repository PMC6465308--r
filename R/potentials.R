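#' Analytic toy potentials
#'
#' Specification of the analytic potential energy surfaces used by the toy
#' Langevin engine. Three kinds are supported:
#' \describe{
#'   \item{`double_well_1d`}{\eqn{V(x) = h (x^2/w^2 - 1)^2} with barrier
#'     height `h` (kT units) and minima at \eqn{x = \pm w}.}
#'   \item{`double_well_2d`}{\eqn{V(x, y) = h (x^2/w^2 - 1)^2 + k y^2 / 2},
#'     a symmetric double well along x with harmonic confinement of
#'     stiffness `k` orthogonal to it. The saddle at \eqn{x = 0} is an
#'     analytic committor-1/2 surface by symmetry.}
#'   \item{`harmonic`}{\eqn{V(\mathbf{x}) = k |\mathbf{x}|^2 / 2} in any
#'     dimension.}
#' }
#'
#' @param kind one of `"double_well_1d"`, `"double_well_2d"`, `"harmonic"`.
#' @param barrier_height barrier height h in kT units (double wells).
#' @param well_separation half-distance w between minima, length units.
#' @param stiffness orthogonal / harmonic stiffness k, kT per length^2.
#' @param dimensionality space dimension (only used for `"harmonic"`).
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(kind = c("double_well_2d", "double_well_1d", "harmonic"),
                           barrier_height = 5, well_separation = 1,
                           stiffness = 5, dimensionality = NULL) {
  kind <- match.arg(kind)
  if (kind != "harmonic") {
    if (barrier_height <= 0) stop("barrier height must be positive")
    if (well_separation <= 0) stop("well separation must be positive")
  }
  if (stiffness <= 0) stop("stiffness must be positive")
  dim <- switch(kind,
    double_well_1d = 1L,
    double_well_2d = 2L,
    harmonic = as.integer(if (is.null(dimensionality)) 1L else dimensionality)
  )
  if (dim < 1L) stop("dimensionality must be >= 1")
  structure(
    list(kind = kind, barrier_height = barrier_height,
         well_separation = well_separation, stiffness = stiffness,
         dimensionality = dim),
    class = "potential_spec"
  )
}

#' Potential energy
#' @param potential a [potential_spec()].
#' @param x position vector of length `potential$dimensionality`.
#' @return scalar energy in kT units.
#' @export
potential_energy <- function(potential, x) {
  h <- potential$barrier_height; w <- potential$well_separation
  k <- potential$stiffness
  switch(potential$kind,
    double_well_1d = h * (x[1]^2 / w^2 - 1)^2,
    double_well_2d = h * (x[1]^2 / w^2 - 1)^2 + 0.5 * k * x[2]^2,
    harmonic = 0.5 * k * sum(x^2)
  )
}

#' Potential gradient
#' @inheritParams potential_energy
#' @return gradient vector, kT per length unit.
#' @export
potential_gradient <- function(potential, x) {
  h <- potential$barrier_height; w <- potential$well_separation
  k <- potential$stiffness
  switch(potential$kind,
    double_well_1d = 4 * h * x[1] * (x[1]^2 / w^2 - 1) / w^2,
    double_well_2d = c(4 * h * x[1] * (x[1]^2 / w^2 - 1) / w^2, k * x[2]),
    harmonic = k * x
  )
}

#' Analytic minima of a potential
#' @inheritParams potential_energy
#' @return matrix with one minimum per row.
#' @export
potential_minima <- function(potential) {
  w <- potential$well_separation
  switch(potential$kind,
    double_well_1d = matrix(c(-w, w), ncol = 1),
    double_well_2d = matrix(c(-w, 0, w, 0), ncol = 2, byrow = TRUE),
    harmonic = matrix(0, nrow = 1, ncol = potential$dimensionality)
  )
}
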