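#' @include AllClasses.R utils.R
NULL

#' Material constructors
#'
#' \code{neoHookean()} builds the compressible neo-Hookean material
#' Psi = C10 (Ib1 - 3) + (1/D1) (J - 1)^2. \code{hgo()} adds a single
#' tension-only collagen fibre family:
#' Psi = Psi_NH + k1/(2 k2) [exp(k2 E^2) - 1] with
#' E = kappa (Ib1 - 3) + (1 - 3 kappa)(Ib4 - 1), the fibre term active only
#' when E > 0 (fibres carry no load when the matrix is compressed along
#' them). Near-incompressibility is parameterized by an effective Poisson
#' ratio: with small-strain identities mu0 = 2 C10 and K0 = 2/D1,
#' D1 = 3 (1 - 2 nu) / (2 C10 (1 + nu)).
#'
#' @param C10 matrix stiffness (kPa)
#' @param nu effective small-strain Poisson ratio used to derive D1 when D1
#'   is not given (default 0.49, near-incompressible)
#' @param D1 inverse-bulk parameter (1/kPa); overrides \code{nu}
#' @return a \linkS4class{NeoHookean} or \linkS4class{HGO} object
#' @export
neoHookean <- function(C10, nu = 0.49, D1 = NULL) {
  if (is.null(D1)) D1 <- d1FromNu(C10, nu)
  new("NeoHookean", C10 = C10, D1 = D1)
}

#' @rdname neoHookean
#' @param k1 fibre stiffness (kPa)
#' @param k2 dimensionless fibre nonlinearity
#' @param kappa fibre dispersion in [0, 1/3] (0 = perfectly aligned)
#' @export
hgo <- function(C10, k1, k2 = 200, kappa = 0, nu = 0.49, D1 = NULL) {
  if (is.null(D1)) D1 <- d1FromNu(C10, nu)
  new("HGO", C10 = C10, D1 = D1, k1 = k1, k2 = k2, kappa = kappa)
}

#' Small-strain parameter conversions
#'
#' \code{d1FromNu}: D1 = 3 (1 - 2 nu) / (2 C10 (1 + nu)) from mu0 = 2 C10
#' and K0 = 2/D1. \code{youngsToC10}: C10 = E / (4 (1 + nu)) from
#' E = 2 mu (1 + nu), mu = 2 C10; the conversion factor depends on the
#' assumed Poisson ratio and is therefore an explicit choice, not a
#' constant.
#'
#' @param C10 matrix stiffness (kPa)
#' @param nu effective Poisson ratio
#' @return \code{d1FromNu}: D1 in 1/kPa
#' @export
d1FromNu <- function(C10, nu = 0.49) {
  if (nu >= 0.5 || nu <= -1) stop("nu must lie in (-1, 0.5)")
  3 * (1 - 2 * nu) / (2 * C10 * (1 + nu))
}

#' @rdname d1FromNu
#' @param E Young's modulus (kPa)
#' @export
youngsToC10 <- function(E, nu = 0.49) E / (4 * (1 + nu))

# encode a material as the numeric vector consumed by the C++ kernel
matVector <- function(material) {
  if (is(material, "HGO"))
    c(1, material@C10, material@D1, material@k1, material@k2,
      material@kappa)
  else if (is(material, "NeoHookean"))
    c(0, material@C10, material@D1, 0, 0, 0)
  else stop("material must be NeoHookean or HGO")
}

stateFiber <- function(state, material) {
  if (is(material, "HGO")) {
    if (!is.finite(state@fiberAngleDeg))
      stop("HGO material requires a defined fiber angle")
    th <- state@fiberAngleDeg * pi / 180
    c(cos(th), sin(th))
  } else c(1, 0)
}

#' Strain energy density of a material at a deformation state
#'
#' Evaluates the stored energy (kPa) for the full 3D kinematics implied by
#' the in-plane deformation gradient and the out-of-plane stretch. For an
#' HGO material the fibre term is included only when the fibre strain
#' measure E is positive.
#'
#' @param state a \linkS4class{DeformationState}
#' @param material \linkS4class{NeoHookean} or \linkS4class{HGO}
#' @return energy density in kPa
#' @export
strainEnergy <- function(state, material) {
  stopifnot(is(state, "DeformationState"))
  .cpp_point(as.vector(state@F), state@lambda3, matVector(material),
             stateFiber(state, material), need_hess = FALSE)$energy
}

#' Cauchy stress at a deformation state
#'
#' sigma = (2/J) F (dPsi/dC) F' for the 3D kinematics
#' blockdiag(F_inplane, lambda3); returns the symmetric 3 x 3 tensor (kPa).
#'
#' @inheritParams strainEnergy
#' @return 3 x 3 symmetric matrix (kPa)
#' @export
cauchyStress <- function(state, material) {
  stopifnot(is(state, "DeformationState"))
  .cpp_point(as.vector(state@F), state@lambda3, matVector(material),
             stateFiber(state, material), need_hess = FALSE)$sigma
}

#' First Piola-Kirchhoff stress components
#'
#' Gradient of the energy with respect to the kinematic variables
#' (F11, F21, F12, F22, lambda3): the in-plane first Piola-Kirchhoff stress
#' and its out-of-plane component P33.
#'
#' @inheritParams strainEnergy
#' @return numeric length-5 vector (kPa)
#' @export
pkStress <- function(state, material) {
  stopifnot(is(state, "DeformationState"))
  .cpp_point(as.vector(state@F), state@lambda3, matVector(material),
             stateFiber(state, material), need_hess = FALSE)$grad
}

#' Consistent material tangent
#'
#' The Hessian of the strain energy with respect to
#' (F11, F21, F12, F22, lambda3): the first-elasticity (dP/dF) tangent for
#' the plane-stress kinematics, used to build the Newton stiffness. It is
#' the exact linearization of \code{\link{pkStress}} (symmetric by
#' construction).
#'
#' @inheritParams strainEnergy
#' @return 5 x 5 symmetric matrix (kPa)
#' @export
materialTangent <- function(state, material) {
  stopifnot(is(state, "DeformationState"))
  .cpp_point(as.vector(state@F), state@lambda3, matVector(material),
             stateFiber(state, material), need_hess = TRUE)$hess
}

#' Plane-stress condensation at a material point
#'
#' Solves sigma33(F_inplane, lambda3) = 0 for the thickness stretch by a
#' safeguarded scalar Newton (tolerance |sigma33| < 1e-10 max(1 kPa,
#' ||sigma||), root sought in lambda3 in [0.05, 20]) and returns the
#' statically condensed in-plane tangent
#' A = H_FF - H_Fl H_ll^{-1} H_lF.
#'
#' @param F 2 x 2 in-plane deformation gradient (det > 0)
#' @param material \linkS4class{NeoHookean} or \linkS4class{HGO}
#' @param fiberAngleDeg fibre angle for HGO materials (degrees)
#' @param lambda3Init starting guess for the thickness stretch
#' @return list: \code{lambda3}, \code{sigma} (3 x 3 with sigma33 = 0 to
#'   tolerance), \code{P} (in-plane first Piola), \code{tangent} (4 x 4
#'   condensed), \code{energy}
#' @export
planeStressCondense <- function(F, material, fiberAngleDeg = NA,
                                lambda3Init = 1) {
  if (det(F) <= 0) stop("det(F) must be positive")
  a0 <- stateFiber(deformationState(F, 1, fiberAngleDeg), material)
  .cpp_plane_stress(as.vector(F), matVector(material), a0, lambda3Init)
}
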