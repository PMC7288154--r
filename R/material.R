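#' Mooney-Rivlin material parameters
#'
#' Parameter container for the compressible Mooney-Rivlin strain-energy
#' density \deqn{w = C_1(\bar I_1 - 3) + C_2(\bar I_2 - 3) + D_v(J - 1)^2}
#' written in the isochoric invariants \eqn{\bar I_1 = J^{-2/3} I_1},
#' \eqn{\bar I_2 = J^{-4/3} I_2}.  The defaults are the benchmark material
#' used throughout the package; its instantaneous uniaxial tangent modulus in
#' the incompressible limit is \eqn{6(C_1 + C_2) = 206.7} MPa.
#'
#' Two conventions for the volumetric parameter are in circulation.  In the
#' `"inverse"` (finite-element, default) convention `D1` is a compliance-like
#' parameter and the volumetric stiffness is \eqn{D_v = 1/D_1} (initial bulk
#' modulus \eqn{\kappa_0 = 2/D_1}); with the default `D1 = 0.0029` this gives
#' \eqn{\kappa_0 = 689.7} MPa and an initial Poisson ratio of 0.45,
#' consistent with a nearly incompressible rubber-like solid.  The
#' `"direct"` convention takes \eqn{D_v = D_1} verbatim (a nearly
#' pressure-free material at the default value, kept for completeness).
#'
#' @param C1,C2 deviatoric (stress-like) coefficients, MPa.
#' @param D1 volumetric parameter (see Details).
#' @param volumetric `"inverse"` (default) or `"direct"`.
#' @return an object of class `mooney_rivlin` with the effective volumetric
#'   coefficient in field `Dv`.
#' @examples
#' mat <- mooney_rivlin()
#' mr_energy(diag(3), mat)  # zero at the reference configuration
#' @export
mooney_rivlin <- function(C1 = 27.56, C2 = 6.89, D1 = 0.0029,
                          volumetric = c("inverse", "direct")) {
  volumetric <- match.arg(volumetric)
  stopifnot(C1 > 0, C2 >= 0, D1 > 0)
  Dv <- if (volumetric == "inverse") 1 / D1 else D1
  structure(list(C1 = C1, C2 = C2, D1 = D1, Dv = Dv,
                 volumetric = volumetric), class = "mooney_rivlin")
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf(
    "Mooney-Rivlin material: C1 = %g MPa, C2 = %g MPa, D1 = %g (%s)\n",
    x$C1, x$C2, x$D1, x$volumetric))
  cat(sprintf("  volumetric coefficient %g MPa, bulk modulus %g MPa\n",
              x$Dv, 2 * x$Dv))
  cat(sprintf("  incompressible-limit tangent modulus 6(C1+C2) = %g MPa\n",
              6 * (x$C1 + x$C2)))
  invisible(x)
}

#' Prony relaxation series
#'
#' Normalised shear and bulk relaxation moduli
#' \deqn{G(t)/G_0 = 1 - \sum_i \bar g_i (1 - e^{-t/\tau_i}),}
#' and likewise for \eqn{K(t)/K_0} with weights \eqn{\bar k_i}.  Relaxation
#' times are shared between the shear and bulk branches.
#'
#' @param shear dimensionless shear weights \eqn{\bar g_i}, each in `[0, 1)`,
#'   summing to less than 1.
#' @param bulk dimensionless bulk weights \eqn{\bar k_i}.
#' @param tau relaxation times, seconds.
#' @return an object of class `prony_series`.
#' @export
prony_series <- function(shear = c(0.2, 0.1), bulk = c(0.5, 0.2),
                         tau = c(0.1, 0.2)) {
  stopifnot(length(shear) == length(tau), length(bulk) == length(tau),
            all(shear >= 0), all(shear < 1), sum(shear) < 1,
            all(bulk >= 0), all(bulk < 1), sum(bulk) < 1, all(tau > 0))
  structure(list(shear = shear, bulk = bulk, tau = tau), class = "prony_series")
}

#' Invariants of a right Cauchy-Green tensor
#'
#' @param C symmetric positive-definite 3x3 matrix (or a length-3 vector of
#'   principal stretches \eqn{\lambda_i}, in which case `C = diag(lambda^2)`).
#' @return list with `I1`, `I2`, `J`, and the isochoric `I1_bar`, `I2_bar`.
#' @export
invariants_of <- function(C) {
  C <- as_cauchy_green(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("invalid kinematics: C must be positive definite")
  I1 <- sum(ev)
  I2 <- ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]
  J <- sqrt(prod(ev))
  list(I1 = I1, I2 = I2, J = J,
       I1_bar = J^(-2 / 3) * I1, I2_bar = J^(-4 / 3) * I2)
}

as_cauchy_green <- function(C) {
  if (is.vector(C) && length(C) == 3L) {
    if (any(C <= 0)) stop("invalid kinematics: stretches must be positive")
    return(diag(C^2))
  }
  if (!is.matrix(C) || !all(dim(C) == c(3L, 3L)))
    stop("C must be a 3x3 matrix or a length-3 stretch vector")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("invalid kinematics: C must be symmetric")
  (C + t(C)) / 2
}

#' Mooney-Rivlin strain-energy density
#'
#' @inheritParams invariants_of
#' @param p a [mooney_rivlin()] parameter set.
#' @return energy density, MPa (zero at `C = diag(3)`).
#' @export
mr_energy <- function(C, p) {
  iv <- invariants_of(C)
  p$C1 * (iv$I1_bar - 3) + p$C2 * (iv$I2_bar - 3) + p$Dv * (iv$J - 1)^2
}

#' Mooney-Rivlin second Piola-Kirchhoff stress
#'
#' Closed-form \eqn{S = 2\,\partial w/\partial C} for the compressible
#' Mooney-Rivlin energy.  `parts = TRUE` returns the isochoric (shear-like)
#' and volumetric contributions separately; the Prony series acts on these
#' two parts independently in the viscoelastic update.
#'
#' @inheritParams mr_energy
#' @param parts return a list with `iso` and `vol` components instead of the
#'   total.
#' @return 3x3 symmetric stress matrix (MPa), or a list of two such matrices.
#' @export
mr_stress <- function(C, p, parts = FALSE) {
  C <- as_cauchy_green(C)
  iv <- invariants_of(C)
  Cinv <- solve(C)
  I3 <- diag(3)
  J <- iv$J
  dI1b <- J^(-2 / 3) * (I3 - iv$I1 / 3 * Cinv)
  dI2b <- J^(-4 / 3) * (iv$I1 * I3 - C - 2 * iv$I2 / 3 * Cinv)
  iso <- 2 * (p$C1 * dI1b + p$C2 * dI2b)
  vol <- 2 * p$Dv * (J - 1) * J * Cinv
  if (parts) list(iso = iso, vol = vol) else iso + vol
}

#' First Piola-Kirchhoff stress from a second Piola-Kirchhoff stress
#'
#' `P = F S`.  For the diagonal (principal-frame) kinematics used by the
#' biaxial simulator `F = diag(lambda)`.
#'
#' @param S second Piola-Kirchhoff stress, 3x3.
#' @param F deformation gradient, 3x3 (or length-3 principal stretches).
#' @export
pk1_from_pk2 <- function(S, F) {
  if (is.vector(F) && length(F) == 3L) F <- diag(F)
  F %*% S
}

#' Uniaxial Cauchy and nominal stress under exact incompressibility
#'
#' Eliminates the indeterminate pressure of the incompressible limit from the
#' condition of zero lateral stress:  for \eqn{\lambda_1 = \lambda},
#' \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}} the isochoric Mooney-Rivlin
#' response gives \eqn{\sigma = 2(C_1 + C_2/\lambda)(\lambda^2 -
#' \lambda^{-1})} and the nominal (first Piola-Kirchhoff) stress
#' \eqn{P = \sigma/\lambda}.  The volumetric coefficient plays no role.
#'
#' @param lambda axial stretch (vectorised).
#' @param p a [mooney_rivlin()] parameter set.
#' @return list with `cauchy` and `nominal` stress vectors, MPa.
#' @export
uniaxial_stress_incompressible <- function(lambda, p) {
  stopifnot(all(lambda > 0))
  sigma <- 2 * (p$C1 + p$C2 / lambda) * (lambda^2 - 1 / lambda)
  list(cauchy = sigma, nominal = sigma / lambda)
}

#' Instantaneous small-strain tangent modulus
#'
#' Central-difference slope of the incompressible uniaxial nominal stress at
#' zero strain; for a Mooney-Rivlin material this converges to
#' \eqn{6(C_1 + C_2)}.
#'
#' @inheritParams uniaxial_stress_incompressible
#' @param h stretch perturbation for the central difference.
#' @return modulus in MPa.
#' @export
tangent_modulus <- function(p = mooney_rivlin(), h = 1e-5) {
  s <- uniaxial_stress_incompressible(c(1 + h, 1 - h), p)$nominal
  (s[1] - s[2]) / (2 * h)
}

#' Normalised Prony relaxation functions
#'
#' @param t time(s), seconds, non-negative (vectorised).
#' @param prony a [prony_series()].
#' @return list with vectors `shear` (\eqn{G(t)/G_0}) and `bulk`
#'   (\eqn{K(t)/K_0}).
#' @export
prony_ratio <- function(t, prony) {
  if (any(t < 0)) stop("t must be non-negative")
  decay <- function(w) {
    vapply(t, function(ti) 1 - sum(w * (1 - exp(-ti / prony$tau))), 0)
  }
  list(shear = decay(prony$shear), bulk = decay(prony$bulk))
}
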