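#' @useDynLib softinverse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx dist median prcomp pnorm rlnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv modifyList
NULL

# classed error helper: all package errors inherit "softinverse_error"
si_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "softinverse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Shear modulus from Young's modulus
#'
#' Converts the Young's modulus `E` and Poisson's ratio `nu` of an isotropic
#' material to its shear modulus via `mu = E / (2 (1 + nu))`. For the
#' incompressible materials used throughout the benchmarks `nu = 0.5`, so
#' `mu = E / 3`.
#'
#' @param E Young's modulus in Pa. Must be non-negative.
#' @param nu Poisson's ratio, in `[0, 0.5]`.
#' @return Shear modulus in Pa.
#' @seealso [young_from_shear()] for the inverse conversion.
#' @export
#' @examples
#' shear_from_young(1e3, 0.5) # 333.33 Pa
shear_from_young <- function(E, nu) {
  if (any(E < 0)) si_stop("Young's modulus must be non-negative", "invalid_parameter")
  if (any(nu < 0 | nu > 0.5)) si_stop("Poisson's ratio must lie in [0, 0.5]", "invalid_parameter")
  E / (2 * (1 + nu))
}

#' Young's modulus from shear modulus
#'
#' Inverse of [shear_from_young()]: `E = 2 mu (1 + nu)`.
#'
#' @param mu Shear modulus in Pa. Must be non-negative.
#' @param nu Poisson's ratio, in `[0, 0.5]`.
#' @return Young's modulus in Pa.
#' @export
young_from_shear <- function(mu, nu) {
  if (any(mu < 0)) si_stop("shear modulus must be non-negative", "invalid_parameter")
  if (any(nu < 0 | nu > 0.5)) si_stop("Poisson's ratio must lie in [0, 0.5]", "invalid_parameter")
  2 * mu * (1 + nu)
}

#' Lame parameters from (E, nu)
#'
#' Classical linear-elastic relations, used to parameterize the
#' Saint Venant-Kirchhoff model. `nu` must be strictly below 0.5 (the first
#' Lame parameter diverges in the incompressible limit).
#'
#' @param E Young's modulus in Pa.
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @return A list with elements `lambda` and `mu` (both Pa).
#' @export
lame_parameters <- function(E, nu) {
  if (any(E < 0)) si_stop("Young's modulus must be non-negative", "invalid_parameter")
  if (any(nu < 0 | nu >= 0.5)) {
    si_stop("Poisson's ratio must lie in [0, 0.5) for Lame parameters", "invalid_parameter")
  }
  list(
    lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu = E / (2 * (1 + nu))
  )
}

#' Bulk modulus for the nearly-incompressible penalty
#'
#' The forward solver enforces incompressibility through a volumetric penalty
#' `kappa/2 (J - 1)^2` whose stiffness is derived from an effective Poisson's
#' ratio just below 0.5: `kappa = E / (3 (1 - 2 nu_eff))`.
#'
#' @param E Young's modulus in Pa.
#' @param nu_eff Effective Poisson's ratio, default 0.499.
#' @return Bulk modulus in Pa.
#' @export
bulk_modulus <- function(E, nu_eff = 0.499) {
  if (any(E < 0)) si_stop("Young's modulus must be non-negative", "invalid_parameter")
  if (any(nu_eff < 0 | nu_eff >= 0.5)) {
    si_stop("effective Poisson's ratio must lie in [0, 0.5)", "invalid_parameter")
  }
  E / (3 * (1 - 2 * nu_eff))
}

#' Material parameter set
#'
#' Bundles the per-region material description used by the forward solver:
#' Young's modulus, Poisson's ratio (0.5 for the incompressible soft
#' materials of the benchmarks), mass density, constitutive model, and - for
#' membrane structures - the thickness. Derived quantities are attached:
#' the shear modulus `mu = E / (2(1+nu))`, the penalty bulk modulus (from
#' `nu_eff`), and, when a thickness is present, the arterial stiffness
#' `AS = E * T` used to report valve leaflet properties.
#'
#' @param young_modulus Young's modulus `E` in Pa (> 0).
#' @param poisson_ratio Poisson's ratio `nu` in `[0, 0.5]`; default 0.5.
#' @param density Mass density in kg/m^3 (water/soft tissue is about 1000).
#'   Only exercised by the transient solver and body forces.
#' @param thickness Membrane thickness in mm, or `NULL` for solid bodies.
#' @param model Constitutive model, `"neo_hookean"` (default) or `"stvk"`.
#' @param nu_eff Effective Poisson's ratio for the volumetric penalty of the
#'   nearly-incompressible solid formulation; default 0.499.
#' @return An object of class `material_parameters`.
#' @export
#' @examples
#' material_parameters(1e3)                       # soft silicone-like solid
#' material_parameters(1e6, thickness = 0.3)      # healthy valve leaflet
material_parameters <- function(young_modulus, poisson_ratio = 0.5,
                                density = 1000, thickness = NULL,
                                model = c("neo_hookean", "stvk"),
                                nu_eff = 0.499) {
  model <- match.arg(model)
  if (!is.numeric(young_modulus) || length(young_modulus) != 1 || young_modulus <= 0) {
    si_stop("young_modulus must be a single positive number", "invalid_parameter")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    si_stop("poisson_ratio must lie in [0, 0.5]", "invalid_parameter")
  }
  if (!is.null(thickness) && thickness <= 0) {
    si_stop("thickness must be positive when supplied", "invalid_parameter")
  }
  out <- list(
    young_modulus = young_modulus,
    poisson_ratio = poisson_ratio,
    shear_modulus = shear_from_young(young_modulus, poisson_ratio),
    bulk_modulus = bulk_modulus(young_modulus, nu_eff),
    density = density,
    thickness = thickness,
    arterial_stiffness = if (!is.null(thickness)) young_modulus * thickness else NULL,
    model = model,
    nu_eff = nu_eff
  )
  class(out) <- "material_parameters"
  out
}

#' @exportS3Method base::print
print.material_parameters <- function(x, ...) {
  cat(sprintf("<material_parameters> %s: E = %.6g Pa, nu = %g, mu = %.6g Pa",
              x$model, x$young_modulus, x$poisson_ratio, x$shear_modulus))
  if (!is.null(x$thickness)) {
    cat(sprintf(", T = %g mm, AS = %.6g Pa*mm", x$thickness, x$arterial_stiffness))
  }
  cat("\n")
  invisible(x)
}

#' Incompressible Neo-Hookean strain energy density
#'
#' `W = mu/2 (lambda1^2 + lambda2^2 + lambda3^2 - 3)` with `lambda_i` the
#' principal stretches. Non-negative on the incompressible manifold
#' `lambda1 lambda2 lambda3 = 1` and zero only in the reference state.
#'
#' @param stretches Numeric vector of the three principal stretches (all > 0).
#' @param mu Shear modulus in Pa.
#' @return Strain energy per unit reference volume (Pa).
#' @export
#' @examples
#' neo_hookean_energy(c(1, 1, 1), 5)          # 0 at the reference state
#' neo_hookean_energy(c(2, 2^-0.5, 2^-0.5), 2) # 2: uniaxial incompressible
neo_hookean_energy <- function(stretches, mu) {
  if (length(stretches) != 3 || any(!is.finite(stretches)) || any(stretches <= 0)) {
    si_stop("principal stretches must be three positive finite numbers", "invalid_state")
  }
  mu / 2 * (sum(stretches^2) - 3)
}

#' Nearly-incompressible Neo-Hookean energy (penalty form)
#'
#' The form assembled by the finite-element solver: an isochoric Neo-Hookean
#' term plus a volumetric penalty,
#' `W = mu/2 (J^{-2/3} I1 - 3) + kappa/2 (J - 1)^2`,
#' with `I1 = tr(F^T F)` and `J = det F`. As `kappa -> Inf` this converges to
#' the exact-incompressible law of [neo_hookean_energy()].
#'
#' @param F Deformation gradient, a 3x3 matrix with positive determinant.
#' @param mu Shear modulus in Pa.
#' @param kappa Penalty bulk modulus in Pa.
#' @return Strain energy per unit reference volume (Pa).
#' @export
neo_hookean_penalty_energy <- function(F, mu, kappa) {
  F <- as.matrix(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) si_stop("det(F) must be positive", "invalid_state")
  I1 <- sum(F^2)
  mu / 2 * (J^(-2 / 3) * I1 - 3) + kappa / 2 * (J - 1)^2
}

#' Cauchy stress of the incompressible Neo-Hookean model
#'
#' For an isochoric deformation gradient `F` (det F = 1 within `tol`) and a
#' pressure-like Lagrange multiplier `p`, the Cauchy stress is
#' `sigma = mu F F^T - p I`, the push-forward of the second Piola-Kirchhoff
#' stress expressed along the principal stretch directions. At `F = I` with
#' `p = mu` the body is stress free; the stress is objective under rigid
#' rotations of `F`.
#'
#' @param F Deformation gradient, 3x3 with `|det F - 1| <= tol`.
#' @param mu Shear modulus in Pa.
#' @param p Incompressibility pressure in Pa.
#' @param tol Tolerance on the isochoric constraint; default 1e-8.
#' @return Symmetric 3x3 Cauchy stress tensor (Pa).
#' @export
neo_hookean_cauchy_stress <- function(F, mu, p, tol = 1e-8) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3))) si_stop("F must be 3x3", "invalid_state")
  J <- det(F)
  if (!is.finite(J) || abs(J - 1) > tol) {
    si_stop(sprintf("incompressibility violated: |det F - 1| = %.3g > %.3g",
                    abs(J - 1), tol), "incompressibility_violation")
  }
  mu * (F %*% t(F)) - p * diag(3)
}

#' Second Piola-Kirchhoff stress of the Saint Venant-Kirchhoff model
#'
#' `S = lambda tr(E) I + 2 mu E` for a symmetric Green-Lagrange strain `E`;
#' linear in the strain. Used for the cross-model generality test in which
#' the observation is generated with one constitutive law and the inversion
#' runs another.
#'
#' @param green_strain Symmetric 3x3 Green-Lagrange strain tensor.
#' @param lame_lambda First Lame parameter in Pa.
#' @param mu Shear modulus (second Lame parameter) in Pa.
#' @param tol Symmetry tolerance; default 1e-10 relative.
#' @return Symmetric 3x3 second Piola-Kirchhoff stress tensor (Pa).
#' @export
stvk_pk2_stress <- function(green_strain, lame_lambda, mu, tol = 1e-10) {
  E <- as.matrix(green_strain)
  if (!all(dim(E) == c(3, 3))) si_stop("green_strain must be 3x3", "invalid_state")
  scale <- max(abs(E), 1)
  if (max(abs(E - t(E))) > tol * scale) {
    si_stop("green_strain must be symmetric", "invalid_state")
  }
  lame_lambda * sum(diag(E)) * diag(3) + 2 * mu * E
}
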