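# Abnormal-region parameterizations: an axis-aligned brick (beam benchmark)
# and a revolved Fourier-perturbed curve (balloon and valve benchmarks).
# Elements are labelled "abnormal" when their centroid lies inside the
# region (boundary inclusive), which makes label counts exact and
# deterministic for a given mesh.

#' Brick abnormality specification
#'
#' A stiff inclusion spanning the full cross-section of the beam over an
#' axial interval, described by its center position `C` and half-width `W`
#' along the beam axis. The experimental two-axis variant constrains both
#' the axial span (`C`, `W`) and the height span (`C_z`, `W_z`).
#'
#' @param center Axial center `C` in mm.
#' @param half_width Axial half-width `W` in mm (> 0 for a non-empty brick).
#' @param center_z,half_width_z Optional height-axis center/half-width (mm);
#'   when `NULL` the brick spans the full height.
#' @return A `brick_spec` object.
#' @export
#' @examples
#' brick_abnormality(40, 10) # 20 mm inclusion at the right end of a 50 mm beam
brick_abnormality <- function(center, half_width, center_z = NULL, half_width_z = NULL) {
  if (!is.finite(center) || !is.finite(half_width) || half_width < 0) {
    si_stop("brick needs finite center and non-negative half_width", "invalid_config")
  }
  structure(list(center = center, half_width = half_width,
                 center_z = center_z, half_width_z = half_width_z),
            class = c("brick_spec", "abnormality_spec"))
}

#' Revolved-curve abnormality specification
#'
#' The planar polar curve `R(theta) = R0 (1 + C1 cos(4 theta) + C2 cos(8 theta))`
#' revolved about the z-axis of a frame translated to `center`, producing an
#' axisymmetric star-like solid. `theta` is taken as the polar angle from
#' the local +z axis, so a point belongs to the region when its distance
#' from `center` is at most `R(theta)`. With `C1 = C2 = 0` the region is a
#' ball of radius `R0`.
#'
#' @param R0 Base radius in mm (> 0).
#' @param C1,C2 Fourier coefficients, each in `[-0.5, 0.5]` (the search
#'   bounds; also what keeps `R(theta)` positive).
#' @param center Length-3 offset `(P_x, P_y, P_z)` in mm.
#' @return A `revolved_spec` object.
#' @export
#' @examples
#' revolved_shape(41.2, 0.47, -0.35, c(-4.5, 62.1, 65.7)) # balloon truth
revolved_shape <- function(R0, C1 = 0, C2 = 0, center = c(0, 0, 0)) {
  if (!is.finite(R0) || R0 <= 0) si_stop("R0 must be positive", "invalid_config")
  if (abs(C1) > 0.5 || abs(C2) > 0.5) {
    si_stop("C1 and C2 must lie in [-0.5, 0.5]", "invalid_config")
  }
  if (length(center) != 3 || any(!is.finite(center))) {
    si_stop("center must be a finite length-3 vector", "invalid_config")
  }
  structure(list(R0 = R0, C1 = C1, C2 = C2, center = as.numeric(center)),
            class = c("revolved_spec", "abnormality_spec"))
}

#' Radius of the revolved generator curve
#'
#' Evaluates `R(theta) = R0 (1 + C1 cos(4 theta) + C2 cos(8 theta))`.
#'
#' @param theta Angle(s) in radians, measured from the revolution axis.
#' @param spec A [revolved_shape()] specification.
#' @return Radius in mm (vectorized over `theta`).
#' @export
revolved_radius <- function(theta, spec) {
  if (!inherits(spec, "revolved_spec")) si_stop("spec must be a revolved_spec", "invalid_config")
  spec$R0 * (1 + spec$C1 * cos(4 * theta) + spec$C2 * cos(8 * theta))
}

#' Point membership in a revolved abnormality region
#'
#' A point belongs to the solid of revolution when, after translating by
#' `-center`, its spherical radius does not exceed `R(theta)` at its polar
#' angle `theta` (from the +z axis). The boundary is inclusive.
#'
#' @param points A length-3 vector or an `n x 3` matrix of coordinates (mm).
#' @param spec A [revolved_shape()].
#' @return Logical vector of length `n`.
#' @export
point_in_revolved_region <- function(points, spec) {
  if (!inherits(spec, "revolved_spec")) si_stop("spec must be a revolved_spec", "invalid_config")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  p <- sweep(points, 2, spec$center)
  rho <- sqrt(rowSums(p^2))
  theta <- ifelse(rho > 0, acos(pmin(1, pmax(-1, p[, 3] / pmax(rho, 1e-300)))), 0)
  rho <= revolved_radius(theta, spec)
}

#' Label mesh elements by abnormality membership
#'
#' Marks an element `"abnormal"` when its centroid lies inside the given
#' abnormality region, `"base"` otherwise. Labelling is deterministic and
#' independent of element order; an empty abnormal set is legal (the
#' candidate simply degenerates to a homogeneous body).
#'
#' @param mesh An `fe_mesh`.
#' @param spec A [brick_abnormality()] or [revolved_shape()].
#' @return The mesh with its `region` labels replaced.
#' @export
label_elements <- function(mesh, spec) {
  cent <- element_centroids(mesh)
  inside <- if (inherits(spec, "brick_spec")) {
    ok <- abs(cent[, 1] - spec$center) <= spec$half_width
    if (!is.null(spec$center_z)) {
      ok <- ok & abs(cent[, 3] - spec$center_z) <= spec$half_width_z
    }
    ok
  } else if (inherits(spec, "revolved_spec")) {
    point_in_revolved_region(cent, spec)
  } else {
    si_stop("unknown abnormality spec", "invalid_config")
  }
  mesh$region <- ifelse(inside, "abnormal", "base")
  mesh
}
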