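# Shape-recovery scoring. Abnormal regions recovered on a curved body are
# compared as 2-D binary masks: balloon patches through an equirectangular
# spherical-map projection of the northern hemisphere, valve patches
# through a PCA plane projection, both scored with the structural
# similarity index (SSIM).

new_binary_mask <- function(values, projection) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(values, class = "binary_mask", projection = projection)
}

#' Spherical-map projection of abnormal surface elements
#'
#' Rasterizes the abnormal-region labels of a spherical shell mesh onto an
#' equirectangular grid of the northern hemisphere: columns span azimuth
#' `[-pi, pi)`, rows span polar angle `[0, pi/2]` (pole at the first row).
#' Each pixel takes the label of the nearest element centroid in
#' great-circle distance.
#'
#' @param mesh A labelled spherical shell `fe_mesh` (node radii must be
#'   uniform to within 10%).
#' @param hemisphere Only `"north"` is supported.
#' @param resolution Grid size (resolution x resolution); default 128.
#' @return A `binary_mask` matrix of 0/1 values.
#' @export
spherical_projection <- function(mesh, hemisphere = "north", resolution = 128) {
  hemisphere <- match.arg(hemisphere, "north")
  r <- sqrt(rowSums(mesh$nodes^2))
  if (sd(r) / mean(r) > 0.1) {
    si_stop("mesh is not a (near-)spherical shell", "invalid_input")
  }
  cent <- element_centroids(mesh)
  cr <- sqrt(rowSums(cent^2))
  theta_c <- acos(pmin(1, pmax(-1, cent[, 3] / cr)))
  phi_c <- atan2(cent[, 2], cent[, 1])
  lab <- as.numeric(mesh$region == "abnormal")
  phi_g <- -pi + (seq_len(resolution) - 0.5) * (2 * pi / resolution)
  theta_g <- (seq_len(resolution) - 0.5) * (pi / 2 / resolution)
  # unit vectors of centroids and of every grid point; nearest by max dot
  cu <- cbind(sin(theta_c) * cos(phi_c), sin(theta_c) * sin(phi_c), cos(theta_c))
  out <- matrix(0, resolution, resolution)
  st <- sin(theta_g); ct <- cos(theta_g)
  for (i in seq_len(resolution)) {
    gu <- cbind(st[i] * cos(phi_g), st[i] * sin(phi_g), rep(ct[i], resolution))
    dots <- gu %*% t(cu)
    out[i, ] <- lab[max.col(dots, ties.method = "first")]
  }
  new_binary_mask(out, list(type = "spherical_north", resolution = resolution))
}

#' PCA plane projection of a point set
#'
#' Projects 3-D points (typically abnormal-element centroids) onto their
#' two leading principal axes and rasterizes the result as a binary mask.
#' When `ref_points` is supplied, the axes, the axis signs and the raster
#' window are fitted on the union of both sets, so that a ground-truth and
#' an estimated point cloud are projected into directly comparable masks.
#' Axis signs are fixed by requiring a positive score for the first point
#' of the (union) set, removing the reflection ambiguity of PCA.
#'
#' @param points `n x 3` matrix (n >= 3, not all collinear).
#' @param ref_points Optional second point set included in the axis fit.
#' @param resolution Raster grid size; default 128.
#' @param radius Stamp radius around each projected point, in projected
#'   units; default 1.5 x the median nearest-neighbour distance of the
#'   union scores.
#' @return A `binary_mask`.
#' @export
pca_projection <- function(points, ref_points = NULL, resolution = 128,
                           radius = NULL) {
  points <- rbind(points)
  union <- rbind(points, ref_points)
  if (nrow(union) < 3) si_stop("need at least 3 points", "invalid_input")
  pc <- prcomp(union, center = TRUE, rank. = 2)
  if (pc$sdev[2] < 1e-12 * max(pc$sdev[1], 1e-300)) {
    si_stop("degenerate (collinear) point set", "invalid_input")
  }
  rot <- pc$rotation
  su <- scale(union, center = pc$center, scale = FALSE) %*% rot
  for (k in 1:2) if (su[1, k] < 0) { rot[, k] <- -rot[, k]; su[, k] <- -su[, k] }
  s <- scale(points, center = pc$center, scale = FALSE) %*% rot
  if (is.null(radius)) {
    dd <- as.matrix(dist(su))
    diag(dd) <- Inf
    radius <- 1.5 * median(apply(dd, 1, min))
  }
  lim <- apply(su, 2, range)
  pad <- radius + 1e-9
  xs <- seq(lim[1, 1] - pad, lim[2, 1] + pad, length.out = resolution)
  ys <- seq(lim[1, 2] - pad, lim[2, 2] + pad, length.out = resolution)
  out <- matrix(0, resolution, resolution)
  r2 <- radius^2
  for (p in seq_len(nrow(s))) {
    dx2 <- (xs - s[p, 1])^2
    dy2 <- (ys - s[p, 2])^2
    hit_x <- which(dx2 <= r2)
    if (length(hit_x) == 0) next
    for (ix in hit_x) {
      out[ix, dx2[ix] + dy2 <= r2] <- 1
    }
  }
  new_binary_mask(out, list(type = "pca_plane", resolution = resolution,
                            radius = radius))
}

# 'valid' 2-D convolution with a small kernel via shift-accumulate
conv2_valid <- function(x, w) {
  k <- nrow(w)
  n <- nrow(x) - k + 1
  m <- ncol(x) - k + 1
  if (n < 1 || m < 1) si_stop("mask smaller than the SSIM window", "invalid_input")
  out <- matrix(0, n, m)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    out <- out + w[a, b] * x[a:(a + n - 1), b:(b + m - 1)]
  }
  out
}

#' Structural similarity index between two masks
#'
#' Standard SSIM with a Gaussian window (sigma = 1.5, 7 x 7 by default),
#' stabilizing constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with dynamic
#' range `L = 1`, averaged over all (valid) window positions. Returns 1
#' for identical inputs and is symmetric. The score depends on the raster
#' resolution and window, which the mask records in its projection
#' descriptor.
#'
#' @param mask_a,mask_b Equal-shaped numeric matrices (typically 0/1).
#' @param K1,K2 Stabilizer fractions; defaults 0.01 and 0.03.
#' @param L Dynamic range; default 1.
#' @param window Odd window size; default 7.
#' @param sigma Gaussian window width; default 1.5.
#' @return SSIM score in `[-1, 1]`.
#' @export
#' @examples
#' m <- matrix(c(0, 1), 16, 16)
#' ssim(m, m) # 1
ssim <- function(mask_a, mask_b, K1 = 0.01, K2 = 0.03, L = 1,
                 window = 7, sigma = 1.5) {
  a <- as.matrix(mask_a); b <- as.matrix(mask_b)
  if (!all(dim(a) == dim(b))) si_stop("masks must have identical shapes", "invalid_input")
  half <- (window - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- outer(g, g)
  w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu_a <- conv2_valid(a, w); mu_b <- conv2_valid(b, w)
  va <- conv2_valid(a * a, w) - mu_a^2
  vb <- conv2_valid(b * b, w) - mu_b^2
  vab <- conv2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * vab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}
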