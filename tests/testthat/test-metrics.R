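# Shape-recovery scoring: SSIM, spherical map projection, PCA projection.

test_that("SSIM is 1 for identical masks, symmetric, and bounded", {
  set.seed(51)
  a <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  b <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-14)
  expect_gte(ssim(a, b), -1)
  expect_lte(ssim(a, b), 1)
  expect_lt(ssim(a, b), 1)
  expect_error(ssim(a, b[1:16, ]), class = "invalid_input")
})

test_that("SSIM of constant masks matches the closed form", {
  ones <- matrix(1, 16, 16)
  zeros <- matrix(0, 16, 16)
  # both local variances vanish: SSIM = (C1 / (1 + C1)) * 1
  C1 <- 0.01^2
  expect_equal(ssim(ones, zeros), C1 / (1 + C1), tolerance = 1e-12)
  expect_equal(ssim(zeros, zeros), 1)
})

test_that("a structured mask scores poorly against its complement", {
  set.seed(53)
  a <- matrix(0, 48, 48)
  a[12:36, 12:36] <- 1 # coherent block, not pure noise
  expect_lt(ssim(a, 1 - a), 0.5)
})

test_that("spherical projection reproduces trivial and cap masks", {
  m <- build_sphere_mesh(100, 3, 2)
  m$region <- rep("base", nrow(m$elems))
  expect_true(all(spherical_projection(m, resolution = 64) == 0))
  m$region <- rep("abnormal", nrow(m$elems))
  expect_true(all(spherical_projection(m, resolution = 64) == 1))
  # polar cap of half-angle 30 degrees: top rows set, area fraction ~ 1 - cos(30)
  cap <- label_elements(m, revolved_shape(2 * 100 * sin(pi / 12), 0, 0,
                                          center = c(0, 0, 100)))
  msk <- spherical_projection(cap, resolution = 128)
  theta <- (seq_len(128) - 0.5) * (pi / 2) / 128
  w <- sin(theta) # area weight per polar row
  frac <- sum(msk * w) / (128 * sum(w))
  expect_equal(frac, 1 - cos(pi / 6), tolerance = 0.05 * 1)
  # top rows (well inside the cap) fully set, bottom rows clear
  expect_true(all(msk[1:10, ] == 1))
  expect_true(all(msk[100:128, ] == 0))
  expect_error(spherical_projection(build_beam_mesh(), resolution = 32),
               class = "invalid_input")
})

test_that("spherical projection conserves the abnormal area fraction within 5%", {
  m <- build_sphere_mesh(100, 3, 2)
  lab <- label_elements(m, revolved_shape(41.2, 0.47, -0.35, c(-4.5, 62.1, 65.7)))
  msk <- spherical_projection(lab, resolution = 128)
  # element-area fraction restricted to the northern hemisphere
  cent <- element_centroids(lab)
  north <- cent[, 3] > 0
  areas <- element_measures(lab)
  elem_frac <- sum(areas[north & lab$region == "abnormal"]) / sum(areas[north])
  theta <- (seq_len(128) - 0.5) * (pi / 2) / 128
  w <- sin(theta)
  mask_frac <- sum(msk * w) / (128 * sum(w))
  expect_equal(mask_frac, elem_frac, tolerance = 0.05)
})

test_that("PCA projection is consistent for identical and coplanar point sets", {
  set.seed(57)
  pts <- cbind(rnorm(40), rnorm(40), 0)
  # coplanar: the two leading axes span the plane exactly
  pc <- prcomp(pts)
  expect_lt(pc$sdev[3], 1e-12)
  m1 <- pca_projection(pts, resolution = 64)
  m2 <- pca_projection(pts, resolution = 64)
  expect_identical(unclass(m1), unclass(m2))
  expect_equal(ssim(m1, m2), 1)
  expect_error(pca_projection(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               class = "invalid_input")
})

test_that("PCA mask pair on shared axes scores rotated copies as identical", {
  set.seed(59)
  pts <- cbind(rnorm(60), 0.5 * rnorm(60), 0.1 * rnorm(60))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- pts %*% R
  # same cloud rigidly rotated in-plane: projections onto shared axes match
  m1 <- pca_projection(pts, ref_points = pts, resolution = 64)
  m2 <- pca_projection(rot, ref_points = rot, resolution = 64)
  expect_equal(ssim(m1, m2), 1, tolerance = 0.02)
})
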