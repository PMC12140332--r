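# Constitutive laws: conversions, energies, stresses, and their
# consistency/objectivity properties.

test_that("shear modulus conversion matches E / (2(1+nu)) and round-trips", {
  expect_equal(shear_from_young(1e3, 0.5), 1e3 / 3, tolerance = 1e-12)
  expect_equal(shear_from_young(0, 0.5), 0)
  expect_equal(shear_from_young(1e6, 0.5), 1e6 / 3, tolerance = 1e-12)
  # exact inverse pair over a range of moduli and ratios
  set.seed(11)
  for (i in 1:20) {
    E <- 10^runif(1, 2, 10)
    nu <- runif(1, 0, 0.5)
    expect_equal(young_from_shear(shear_from_young(E, nu), nu), E,
                 tolerance = 1e-13)
  }
  expect_error(shear_from_young(-1, 0.3), class = "invalid_parameter")
  expect_error(shear_from_young(1e3, 0.6), class = "invalid_parameter")
})

test_that("Neo-Hookean energy density matches hand-evaluated cases", {
  expect_equal(neo_hookean_energy(c(1, 1, 1), 123), 0)
  expect_equal(neo_hookean_energy(c(2, 2^-0.5, 2^-0.5), 2), 2, tolerance = 1e-12)
  # (1/2)(1.5^2 + 1/1.5^2 + 1 - 3) = 0.3472...
  expect_equal(neo_hookean_energy(c(1.5, 1 / 1.5, 1), 1), 0.347222222222,
               tolerance = 1e-10)
  expect_error(neo_hookean_energy(c(1, -1, 1), 1), class = "invalid_state")
  # non-negative on the incompressible manifold
  set.seed(7)
  for (i in 1:50) {
    expect_gte(neo_hookean_energy(random_incompressible_stretches(), 2), 0)
  }
})

test_that("incompressible Cauchy stress is stress-free at reference and objective", {
  expect_equal(neo_hookean_cauchy_stress(diag(3), 5, 5), matrix(0, 3, 3))
  set.seed(13)
  for (i in 1:20) {
    R <- random_rotation()
    s <- neo_hookean_cauchy_stress(R, 3, 3)
    expect_lt(max(abs(s)), 1e-10)
  }
  expect_error(neo_hookean_cauchy_stress(2 * diag(3), 1, 1),
               class = "incompressibility_violation")
})

test_that("uniaxial incompressible stress matches sigma11 = mu (l^2 - 1/l)", {
  lam <- 2
  F <- diag(c(lam, lam^-0.5, lam^-0.5))
  mu <- 1
  p <- mu / lam # lateral stress vanishes
  s <- neo_hookean_cauchy_stress(F, mu, p)
  expect_equal(s[1, 1], 3.5, tolerance = 1e-12)
  expect_equal(s[2, 2], 0, tolerance = 1e-12)
  expect_equal(s[3, 3], 0, tolerance = 1e-12)
})

test_that("energy differentiation reproduces principal Kirchhoff terms mu lambda_i^2", {
  # sigma_i = lambda_i dW/dlambda_i - p; the energetic part is mu lambda_i^2
  set.seed(17)
  for (i in 1:20) {
    lam <- random_incompressible_stretches()
    mu <- runif(1, 0.5, 5)
    h <- 1e-6
    for (k in 1:3) {
      lp <- lam; lp[k] <- lp[k] + h
      lm <- lam; lm[k] <- lm[k] - h
      dW <- (neo_hookean_energy(lp, mu) - neo_hookean_energy(lm, mu)) / (2 * h)
      expect_equal(lam[k] * dW, mu * lam[k]^2, tolerance = 1e-6)
    }
  }
})

test_that("energy and stress are invariant under rigid rotations of F", {
  set.seed(19)
  for (i in 1:10) {
    lam <- random_incompressible_stretches()
    F <- diag(lam)
    R <- random_rotation()
    mu <- 2.5
    # energy via singular values of RF equals energy of F
    sv <- svd(R %*% F)$d
    expect_equal(neo_hookean_energy(sv, mu), neo_hookean_energy(lam, mu),
                 tolerance = 1e-10)
    # frobenius norm of the stress is rotation invariant
    s1 <- neo_hookean_cauchy_stress(F, mu, mu, tol = 1e-6)
    s2 <- neo_hookean_cauchy_stress(R %*% F, mu, mu, tol = 1e-6)
    expect_equal(sqrt(sum(s1^2)), sqrt(sum(s2^2)), tolerance = 1e-10)
  }
})

test_that("StVK second Piola-Kirchhoff stress is linear and matches closed form", {
  expect_equal(stvk_pk2_stress(matrix(0, 3, 3), 2, 3), matrix(0, 3, 3))
  E <- diag(c(0.1, 0, 0))
  expect_equal(stvk_pk2_stress(E, 0, 1), diag(c(0.2, 0, 0)), tolerance = 1e-14)
  set.seed(23)
  A <- matrix(rnorm(9), 3, 3); A <- (A + t(A)) / 2
  expect_equal(stvk_pk2_stress(2 * A, 1.7, 0.9),
               2 * stvk_pk2_stress(A, 1.7, 0.9), tolerance = 1e-12)
  expect_error(stvk_pk2_stress(matrix(rnorm(9), 3, 3), 1, 1),
               class = "invalid_state")
})

test_that("penalty energy approaches the exact incompressible law as kappa grows", {
  lam <- c(1.3, 1 / 1.3, 1)
  F <- diag(lam)
  mu <- 2
  expect_equal(neo_hookean_penalty_energy(F, mu, 1e6),
               neo_hookean_energy(lam, mu), tolerance = 1e-8)
  expect_error(neo_hookean_penalty_energy(diag(c(1, 1, -1)), 1, 1),
               class = "invalid_state")
})

test_that("material parameter sets validate inputs and derive AS = E * T", {
  mp <- material_parameters(1e6, thickness = 0.3)
  expect_equal(mp$arterial_stiffness, 3e5)
  expect_equal(mp$shear_modulus, 1e6 / 3, tolerance = 1e-12)
  expect_error(material_parameters(-1), class = "invalid_parameter")
  expect_error(material_parameters(1e3, poisson_ratio = 0.7),
               class = "invalid_parameter")
  expect_error(material_parameters(1e3, thickness = 0), class = "invalid_parameter")
})
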