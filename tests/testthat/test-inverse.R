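# Inverse pipeline: loss conventions, candidate simulation, and the
# identifiability floor in inverse-crime mode.

test_that("deformation loss is the squared norm, symmetric, and shape-checked", {
  D <- array(0, dim = c(2, 1, 3))
  Dh <- D
  Dh[2, 1, ] <- c(3, 4, 0)
  expect_equal(deformation_loss(D, D), 0)
  expect_equal(deformation_loss(D, Dh), 25)
  expect_equal(deformation_loss(Dh, D), deformation_loss(D, Dh))
  expect_error(deformation_loss(D, array(0, dim = c(3, 1, 3))),
               class = "invalid_input")
})

test_that("loss is invariant under consistent keypoint permutations", {
  set.seed(83)
  D <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  Dh <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  perm <- sample(4)
  expect_equal(deformation_loss(D[, perm, , drop = FALSE], Dh[, perm, , drop = FALSE]),
               deformation_loss(D, Dh), tolerance = 1e-12)
})

test_that("relative error follows |est - truth| / |truth|", {
  expect_equal(relative_error(1000, 1000), 0)
  expect_equal(relative_error(998, 1000), 0.002)
  expect_equal(relative_error(1.04e6, 1e6), 0.04)
  expect_error(relative_error(1, 0), class = "undefined_error")
})

test_that("simulating at the generating parameters reproduces the observation exactly", {
  case <- get_case("beam_case4", "desk")
  obs <- generate_observation(case)
  D_hat <- simulate_candidate(case, list())
  loss <- deformation_loss(obs$D, D_hat)
  expect_lte(loss, 1e-10 * (1 + sum(obs$D^2)))
})

test_that("degenerate abnormality specs give a valid homogeneous simulation", {
  case <- get_case("beam_case4", "desk")
  D0 <- simulate_candidate(case, list(W = 0))
  expect_false(is.null(D0))
  hom <- get_case("beam_case1", "desk")
  D_hom <- simulate_candidate(hom, list())
  expect_equal(D0, D_hom, tolerance = 1e-12)
})

test_that("the solver stays stable with the abnormal modulus at the upper bound", {
  case <- get_case("beam_case4", "desk")
  obs <- generate_observation(case)
  D_stiff <- simulate_candidate(case, list(E_a = 1e10))
  expect_false(is.null(D_stiff))
  expect_true(is.finite(deformation_loss(obs$D, D_stiff)))
})

test_that("cross-model observations are nearly reproducible by the other law", {
  # observation generated with Saint Venant-Kirchhoff, virtual twin runs
  # Neo-Hookean at the same parameters: the model-mismatch floor stays a
  # small fraction of the trajectory norm, so cross-model inversion is
  # well-posed for the shape (the stiff modulus saturates; see vignette)
  case <- get_case("beam_stvk", "desk")
  obs <- generate_observation(case)
  D_nh <- simulate_candidate(case, list())
  floor_loss <- deformation_loss(obs$D, D_nh)
  expect_lt(floor_loss, 0.02 * sum(obs$D^2))
  expect_gt(floor_loss, 0) # the two laws are genuinely different
})

test_that("run_inverse validates its contract", {
  case <- get_case("beam_case4", "desk")
  obs <- generate_observation(case)
  expect_error(run_inverse(case, obs, optimizer = bo_config(budget = 0)),
               class = "contract_violation")
})

test_that("a two-parameter inverse run is seed-reproducible end to end", {
  case <- get_case("beam_case2", "desk")
  obs <- generate_observation(case)
  cfg <- bo_config(q = 2, n0 = 4, budget = 8, seed = 123)
  r1 <- run_inverse(case, obs, optimizer = cfg)
  r2 <- run_inverse(case, obs, optimizer = cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$estimates, r2$estimates)
})
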