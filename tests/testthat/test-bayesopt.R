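# Batch Bayesian optimizer: surrogate, acquisition, temperatures,
# proposals, and the full loop on analytic objectives.

test_that("search spaces validate bounds and encode/decode round-trip", {
  sp <- search_space(c("E", "C"), c(1e2, 0), c(1e10, 50), c("log10", "linear"))
  x <- cbind(1e5, 25)
  z <- softinverse:::space_encode(sp, x)
  expect_equal(as.numeric(z), c(5, 25))
  expect_equal(as.numeric(softinverse:::space_decode(sp, z)), c(1e5, 25))
  expect_error(search_space("x", 1, 1), class = "invalid_config")
  expect_error(search_space("x", -1, 1, "log10"), class = "invalid_config")
})

test_that("surrogate reproduces constant targets with zero variance", {
  set.seed(61)
  X <- matrix(runif(20), 10, 2)
  s <- fit_surrogate(X, rep(3.5, 10), seed = 1)
  pr <- predict_surrogate(s, matrix(runif(10), 5, 2))
  expect_equal(pr$mean, rep(3.5, 5), tolerance = 1e-12)
  expect_equal(pr$var, rep(0, 5), tolerance = 1e-12)
  expect_error(fit_surrogate(matrix(1, 1, 2), 1), class = "insufficient_data")
})

test_that("surrogate variance is larger far from the training data", {
  # fixed seeded fixture: a smooth trend sampled on the unit square,
  # queried at training points vs extrapolation points outside the hull
  set.seed(63)
  X <- matrix(runif(80), 40, 2)
  L <- X[, 1] + X[, 2]
  s <- fit_surrogate(X, L, seed = 7)
  near <- predict_surrogate(s, X[1:10, , drop = FALSE])
  far <- predict_surrogate(s, matrix(c(1.5, 1.5, 2, 2, -0.5, -0.5), 3, 2,
                                     byrow = TRUE))
  expect_gte(mean(far$var), mean(near$var))
})

test_that("surrogate refits are deterministic given the seed", {
  set.seed(65)
  X <- matrix(runif(40), 20, 2)
  L <- rowSums(X^2)
  q <- matrix(runif(10), 5, 2)
  p1 <- predict_surrogate(fit_surrogate(X, L, seed = 42), q)
  p2 <- predict_surrogate(fit_surrogate(X, L, seed = 42), q)
  expect_identical(p1, p2)
})

test_that("MGF acquisition matches hand-evaluated cases", {
  # t = 0 reduces to the probability of improvement
  expect_equal(mgf_acquisition(0.5, 1, 1, 0), pnorm(0.5), tolerance = 1e-12)
  expect_equal(mgf_acquisition(0.5, 1, 1, 0), 0.69146, tolerance = 1e-5)
  # direct evaluation at t = 1: Phi(1) exp(-0.5)
  expect_equal(mgf_acquisition(1, 1, 1, 1), pnorm(1) * exp(-0.5), tolerance = 1e-12)
  expect_equal(mgf_acquisition(1, 1, 1, 1), 0.5103, tolerance = 1e-4)
  # s -> 0 with no predicted improvement: acquisition vanishes
  expect_equal(mgf_acquisition(2, 0, 1, 0.5), 0)
  expect_error(mgf_acquisition(1, 1, 1, -1), class = "invalid_parameter")
})

test_that("MGF acquisition equals probability of improvement at t = 0 on random states", {
  set.seed(67)
  for (i in 1:100) {
    m <- rnorm(1); v <- runif(1, 1e-6, 4); lmin <- rnorm(1)
    pi_direct <- pnorm((lmin - m) / sqrt(v))
    expect_equal(mgf_acquisition(m, v, lmin, 0), pi_direct, tolerance = 1e-12)
  }
})

test_that("temperature samples are positive with lognormal moments", {
  set.seed(69)
  t <- sample_temperature(1e5)
  expect_true(all(t > 0))
  expect_equal(median(t), 1, tolerance = 0.02)
  expect_equal(mean(t), exp(0.5), tolerance = 0.02)
})

test_that("batch proposals are in-bounds and reproducible", {
  set.seed(71)
  X <- matrix(runif(40, 0, 10), 20, 2)
  L <- rowSums((X - 3)^2)
  s <- fit_surrogate(X, L, seed = 5)
  sp <- search_space(c("a", "b"), c(0, 0), c(10, 10))
  set.seed(72)
  p1 <- propose_batch(s, sp, 8, min(L), X_eval = X, es_generations = 10)
  expect_equal(dim(p1$X), c(8, 2))
  expect_true(all(p1$X >= 0 & p1$X <= 10))
  expect_length(p1$t, 8)
  set.seed(72)
  p2 <- propose_batch(s, sp, 8, min(L), X_eval = X, es_generations = 10)
  expect_identical(p1, p2)
})

test_that("a 1-D acquisition with a unique maximum is found by the inner search", {
  # hand-built deterministic criterion: maximize -(z - 7.3)^2 on [0, 10]
  res <- softinverse:::es_maximize(function(Z) -(Z[, 1] - 7.3)^2, 0, 10,
                                   generations = 60)
  expect_equal(res$x, 7.3, tolerance = 1e-3)
})

test_that("the optimizer solves the quadratic and log-scale analytic problems", {
  sp <- search_space("x", 0, 10)
  res <- bo_minimize(function(x) (x[["x"]] - 3)^2, sp,
                     bo_config(q = 4, n0 = 8, budget = 60, seed = 1))
  expect_lte(abs(res$best$x - 3), 0.1)
  expect_equal(res$n_evaluations, 60)
  sp2 <- search_space("x", 1e2, 1e10, encoding = "log10")
  res2 <- bo_minimize(function(x) (log10(x[["x"]]) - 5)^2, sp2,
                      bo_config(q = 4, n0 = 8, budget = 60, seed = 1))
  expect_gte(res2$best$x, 10^4.9)
  expect_lte(res2$best$x, 10^5.1)
})

test_that("best-so-far trace is non-increasing and budget N = n0 returns the design best", {
  sp <- search_space(c("a", "b"), c(-5, -5), c(5, 5))
  f <- function(x) sum((unlist(x) - 1)^2)
  res <- bo_minimize(f, sp, bo_config(q = 4, n0 = 10, budget = 50, seed = 3))
  expect_true(all(diff(res$history$best_so_far) <= 0))
  res0 <- bo_minimize(f, sp, bo_config(q = 4, n0 = 10, budget = 10, seed = 3))
  expect_equal(res0$n_evaluations, 10)
  expect_equal(res0$iterations, 0)
  expect_equal(res0$best$loss, min(res0$history$loss))
})

test_that("runs are seed-deterministic and objective errors become +Inf", {
  sp <- search_space("x", 0, 1)
  f <- function(x) if (x[["x"]] > 0.9) stop("boom") else (x[["x"]] - 0.2)^2
  r1 <- suppressWarnings(bo_minimize(f, sp, bo_config(q = 2, n0 = 6, budget = 20, seed = 9)))
  r2 <- suppressWarnings(bo_minimize(f, sp, bo_config(q = 2, n0 = 6, budget = 20, seed = 9)))
  expect_identical(r1$history, r2$history)
  expect_true(any(!is.finite(r1$history$loss)) || all(r1$history$x <= 0.9))
  expect_lt(abs(r1$best$x - 0.2), 0.2)
})

test_that("parallel batch evaluation reproduces the sequential history", {
  sp <- search_space(c("a", "b"), c(0, 0), c(1, 1))
  f <- function(x) (x[["a"]] - 0.3)^2 + (x[["b"]] - 0.6)^2
  seq_run <- bo_minimize(f, sp, bo_config(q = 4, n0 = 6, budget = 26, seed = 4))
  par_run <- bo_minimize(f, sp, bo_config(q = 4, n0 = 6, budget = 26, seed = 4,
                                          workers = 2))
  expect_equal(par_run$history, seq_run$history, tolerance = 1e-15)
})
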