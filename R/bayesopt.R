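# Gradient-free batch Bayesian optimizer: random-forest surrogate,
# moment-generating-function (MGF) acquisition with lognormal temperature
# sampling, and a self-adaptive (mu+lambda) evolution strategy as the inner
# acquisition maximizer. The loop is batch-sequential: each iteration draws
# q temperatures, maximizes the q acquisition criteria, evaluates the q
# proposals, and refits the forest on the augmented data.

#' Search space
#'
#' Defines the optimizer's decision vector: one row per dimension with a
#' name, bounds and an encoding. Moduli-like dimensions spanning many
#' decades use the `"log10"` encoding (the optimizer then works in
#' log-space); geometric dimensions stay `"linear"`.
#'
#' @param names Character vector of dimension names.
#' @param lower,upper Numeric bounds in physical units; `lower < upper`,
#'   and strictly positive for log-encoded dimensions.
#' @param encoding Character vector, `"linear"` or `"log10"` per dimension
#'   (recycled).
#' @return A `search_space` object.
#' @export
#' @examples
#' search_space(c("E_b", "C"), c(1e2, 0), c(1e10, 50), c("log10", "linear"))
search_space <- function(names, lower, upper, encoding = "linear") {
  d <- length(names)
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  encoding <- rep_len(encoding, d)
  if (any(lower >= upper)) si_stop("need lower < upper in every dimension", "invalid_config")
  if (any(encoding == "log10" & lower <= 0)) {
    si_stop("log10 encoding requires strictly positive bounds", "invalid_config")
  }
  if (!all(encoding %in% c("linear", "log10"))) {
    si_stop("encoding must be 'linear' or 'log10'", "invalid_config")
  }
  structure(list(names = names, lower = lower, upper = upper, encoding = encoding),
            class = "search_space")
}

space_encode <- function(space, x) {
  x <- rbind(x)
  out <- x
  lg <- space$encoding == "log10"
  out[, lg] <- log10(x[, lg, drop = FALSE])
  out
}

space_decode <- function(space, z) {
  z <- rbind(z)
  out <- z
  lg <- space$encoding == "log10"
  out[, lg] <- 10^z[, lg, drop = FALSE]
  colnames(out) <- space$names
  out
}

space_bounds_encoded <- function(space) {
  lo <- space$lower; hi <- space$upper
  lg <- space$encoding == "log10"
  lo[lg] <- log10(lo[lg]); hi[lg] <- log10(hi[lg])
  list(lower = lo, upper = hi)
}

#' Fit the random-forest surrogate
#'
#' Trains a bootstrap random forest on the evaluated configurations (in
#' encoded coordinates) and their losses. Predictions expose both the
#' forest mean and the empirical variance of the individual tree
#' predictions, which serves as the surrogate uncertainty in the MGF
#' acquisition. Non-finite losses (failed forward solves) are replaced for
#' fitting by ten times the largest finite loss, so failed regions repel
#' the search without poisoning the fit.
#'
#' @param X Matrix of evaluated configurations, `n x d`, encoded coordinates.
#' @param L Numeric vector of losses (length `n`, may contain `Inf`).
#' @param num_trees Number of trees; default 100.
#' @param seed Integer seed for the forest's bootstrap; default 1.
#' @return An `rf_surrogate` object with a [predict_surrogate()] method.
#' @export
fit_surrogate <- function(X, L, num_trees = 100, seed = 1L) {
  X <- rbind(X)
  if (nrow(X) < 2) si_stop("surrogate needs at least 2 evaluated points", "insufficient_data")
  Lfit <- L
  bad <- !is.finite(Lfit)
  if (any(bad)) {
    # failed evaluations are placed just above the worst observed loss:
    # clearly repulsive, without an outlier magnitude that would soak up
    # the forest's split resolution
    if (all(bad)) {
      Lfit[bad] <- 1
    } else {
      fin <- Lfit[!bad]
      Lfit[bad] <- max(fin) + max(1, 0.25 * diff(range(fin)))
    }
  }
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$y <- Lfit
  fit <- ranger::ranger(
    y ~ ., data = df, num.trees = num_trees, mtry = ncol(X),
    min.node.size = 2, seed = seed, num.threads = 1
  )
  structure(list(fit = fit, d = ncol(X)), class = "rf_surrogate")
}

#' Predict mean and tree variance of the surrogate
#'
#' @param surrogate An `rf_surrogate` from [fit_surrogate()].
#' @param X Matrix of query points (encoded coordinates), `m x d`.
#' @return List with numeric vectors `mean` and `var` (variance across
#'   trees, always >= 0).
#' @export
predict_surrogate <- function(surrogate, X) {
  X <- rbind(X)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  preds <- predict(surrogate$fit, data = df, predict.all = TRUE,
                   num.threads = 1)$predictions
  preds <- rbind(preds) # m x ntree
  m <- rowMeans(preds)
  v <- apply(preds, 1, var)
  v[!is.finite(v)] <- 0
  list(mean = m, var = pmax(v, 0))
}

#' MGF acquisition criterion
#'
#' Moment-generating-function infill criterion for minimization:
#' `M(x, t) = Phi((Lmin - Lhat') / s) * exp((Lmin - Lhat - 1) t + s^2 t^2 / 2)`
#' with `Lhat' = Lhat - s^2 t`, where `Lhat` is the surrogate mean, `s^2`
#' its variance, `Lmin` the best observed loss and `t >= 0` a temperature
#' trading exploration (large `t`) against exploitation (small `t`). At
#' `t = 0` it reduces to the probability of improvement. Larger is better.
#' Evaluation is performed in log space and clamped, so extreme arguments
#' never overflow.
#'
#' @param mean Surrogate mean(s) `Lhat`.
#' @param var Surrogate variance(s) `s^2` (>= 0; a floor of `s >= 1e-12`
#'   guards the division).
#' @param L_min Best loss over all evaluated configurations.
#' @param t Temperature (>= 0).
#' @param log If `TRUE` return the log-acquisition (preferred for ranking).
#' @return Acquisition value(s), same length as `mean`.
#' @export
#' @examples
#' mgf_acquisition(0.5, 1, 1, 0) # probability of improvement: pnorm(0.5)
mgf_acquisition <- function(mean, var, L_min, t, log = FALSE) {
  if (t < 0) si_stop("temperature must be >= 0", "invalid_parameter")
  s <- sqrt(pmax(var, 0))
  s <- pmax(s, 1e-12)
  lhat_p <- mean - s^2 * t
  logM <- pnorm((L_min - lhat_p) / s, log.p = TRUE) +
    (L_min - mean - 1) * t + s^2 * t^2 / 2
  if (log) logM else exp(pmin(logM, 700))
}

#' Sample an acquisition temperature
#'
#' Draws `n` temperatures from Lognormal(0, 1) (median 1, mean `exp(0.5)`),
#' the distribution the batch loop uses to diversify its `q` acquisition
#' criteria per iteration.
#'
#' @param n Number of draws; default 1.
#' @return Positive numeric vector of length `n`.
#' @export
sample_temperature <- function(n = 1) {
  rlnorm(n, meanlog = 0, sdlog = 1)
}

# (mu + lambda) self-adaptive evolution strategy maximizing fn over a box.
# fn must accept a matrix (rows = candidates) and return a numeric vector.
es_maximize <- function(fn, lower, upper, seed_points = NULL,
                        mu = 4, lambda = 28, generations = 50) {
  d <- length(lower)
  range <- upper - lower
  n_seed <- if (is.null(seed_points)) 0 else nrow(seed_points)
  pop <- sweep(sweep(matrix(runif(mu * d), mu, d), 2, range, `*`), 2, lower, `+`)
  if (n_seed > 0) {
    take <- min(mu - 1, n_seed)
    pop[seq_len(take), ] <- seed_points[seq_len(take), , drop = FALSE]
  }
  # per-individual per-dimension step sizes; log-uniform initial scales let
  # selection pick between coarse exploration and fine local refinement
  sig <- sweep(matrix(10^runif(mu * d, -5, -1), mu, d), 2, range, `*`)
  fit <- fn(pop)
  tau_g <- 1 / sqrt(2 * d)
  tau_l <- 1 / sqrt(2 * sqrt(d))
  for (g in seq_len(generations)) {
    parents <- sample.int(mu, lambda, replace = TRUE)
    csig <- sig[parents, , drop = FALSE] *
      exp(tau_g * rnorm(lambda) + tau_l * matrix(rnorm(lambda * d), lambda, d))
    csig <- pmin(csig, matrix(range, lambda, d, byrow = TRUE) * 0.5)
    child <- pop[parents, , drop = FALSE] + csig * matrix(rnorm(lambda * d), lambda, d)
    child <- pmin(pmax(child, matrix(lower, lambda, d, byrow = TRUE)),
                  matrix(upper, lambda, d, byrow = TRUE))
    cfit <- fn(child)
    allp <- rbind(pop, child)
    alls <- rbind(sig, csig)
    allf <- c(fit, cfit)
    keep <- order(allf, decreasing = TRUE)[seq_len(mu)]
    pop <- allp[keep, , drop = FALSE]
    sig <- alls[keep, , drop = FALSE]
    fit <- allf[keep]
  }
  list(x = pop[1, ], value = fit[1])
}

#' Propose a batch of candidate configurations
#'
#' Draws one temperature per batch member (or uses the fixed temperature),
#' then maximizes the corresponding MGF acquisition with the evolution
#' strategy, seeding part of each start population with the best evaluated
#' configurations. Proposals that duplicate an already-evaluated point are
#' re-mutated once and then accepted (the forest tolerates duplicates).
#'
#' @param surrogate An `rf_surrogate`.
#' @param space A [search_space()].
#' @param q Batch size (>= 1).
#' @param L_min Best observed loss.
#' @param X_eval Matrix of already-evaluated configurations (encoded), used
#'   for incumbent seeding and duplicate detection; may be `NULL`.
#' @param L_eval Losses of `X_eval` (identifies the incumbent used to
#'   re-anchor duplicate proposals); may be `NULL`.
#' @param t_mode `"sampled"` (Lognormal(0,1) per member) or `"fixed"`.
#' @param t_fixed Temperature used when `t_mode = "fixed"`; default 2.
#' @param es_generations Generations of the inner evolution strategy.
#' @return List with `X` (q x d encoded matrix) and `t` (temperatures).
#' @export
propose_batch <- function(surrogate, space, q, L_min, X_eval = NULL,
                          L_eval = NULL,
                          t_mode = c("sampled", "fixed"), t_fixed = 2,
                          es_generations = 50) {
  t_mode <- match.arg(t_mode)
  b <- space_bounds_encoded(space)
  d <- length(b$lower)
  rng <- b$upper - b$lower
  seeds <- NULL
  x_best <- NULL
  d_loc <- NULL
  if (!is.null(X_eval) && nrow(X_eval) > 0) {
    ord <- if (!is.null(L_eval)) {
      order(ifelse(is.finite(L_eval), L_eval, Inf))
    } else {
      order(predict_surrogate(surrogate, X_eval)$mean)
    }
    seeds <- X_eval[ord[seq_len(min(3, nrow(X_eval)))], , drop = FALSE]
    x_best <- X_eval[ord[1], ]
    if (nrow(X_eval) > 1) {
      # local sample spacing at the incumbent (normalized coordinates):
      # proposals that cannot add resolution at this spacing are treated as
      # duplicates and re-anchored below
      Z <- sweep(X_eval, 2, rng, `/`)
      dd <- sqrt(colSums((t(Z) - as.numeric(x_best / rng))^2))
      d_loc <- sort(dd)[min(4, length(dd))]
    }
  }
  # anchors for re-mutating redundant proposals: the incumbent plus a few of
  # the better evaluated points, so local search is not captive to a single
  # (possibly spurious) mode
  anchors <- NULL
  if (!is.null(X_eval) && nrow(X_eval) > 0 && !is.null(L_eval)) {
    ordL <- order(ifelse(is.finite(L_eval), L_eval, Inf))
    n_anchor <- min(max(3, ceiling(nrow(X_eval) / 10)), nrow(X_eval))
    anchors <- X_eval[ordL[seq_len(n_anchor)], , drop = FALSE]
  }
  n_random <- if (q >= 4) max(1, floor(q / 4)) else 0
  X <- matrix(0, q, d)
  ts <- numeric(q)
  for (i in seq_len(q)) {
    ts[i] <- if (t_mode == "sampled") sample_temperature(1) else t_fixed
    if (i > q - n_random) {
      # interleaved uniform exploration. An improvement-based criterion can
      # never justify crossing a worse-than-incumbent ridge toward another
      # mode, so part of every batch samples unconditionally.
      X[i, ] <- b$lower + rng * runif(d)
      next
    }
    fn <- function(Z) {
      pr <- predict_surrogate(surrogate, Z)
      mgf_acquisition(pr$mean, pr$var, L_min, ts[i], log = TRUE)
    }
    res <- es_maximize(fn, b$lower, b$upper, seed_points = seeds,
                       generations = es_generations)
    x <- res$x
    if (!is.null(X_eval) && nrow(X_eval) > 0) {
      dmin <- min(sqrt(colSums((t(sweep(X_eval, 2, rng, `/`)) - x / rng)^2)))
      dup <- dmin <= max(1e-9, 0.5 * (d_loc %||% 0))
      if (dup) {
        # a proposal inside the already-resolved neighbourhood of the
        # incumbent adds nothing: re-mutate it once from an anchor at a
        # random scale tied to the local spacing. Small scales refine the
        # optimum geometrically; large ones probe along weakly-determined
        # directions the piecewise-constant forest cannot extrapolate over;
        # independent per-dimension scales keep resolved parameters while
        # probing unresolved ones.
        anchor <- if (!is.null(anchors) && nrow(anchors) > 1 && runif(1) < 0.3) {
          anchors[sample.int(nrow(anchors), 1), ]
        } else {
          x_best
        }
        # mutation scales: half the draws track the local sample spacing
        # (geometric refinement of the optimum), half are log-uniform up to
        # a tenth of the range so cell-jumping moves stay alive even after
        # the neighbourhood is resolved (discrete labelling plateaus need
        # order-element-size steps)
        dl <- log10(max(d_loc %||% 1e-3, 1e-9))
        draw <- function(n) {
          if (runif(1) < 0.5) 10^runif(n, dl - 1.5, dl + 0.5)
          else 10^runif(n, min(dl - 1.5, -5), -1)
        }
        if (runif(1) < 0.5) {
          # single-coordinate move: in anisotropic basins most progress
          # comes from changing one parameter while holding the resolved ones
          scale <- rep(0, d)
          keep <- sample.int(d, 1)
          scale[keep] <- draw(1)
        } else {
          scale <- draw(d)
        }
        scale <- pmin(scale, 0.1)
        x <- anchor + rng * scale * rnorm(d)
        x <- pmin(pmax(x, b$lower), b$upper)
      }
    }
    X[i, ] <- x
  }
  list(X = X, t = ts)
}

#' Optimizer configuration
#'
#' @param q Batch size per iteration; default 8.
#' @param n0 Initial (Latin hypercube) design size; default `2 d + 2`,
#'   resolved when the dimension is known.
#' @param budget Total evaluation budget `N` (initial design included).
#' @param seed Master seed controlling every random draw of the run.
#' @param t_mode Temperature mode, `"sampled"` (Lognormal(0,1)) or
#'   `"fixed"`.
#' @param t_fixed Fixed temperature when `t_mode = "fixed"`; default 2.
#' @param num_trees Trees in the random-forest surrogate; default 100.
#' @param tol Convergence tolerance on the loss: the loop stops early once
#'   the best loss is `<= tol`. Default 0 (run out the budget).
#' @param es_generations Generations of the inner evolution strategy.
#' @param loss_transform Scale on which the forest is trained and the
#'   acquisition evaluated: `"log10"` (default) fits `log10(loss + offset)`
#'   with `offset = max(tol, 1e-300)`, a variance-stabilizing transform
#'   without which the forest spends its resolution on the high-loss
#'   plateaus and cannot rank configurations near the optimum (losses span
#'   ten or more decades in the benchmarks); `"identity"` fits raw losses.
#'   Monotone, so the argmin is unaffected.
#' @param workers Parallel workers for batch evaluation (forked processes);
#'   default 1 (sequential). Results are identical either way for
#'   deterministic objectives.
#' @return A `bo_config` list.
#' @export
bo_config <- function(q = 8, n0 = NULL, budget = 60, seed = 1L,
                      t_mode = c("sampled", "fixed"), t_fixed = 2,
                      num_trees = 100, tol = 0, es_generations = 50,
                      loss_transform = c("log10", "identity"),
                      workers = 1) {
  t_mode <- match.arg(t_mode)
  loss_transform <- match.arg(loss_transform)
  if (q < 1) si_stop("q must be >= 1", "invalid_config")
  structure(list(q = q, n0 = n0, budget = budget, seed = as.integer(seed),
                 t_mode = t_mode, t_fixed = t_fixed, num_trees = num_trees,
                 tol = tol, es_generations = es_generations,
                 loss_transform = loss_transform, workers = workers),
            class = "bo_config")
}

#' Minimize a black-box objective by batch Bayesian optimization
#'
#' Runs the full surrogate loop: a seeded Latin-hypercube initial design in
#' encoded coordinates, then batch-sequential iterations that fit the
#' random forest, maximize `q` MGF acquisition criteria under independently
#' drawn temperatures, evaluate the proposals, and refit. Terminates when
#' the budget is exhausted or the best loss drops to the configured
#' tolerance. Objective errors are recorded as `+Inf` losses with a warning
#' and the run continues.
#'
#' @param objective Function taking a named numeric vector of physical
#'   parameter values and returning a scalar loss.
#' @param space A [search_space()].
#' @param config A [bo_config()].
#' @return List with `best` (named physical vector + `loss`), `history`
#'   (data frame: evaluation index, iteration, parameters, loss,
#'   temperature, best-so-far), `X` (encoded evaluations), `L` (losses),
#'   `n_evaluations` and `iterations`.
#' @export
bo_minimize <- function(objective, space, config = bo_config()) {
  d <- length(space$names)
  if (config$budget < 1) si_stop("budget must be >= 1", "contract_violation")
  n0 <- config$n0 %||% (2 * d + 2)
  n0 <- max(2, min(n0, config$budget))
  set.seed(config$seed)
  b <- space_bounds_encoded(space)

  eval_one <- function(z_enc) {
    x <- setNames(as.numeric(space_decode(space, z_enc)[1, ]), space$names)
    val <- tryCatch(as.numeric(objective(x)),
                    error = function(e) {
                      warning("objective evaluation failed: ", conditionMessage(e),
                              call. = FALSE)
                      Inf
                    })
    if (length(val) != 1 || is.na(val)) Inf else val
  }
  eval_batch <- function(Z) {
    rows <- lapply(seq_len(nrow(Z)), function(i) Z[i, ])
    if (config$workers > 1) {
      unlist(parallel::mclapply(rows, eval_one, mc.cores = config$workers))
    } else {
      vapply(rows, eval_one, numeric(1))
    }
  }

  U <- lhs::randomLHS(n0, d)
  X <- sweep(sweep(U, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  L <- eval_batch(X)
  temps <- rep(NA_real_, n0)
  iter_of <- rep(0L, n0)
  iteration <- 0L
  repeat {
    if (length(L) >= config$budget) break
    finiteL <- L[is.finite(L)]
    if (length(finiteL) > 0 && min(finiteL) <= config$tol) break
    if (length(finiteL) == 0 && length(L) >= config$budget) break
    iteration <- iteration + 1L
    q_now <- min(config$q, config$budget - length(L))
    if (length(finiteL) == 0) {
      # nothing finite to model yet: fall back to uniform random proposals
      Zr <- sweep(sweep(matrix(runif(q_now * d), q_now, d), 2,
                        b$upper - b$lower, `*`), 2, b$lower, `+`)
      prop <- list(X = Zr, t = rep(NA_real_, q_now))
    } else {
      surr_seed <- sample.int(.Machine$integer.max, 1)
      # variance-stabilizing transform (monotone): the forest and the
      # acquisition operate on this scale, the history stores raw losses
      trans <- if (config$loss_transform == "log10") {
        offset <- max(config$tol, 1e-300)
        function(l) log10(pmax(l, 0) + offset)
      } else identity
      surr <- fit_surrogate(X, trans(L), num_trees = config$num_trees,
                            seed = surr_seed)
      L_min <- trans(min(finiteL))
      prop <- propose_batch(surr, space, q_now, L_min, X_eval = X,
                            L_eval = L,
                            t_mode = config$t_mode, t_fixed = config$t_fixed,
                            es_generations = config$es_generations)
    }
    Lnew <- eval_batch(prop$X)
    X <- rbind(X, prop$X)
    L <- c(L, Lnew)
    temps <- c(temps, prop$t)
    iter_of <- c(iter_of, rep(iteration, q_now))
  }
  best_idx <- which.min(L)
  phys <- space_decode(space, X)
  history <- data.frame(
    evaluation = seq_along(L),
    iteration = iter_of,
    phys,
    loss = L,
    temperature = temps,
    best_so_far = cummin(L),
    check.names = FALSE
  )
  best_x <- setNames(as.numeric(phys[best_idx, ]), space$names)
  list(best = list(x = best_x, loss = L[best_idx]),
       history = history, X = X, L = L,
       n_evaluations = length(L), iterations = iteration)
}
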