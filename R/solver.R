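# Nonlinear forward solver: quasi-static Newton with load incrementation and
# automatic step halving, plus a transient (Newmark average-acceleration)
# mode with lumped mass and optional mass-proportional damping. The transient
# mode reproduces the inertial content of ramp loading on very soft bodies,
# which is what makes the absolute modulus scale observable in the beam
# benchmark (a purely quasi-static displacement-driven solve is invariant
# under a common scaling of all moduli).

#' Load program
#'
#' Describes how a mesh is constrained and loaded. All loads and prescribed
#' displacements are ramped linearly from zero over `n_steps` increments
#' (the "time" axis of a trajectory is this load-step axis). When `dynamics`
#' is supplied, the ramp is interpreted as a true time ramp of duration
#' `dynamics$ramp_time` seconds and the solver integrates the equations of
#' motion instead of solving a sequence of equilibria.
#'
#' @param fixed Integer vector of node ids whose dofs in `fixed_comps` are
#'   held at zero, or a list of `list(nodes=, comps=)` blocks.
#' @param fixed_comps Components (subset of 1:3) zeroed at `fixed` nodes.
#' @param prescribed_nodes Node ids driven by `prescribed_value`.
#' @param prescribed_value Target displacement (mm), one value per component
#'   in `prescribed_comps`, reached at the end of the ramp.
#' @param prescribed_comps Components of the prescribed displacement.
#' @param pressure Scalar pressure (Pa) applied as a follower load on
#'   `pressure_faces`, ramped like everything else.
#' @param pressure_faces Face connectivity (rows of node ids, 3 or 4 wide)
#'   oriented so the right-hand normal points in the push direction.
#' @param body_force Force per unit mass, length-3 (requires a density).
#' @param n_steps Number of load increments (>= 1); default 10.
#' @param dynamics `NULL` for quasi-static, else
#'   `list(ramp_time = <s>, damping = <mass-damping alpha, 1/s>)`.
#' @param fixed_dofs Raw global dof ids (`3 (node - 1) + component`) to hold
#'   at zero, for constraints that mix components across nodes.
#' @return A `load_program` object.
#' @export
load_program <- function(fixed = integer(), fixed_comps = 1:3,
                         prescribed_nodes = integer(), prescribed_value = c(0, 0, 0),
                         prescribed_comps = 1:3,
                         pressure = 0, pressure_faces = NULL,
                         body_force = c(0, 0, 0), n_steps = 10,
                         dynamics = NULL, fixed_dofs = integer()) {
  if (n_steps < 1) si_stop("n_steps must be >= 1", "invalid_config")
  if (!is.null(dynamics)) {
    if (is.null(dynamics$ramp_time) || dynamics$ramp_time <= 0) {
      si_stop("dynamics$ramp_time must be positive", "invalid_config")
    }
    dynamics$damping <- dynamics$damping %||% 0
  }
  structure(list(
    fixed = fixed, fixed_comps = fixed_comps,
    prescribed_nodes = prescribed_nodes,
    prescribed_value = prescribed_value,
    prescribed_comps = prescribed_comps,
    pressure = pressure, pressure_faces = pressure_faces,
    body_force = body_force, n_steps = as.integer(n_steps),
    dynamics = dynamics, fixed_dofs = as.integer(fixed_dofs)
  ), class = "load_program")
}

#' Solver control parameters
#'
#' @param rtol Relative residual tolerance per step (vs the first Newton
#'   residual of the step); default 1e-10.
#' @param atol Absolute residual floor; default 1e-12.
#' @param max_iter Maximum Newton iterations per (sub)step; default 50.
#' @param min_substep Smallest allowed fraction of a nominal increment when
#'   halving after non-convergence; default 1/64.
#' @param du_cap Cap on the infinity norm (mm) of a single Newton increment;
#'   `NULL` (default) derives it from the mesh as twice the smallest
#'   element edge.
#' @return A list of control parameters.
#' @export
solver_control <- function(rtol = 1e-10, atol = 1e-12, max_iter = 50,
                           min_substep = 1 / 64, du_cap = NULL) {
  list(rtol = rtol, atol = atol, max_iter = max_iter,
       min_substep = min_substep, du_cap = du_cap)
}

# per-element material property vectors from the region labels
element_materials <- function(mesh, materials) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing)) {
    si_stop(paste("no material for region(s):", paste(missing, collapse = ", ")),
            "invalid_config")
  }
  ne <- nrow(mesh$elems)
  mu <- kappa <- lam <- rho <- thick <- numeric(ne)
  model <- integer(ne)
  for (r in regions) {
    sel <- mesh$region == r
    m <- materials[[r]]
    mu[sel] <- m$shear_modulus
    kappa[sel] <- m$bulk_modulus
    # unit system is (mm, Pa, s): force unit is then uN and the consistent
    # mass unit is grams, so density converts from kg/m^3 to g/mm^3
    rho[sel] <- m$density * 1e-6
    thick[sel] <- if (!is.null(m$thickness)) m$thickness else 0
    if (m$model == "stvk") {
      lp <- lame_parameters(m$young_modulus, min(m$poisson_ratio, m$nu_eff))
      lam[sel] <- lp$lambda
      model[sel] <- 1L
    }
  }
  list(mu = mu, kappa = kappa, lambda = lam, rho = rho, thickness = thick,
       model = model, etype = if (mesh$type == "hex8") 0L else 1L)
}

# constrained dof bookkeeping
constraint_dofs <- function(mesh, load) {
  dof <- function(nodes, comps) {
    as.vector(outer(comps, 3 * (nodes - 1), `+`))
  }
  fixed_dofs <- if (length(load$fixed)) dof(load$fixed, load$fixed_comps) else integer()
  fixed_dofs <- c(fixed_dofs, load$fixed_dofs %||% integer())
  presc_dofs <- integer(); presc_vals <- numeric()
  if (length(load$prescribed_nodes)) {
    for (ci in seq_along(load$prescribed_comps)) {
      cc <- load$prescribed_comps[ci]
      presc_dofs <- c(presc_dofs, 3 * (load$prescribed_nodes - 1) + cc)
      presc_vals <- c(presc_vals, rep(load$prescribed_value[ci], length(load$prescribed_nodes)))
    }
  }
  keep <- !(presc_dofs %in% fixed_dofs)
  presc_dofs <- presc_dofs[keep]; presc_vals <- presc_vals[keep]
  list(fixed = unique(fixed_dofs), presc = presc_dofs, presc_vals = presc_vals)
}

assemble_tangent_system <- function(mesh, em, u, load, factor, mass = NULL) {
  n_dof <- 3 * nrow(mesh$nodes)
  dense <- n_dof <= 1500 # direct dense assembly is faster for small systems
  asm <- assemble_internal_cpp(mesh$nodes, mesh$elems, u, em$mu, em$kappa,
                               em$lambda, em$model, em$thickness, em$etype,
                               TRUE, dense)
  if (!asm$ok) return(NULL)
  resid <- asm$f
  if (dense) K <- asm$K else { ti <- asm$i; tj <- asm$j; tv <- asm$v }
  if (!is.null(load$pressure_faces) && load$pressure * factor != 0) {
    pr <- assemble_pressure_cpp(mesh$nodes, load$pressure_faces, u,
                                load$pressure * factor, TRUE, dense)
    resid <- resid - pr$f
    if (dense) K <- K - pr$K else {
      ti <- c(ti, pr$i); tj <- c(tj, pr$j); tv <- c(tv, -pr$v)
    }
  }
  if (any(load$body_force != 0) && !is.null(mass)) {
    resid <- resid - mass * rep(load$body_force, length.out = 3)[
      rep(1:3, length(resid) / 3)] * factor
  }
  if (!dense) {
    K <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n_dof, n_dof))
  }
  list(resid = resid, K = K, dense = dense)
}

# residual of the (possibly transient) balance at displacement u
full_residual <- function(mesh, em, u, load, factor, mass, dyn) {
  asm <- assemble_internal_cpp(mesh$nodes, mesh$elems, u, em$mu, em$kappa,
                               em$lambda, em$model, em$thickness, em$etype,
                               FALSE, FALSE)
  if (!asm$ok) return(NULL)
  resid <- asm$f
  if (!is.null(load$pressure_faces) && load$pressure * factor != 0) {
    pr <- assemble_pressure_cpp(mesh$nodes, load$pressure_faces, u,
                                load$pressure * factor, FALSE, FALSE)
    resid <- resid - pr$f
  }
  if (any(load$body_force != 0) && !is.null(mass)) {
    resid <- resid - mass * rep(load$body_force, length.out = 3)[
      rep(1:3, length(resid) / 3)] * factor
  }
  if (!is.null(dyn)) {
    bdt2 <- 1 / (dyn$beta * dyn$dt^2)
    a <- bdt2 * (u - dyn$u_n) - dyn$v_n / (dyn$beta * dyn$dt) -
      (1 / (2 * dyn$beta) - 1) * dyn$a_n
    v <- dyn$v_n + dyn$dt * ((1 - dyn$gamma) * dyn$a_n + dyn$gamma * a)
    resid <- resid + dyn$mass * a + dyn$alpha * dyn$mass * v
  }
  resid
}

newton_solve_state <- function(mesh, em, u, load, factor, control,
                               dyn = NULL, mass = NULL) {
  n_dof <- length(u)
  con <- attr(u, "constraints")
  free <- con$free
  # enforce constrained values for this factor
  u[con$fixed] <- 0
  u[con$presc] <- con$presc_vals * factor
  mass_eff <- mass %||% dyn$mass
  ref_norm <- NULL
  rn_prev <- Inf
  K_ff <- NULL
  for (iter in seq_len(control$max_iter)) {
    resid <- full_residual(mesh, em, as.numeric(u), load, factor, mass_eff, dyn)
    if (is.null(resid)) return(list(ok = FALSE, u = u))
    rn <- sqrt(sum(resid[free]^2))
    if (is.null(ref_norm)) ref_norm <- max(rn, control$atol)
    if (rn <= control$rtol * ref_norm + control$atol) {
      out <- list(ok = TRUE, u = u, iters = iter,
                  fint_resid = if (is.null(dyn)) resid else NULL)
      if (!is.null(dyn)) {
        bdt2 <- 1 / (dyn$beta * dyn$dt^2)
        out$a <- bdt2 * (u - dyn$u_n) - dyn$v_n / (dyn$beta * dyn$dt) -
          (1 / (2 * dyn$beta) - 1) * dyn$a_n
        out$v <- dyn$v_n + dyn$dt * ((1 - dyn$gamma) * dyn$a_n + dyn$gamma * out$a)
      }
      return(out)
    }
    # refresh the (finite-difference) tangent when absent or when the
    # previous modified-Newton iteration converged too slowly
    if (is.null(K_ff) || rn > 0.3 * rn_prev) {
      sys <- assemble_tangent_system(mesh, em, u, load, factor, mass_eff)
      if (is.null(sys)) return(list(ok = FALSE, u = u))
      K <- sys$K
      if (!is.null(dyn)) {
        diag_add <- dyn$mass * (1 / (dyn$beta * dyn$dt^2) +
                                  dyn$alpha * dyn$gamma / (dyn$beta * dyn$dt))
        if (sys$dense) diag(K) <- diag(K) + diag_add
        else K <- K + Matrix::Diagonal(n_dof, diag_add)
      }
      K_ff <- K[free, free, drop = FALSE]
    }
    du <- tryCatch({
      d <- if (is.matrix(K_ff)) solve(K_ff, -resid[free]) else
        as.numeric(Matrix::solve(K_ff, -resid[free]))
      if (any(!is.finite(d))) NULL else d
    }, error = function(e) NULL)
    if (is.null(du)) {
      return(list(ok = FALSE, u = u))
    }
    # cap the per-iteration increment at a few element lengths: a
    # near-singular tangent otherwise throws the iterate into an inverted
    # configuration no line search can rescue
    if (!is.null(control$du_cap) && is.finite(control$du_cap)) {
      mx <- max(abs(du))
      if (mx > control$du_cap) {
        du <- du * (control$du_cap / mx)
        K_ff <- NULL
      }
    }
    # globalization. Transient steps use a monotone backtracking line search
    # (the Newmark mass term makes the residual a reliable merit function).
    # Static steps tolerate transient residual growth - Newton on follower
    # pressure routinely overshoots before collapsing quadratically - so
    # only steps that blow up beyond `growth_cap` are damped, and outright
    # divergence (rn far above the step's initial residual) aborts the
    # (sub)step.
    growth_cap <- if (is.null(dyn)) 100 else 1
    if (is.null(dyn) && rn > 1e4 * ref_norm) return(list(ok = FALSE, u = u))
    alpha <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      r_try <- full_residual(mesh, em, as.numeric(u_try), load, factor,
                             mass_eff, dyn)
      rn_try <- if (is.null(r_try)) Inf else sqrt(sum(r_try[free]^2))
      if (rn_try < growth_cap * rn || alpha <= 1 / 32) break
      alpha <- alpha / 2
    }
    if (!is.finite(rn_try)) return(list(ok = FALSE, u = u))
    if (alpha < 1) K_ff <- NULL # damped step: force a fresh tangent
    u[free] <- u[free] + alpha * du
    rn_prev <- rn
    # displacement stagnation: when a full Newton step no longer moves the
    # iterate, the residual has hit its assembly roundoff floor (set by the
    # stiffest elements) and the state is converged even if the relative
    # force criterion is unreachable
    if (alpha == 1 && max(abs(du)) <= 1e-11 * (1 + max(abs(u)))) {
      out <- list(ok = TRUE, u = u, iters = iter,
                  fint_resid = if (is.null(dyn)) r_try else NULL)
      if (!is.null(dyn)) {
        bdt2 <- 1 / (dyn$beta * dyn$dt^2)
        out$a <- bdt2 * (u - dyn$u_n) - dyn$v_n / (dyn$beta * dyn$dt) -
          (1 / (2 * dyn$beta) - 1) * dyn$a_n
        out$v <- dyn$v_n + dyn$dt * ((1 - dyn$gamma) * dyn$a_n + dyn$gamma * out$a)
      }
      return(out)
    }
  }
  list(ok = FALSE, u = u)
}

#' Quasi-static nonlinear forward solve
#'
#' Solves for the equilibrium displacement field of a hyperelastic body under
#' a ramped load program using Newton's method with load incrementation and
#' automatic step halving. When the load program carries a `dynamics` block,
#' the transient equations of motion are integrated instead (Newmark average
#' acceleration, lumped mass, optional mass-proportional damping) with one
#' time step per load increment.
#'
#' @param mesh An `fe_mesh` (hexahedral solid or membrane triangles).
#' @param materials Named list of [material_parameters()], one entry per
#'   region label occurring in `mesh$region` (typically `base`, `abnormal`).
#' @param load A [load_program()].
#' @param control A [solver_control()] list.
#' @return A `displacement_history`: array `(n_steps + 1, n_nodes, 3)` of
#'   nodal displacements in mm, step 1 being the undeformed state. Carries
#'   attributes `final_internal_force` (assembled internal minus external
#'   force at the last step, whose entries at constrained dofs are the
#'   reactions) and `n_steps`.
#' @export
solve_quasistatic <- function(mesh, materials, load, control = solver_control()) {
  em <- element_materials(mesh, materials)
  con <- constraint_dofs(mesh, load)
  n_dof <- 3 * nrow(mesh$nodes)
  constrained <- c(con$fixed, con$presc)
  if (length(constrained) == 0 && is.null(load$dynamics)) {
    si_stop("load program leaves rigid-body modes unconstrained", "constraint_error")
  }
  free <- setdiff(seq_len(n_dof), constrained)
  u <- numeric(n_dof)
  attr(u, "constraints") <- list(fixed = con$fixed, presc = con$presc,
                                 presc_vals = con$presc_vals, free = free)
  if (is.null(control$du_cap)) {
    e1 <- sqrt(rowSums((mesh$nodes[mesh$elems[, 2], , drop = FALSE] -
                          mesh$nodes[mesh$elems[, 1], , drop = FALSE])^2))
    control$du_cap <- 2 * min(e1)
  }
  hist <- array(0, dim = c(load$n_steps + 1, nrow(mesh$nodes), 3))

  dyn <- NULL
  mass <- NULL
  if (!is.null(load$dynamics) || any(load$body_force != 0)) {
    mass <- lumped_mass_cpp(mesh$nodes, mesh$elems, em$rho, em$thickness, em$etype)
  }
  if (!is.null(load$dynamics)) {
    dt <- load$dynamics$ramp_time / load$n_steps
    # default Newmark parameters include numerical dissipation (gamma > 1/2)
    # so that unresolved high-frequency modes decay instead of ringing
    gamma <- load$dynamics$gamma %||% 0.6
    beta <- load$dynamics$beta %||% ((gamma + 0.5)^2 / 4)
    dyn <- list(beta = beta, gamma = gamma, dt = dt, mass = mass,
                alpha = load$dynamics$damping,
                u_n = u, v_n = numeric(n_dof), a_n = numeric(n_dof))
  }

  fint_last <- NULL
  factor_done <- 0
  total_iters <- 0L
  for (step in seq_len(load$n_steps)) {
    target <- step / load$n_steps
    frac <- target - factor_done # nominal increment
    sub <- 1
    while (factor_done < target - 1e-12) {
      attempt <- min(frac / sub, target - factor_done)
      res <- newton_solve_state(mesh, em, u, load, factor_done + attempt,
                                control, dyn, mass)
      if (res$ok) {
        u <- res$u
        attr(u, "constraints") <- list(fixed = con$fixed, presc = con$presc,
                                       presc_vals = con$presc_vals, free = free)
        factor_done <- factor_done + attempt
        fint_last <- res$fint_resid
        total_iters <- total_iters + res$iters
        if (!is.null(dyn)) {
          dyn$u_n <- as.numeric(u); dyn$v_n <- res$v; dyn$a_n <- res$a
        }
      } else {
        # the transient integrator keeps dt fixed (halving would change the
        # computed trajectory, not just refine an equilibrium path)
        if (!is.null(dyn)) {
          si_stop(sprintf(
            "transient Newton failed to converge at time fraction %.4f",
            factor_done), "non_convergence")
        }
        sub <- sub * 2
        if (1 / sub < control$min_substep) {
          si_stop(sprintf(
            "Newton failed to converge at load factor %.4f (substep floor reached)",
            factor_done), "non_convergence")
        }
      }
    }
    hist[step + 1, , ] <- matrix(u, ncol = 3, byrow = TRUE)
  }
  structure(hist,
            class = "displacement_history",
            final_internal_force = fint_last,
            n_steps = load$n_steps,
            newton_iterations = total_iters)
}

#' Inflate a closed shell by internal pressure
#'
#' Convenience wrapper around [solve_quasistatic()] for spherical shells
#' built with [build_sphere_mesh()]: applies the follower pressure of the
#' load program on the shell's inner faces and pins six dofs on three
#' axis-aligned nodes (a 2+2+2 scheme compatible with pure radial motion)
#' to remove rigid-body modes.
#'
#' @param mesh Closed shell `fe_mesh` carrying an `inner_faces` attribute.
#' @param materials Named list of [material_parameters()] per region.
#' @param pressure_program A [load_program()] whose `pressure` is the final
#'   internal pressure in Pa (faces are taken from the mesh).
#' @param control A [solver_control()].
#' @return A `displacement_history` (see [solve_quasistatic()]).
#' @export
inflate <- function(mesh, materials, pressure_program, control = solver_control()) {
  faces <- attr(mesh, "inner_faces")
  if (is.null(faces)) si_stop("mesh has no inner_faces attribute", "invalid_config")
  load <- pressure_program
  load$pressure_faces <- faces
  if (length(load$fixed) == 0 && length(load$fixed_dofs) == 0) {
    r <- sqrt(rowSums(mesh$nodes^2))
    pick <- function(dir) which.max((mesh$nodes %*% dir) / pmax(r, 1e-12))
    nx <- pick(c(1, 0, 0)); nmx <- pick(c(-1, 0, 0)); ny <- pick(c(0, 1, 0))
    # +x node: pin y,z; -x node: pin y,z; +y node: pin x,z -- all six pins
    # are compatible with a purely radial expansion field
    load$fixed_dofs <- c(3 * (nx - 1) + c(2, 3), 3 * (nmx - 1) + c(2, 3),
                         3 * (ny - 1) + c(1, 3))
  }
  solve_quasistatic(mesh, materials, load, control)
}

#' Tracking set
#'
#' @param nodes Keypoint node ids (1-based, non-empty, within the mesh).
#' @param comps Components of displacement entering the loss (subset of 1:3).
#' @return A `tracking_set` object.
#' @export
tracking_set <- function(nodes, comps = 1:3) {
  nodes <- as.integer(nodes)
  if (length(nodes) == 0) si_stop("tracking set must be non-empty", "invalid_config")
  comps <- as.integer(comps)
  if (length(comps) == 0 || any(!comps %in% 1:3)) {
    si_stop("comps must be a non-empty subset of 1:3", "invalid_config")
  }
  structure(list(nodes = nodes, comps = comps), class = "tracking_set")
}

#' Extract keypoint trajectories from a displacement history
#'
#' Slices the per-step nodal displacement array at the tracking nodes and
#' masked components; no interpolation is performed.
#'
#' @param history A `displacement_history` from [solve_quasistatic()].
#' @param tracking A [tracking_set()].
#' @return Numeric array `(steps + 1, n_keypoints, n_components)` in mm.
#' @export
extract_keypoints <- function(history, tracking) {
  if (!inherits(tracking, "tracking_set")) {
    tracking <- tracking_set(tracking$nodes, tracking$comps %||% 1:3)
  }
  n_nodes <- dim(history)[2]
  if (any(tracking$nodes < 1) || any(tracking$nodes > n_nodes)) {
    si_stop("tracking node id out of range", "invalid_config")
  }
  history[, tracking$nodes, tracking$comps, drop = FALSE]
}
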