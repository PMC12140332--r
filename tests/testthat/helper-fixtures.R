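# shared helpers: small random deformation states and meshes built in code

# random incompressible principal stretches (lambda1 lambda2 lambda3 = 1)
random_incompressible_stretches <- function() {
  l1 <- exp(runif(1, -0.4, 0.4))
  l2 <- exp(runif(1, -0.4, 0.4))
  c(l1, l2, 1 / (l1 * l2))
}

# random rotation matrix via QR of a Gaussian matrix (det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# single unit hex under prescribed uniaxial stretch in z, lateral faces free
uniaxial_hex_history <- function(stretch, E = 1e3, n_steps = 5) {
  m <- build_beam_mesh(c(1, 1, 1), c(1, 1, 1))
  bot <- nodes_on_plane(m, 3, 0)
  top <- nodes_on_plane(m, 3, 1)
  n000 <- which(apply(m$nodes, 1, function(p) all(abs(p - c(0, 0, 0)) < 1e-9)))
  n100 <- which(apply(m$nodes, 1, function(p) all(abs(p - c(1, 0, 0)) < 1e-9)))
  pins <- c(3 * (n000 - 1) + c(1, 2), 3 * (n100 - 1) + 2)
  load <- load_program(
    fixed = bot, fixed_comps = 3,
    prescribed_nodes = top, prescribed_value = stretch - 1, prescribed_comps = 3,
    n_steps = n_steps, fixed_dofs = pins
  )
  list(mesh = m, top = top,
       history = solve_quasistatic(m, list(base = material_parameters(E)), load))
}
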