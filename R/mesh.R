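# Mesh construction: structured hexahedral beam, cubed-sphere shell,
# parametric tri-leaflet valve surface. Lengths in mm throughout. Node and
# element ids are 1-based inside R; file exports use 0-based ids.

new_fe_mesh <- function(nodes, elems, type, region = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (is.null(region)) region <- rep("base", nrow(elems))
  if (any(elems < 1L) || any(elems > nrow(nodes))) {
    si_stop("element connectivity index out of range", "invalid_config")
  }
  structure(
    list(nodes = nodes, elems = elems, type = type, region = region),
    class = "fe_mesh"
  )
}

#' @exportS3Method base::print
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %s: %d nodes, %d elements (%d abnormal)\n",
              x$type, nrow(x$nodes), nrow(x$elems), sum(x$region == "abnormal")))
  invisible(x)
}

#' Structured hexahedral beam mesh
#'
#' Axis-aligned beam occupying `[0, L] x [0, W] x [0, H]` (mm), discretized
#' into a uniform grid of 8-node hexahedra. The benchmark beam is
#' 50 x 25 x 3 mm with a 20 x 6 x 4 grid; a coarser "desk" grid of
#' 10 x 3 x 2 is used for fast runs.
#'
#' @param dimensions Numeric length-3, `(L, W, H)` in mm, all positive.
#' @param divisions Integer length-3, `(nx, ny, nz)` element counts, all >= 1.
#' @return An `fe_mesh` with `nx ny nz` hexahedra and
#'   `(nx+1)(ny+1)(nz+1)` nodes, all labelled `"base"`.
#' @export
#' @examples
#' m <- build_beam_mesh(c(50, 25, 3), c(20, 6, 4))
#' nrow(m$elems) # 480
build_beam_mesh <- function(dimensions = c(50, 25, 3), divisions = c(20, 6, 4)) {
  if (length(dimensions) != 3 || any(!is.finite(dimensions)) || any(dimensions <= 0)) {
    si_stop("dimensions must be three positive numbers", "invalid_config")
  }
  dv <- as.integer(divisions)
  if (length(dv) != 3 || any(is.na(dv)) || any(dv < 1)) {
    si_stop("divisions must be three positive integers", "invalid_config")
  }
  nx <- dv[1]; ny <- dv[2]; nz <- dv[3]
  xs <- seq(0, dimensions[1], length.out = nx + 1)
  ys <- seq(0, dimensions[2], length.out = ny + 1)
  zs <- seq(0, dimensions[3], length.out = nz + 1)
  # node index (i,j,k) -> linear id, i fastest
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  grid <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  nodes <- as.matrix(grid)
  colnames(nodes) <- NULL
  ijk <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- ijk$i; j <- ijk$j; k <- ijk$k
  # standard hex ordering: bottom face CCW (viewed from +z), then top face
  elems <- cbind(
    nid(i,     j,     k), nid(i + 1L, j,     k),
    nid(i + 1L, j + 1L, k), nid(i,     j + 1L, k),
    nid(i,     j,     k + 1L), nid(i + 1L, j,     k + 1L),
    nid(i + 1L, j + 1L, k + 1L), nid(i,     j + 1L, k + 1L)
  )
  new_fe_mesh(nodes, elems, "hex8")
}

# deduplicate vertex rows by rounded coordinates; returns list(nodes, index)
dedupe_nodes <- function(pts, digits = 9) {
  key <- apply(round(pts, digits), 1, paste, collapse = "|")
  first <- !duplicated(key)
  list(nodes = pts[first, , drop = FALSE], index = match(key, key[first]))
}

# quad surface grid of the unit cube, n segments per edge, outward CCW quads
cube_surface_grid <- function(n) {
  u <- seq(-1, 1, length.out = n + 1)
  pts <- NULL; quads <- NULL
  faces <- list(
    list(axis = 1, sign = +1), list(axis = 1, sign = -1),
    list(axis = 2, sign = +1), list(axis = 2, sign = -1),
    list(axis = 3, sign = +1), list(axis = 3, sign = -1)
  )
  for (f in faces) {
    base <- nrow(pts %||% matrix(0, 0, 3))
    g <- expand.grid(a = u, b = u, KEEP.OUT.ATTRS = FALSE)
    p <- matrix(0, nrow(g), 3)
    ax <- f$axis; oth <- setdiff(1:3, ax)
    p[, ax] <- f$sign
    p[, oth[1]] <- g$a
    p[, oth[2]] <- g$b
    id <- function(ia, ib) base + ia + (n + 1L) * (ib - 1L)
    ij <- expand.grid(ia = seq_len(n), ib = seq_len(n))
    q <- cbind(id(ij$ia, ij$ib), id(ij$ia + 1L, ij$ib),
               id(ij$ia + 1L, ij$ib + 1L), id(ij$ia, ij$ib + 1L))
    # orient CCW seen from outside (normal along sign * axis)
    ql <- q - base
    v1 <- p[ql[, 2], ] - p[ql[, 1], ]
    v2 <- p[ql[, 4], ] - p[ql[, 1], ]
    nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                 v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                 v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
    flip <- nrm[, ax] * f$sign < 0
    q[flip, ] <- q[flip, c(1, 4, 3, 2)]
    pts <- rbind(pts, p)
    quads <- rbind(quads, q)
  }
  d <- dedupe_nodes(pts)
  quads[] <- d$index[quads]
  list(pts = d$nodes, quads = quads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed spherical shell mesh
#'
#' Cubed-sphere shell: the surface of a cube is subdivided, projected
#' radially onto the mid-surface sphere of radius `radius`, and extruded one
#' hexahedral layer through the thickness (inner radius `radius - t/2`,
#' outer `radius + t/2`). The returned mesh carries the attribute
#' `inner_faces`: the quad connectivity of the inner surface, ordered so
#' that face normals point outward (the direction an internal pressure
#' pushes).
#'
#' @param radius Mid-surface radius in mm; must exceed `thickness`.
#' @param thickness Shell thickness in mm, > 0.
#' @param refinement Subdivision level; the cube edge is split into
#'   `4 * 2^(refinement - 1)` segments, so each level quadruples the face
#'   count. Default 1 (96 elements).
#' @return An `fe_mesh` of hexahedra with attributes `inner_faces`,
#'   `outer_nodes` (ids on the outer surface) and `mid_radius`.
#' @export
build_sphere_mesh <- function(radius = 100, thickness = 3, refinement = 1) {
  if (!is.finite(radius) || !is.finite(thickness) || thickness <= 0 || radius <= thickness) {
    si_stop("need radius > thickness > 0", "invalid_config")
  }
  if (refinement < 1) si_stop("refinement must be >= 1", "invalid_config")
  n <- 4L * 2L^(as.integer(refinement) - 1L)
  g <- cube_surface_grid(n)
  # equiangular mapping: remap the two in-face coordinates u -> tan(u pi/4)
  # before normalizing, which nearly equalizes the element solid angles
  pts <- g$pts
  on_face <- abs(abs(pts) - 1) < 1e-12
  pts[!on_face] <- tan(pts[!on_face] * pi / 4)
  dirs <- pts / sqrt(rowSums(pts^2))
  r_in <- radius - thickness / 2
  r_out <- radius + thickness / 2
  nin <- nrow(dirs)
  nodes <- rbind(dirs * r_in, dirs * r_out)
  # hex: inner quad (CCW from outside) as bottom, outer quad as top
  elems <- cbind(g$quads, g$quads + nin)
  m <- new_fe_mesh(nodes, elems, "hex8")
  attr(m, "inner_faces") <- g$quads
  attr(m, "outer_nodes") <- seq_len(nin) + nin
  attr(m, "mid_radius") <- radius
  attr(m, "thickness") <- thickness
  m
}

#' Simplified parametric tri-leaflet valve surface
#'
#' A stand-in synthetic tri-leaflet aortic valve geometry: three identical
#' membrane leaflets attached to a root cylinder of radius `r_co`, with
#' scalloped lower (attachment) edges rising to commissure points, free
#' coaptation edges around a central orifice, and a sagging belly. It is a
#' deliberately simplified surface - not derived from imaging data - that
#' reproduces the mechanically relevant features: fixed lower edges, free
#' upper edges, and a stiffenable patch region.
#'
#' @param r_co Root (annulus) radius in mm; default 12.5.
#' @param n_s Grid divisions from attachment to free edge; default 8.
#' @param n_t Grid divisions across a leaflet; default 10.
#' @return An `fe_mesh` of `tri3` membrane triangles, oriented so that face
#'   normals point in the push direction of the trans-valvular pressure
#'   (downward, from the aortic side). Attributes: `fixed_nodes` (attachment
#'   edge ids), `r_co`.
#' @export
build_valve_mesh <- function(r_co = 12.5, n_s = 8, n_t = 10) {
  if (r_co <= 0 || n_s < 2 || n_t < 2) si_stop("invalid valve mesh parameters", "invalid_config")
  h_c <- 0.6 * r_co   # commissure height
  h_f <- 0.25 * r_co  # free-edge height at leaflet center
  r_f <- 0.12 * r_co  # free-edge radius at leaflet center
  sag <- 0.25 * r_co  # belly dip
  pts <- NULL; tris <- NULL; fixed <- NULL
  for (k in 0:2) {
    phi0 <- 2 * pi * k / 3
    tt <- seq(-1, 1, length.out = n_t + 1) # scaled angular coordinate
    ss <- seq(0, 1, length.out = n_s + 1)
    base <- nrow(pts %||% matrix(0, 0, 3))
    id <- function(i, j) base + i + (n_t + 1L) * (j - 1L) # i over t, j over s
    p <- matrix(0, (n_t + 1) * (n_s + 1), 3)
    for (j in seq_along(ss)) for (i in seq_along(tt)) {
      t <- tt[i]; s <- ss[j]
      z_att <- h_c * t^2
      r_fe <- r_f + (r_co - r_f) * abs(t)^1.3
      z_fe <- h_f + (h_c - h_f) * t^2
      r <- (1 - s) * r_co + s * r_fe
      z <- (1 - s) * z_att + s * z_fe - sag * sin(pi * s) * cos(pi * t / 2)
      phi <- phi0 + t * pi / 3
      p[id(i, j) - base, ] <- c(r * cos(phi), r * sin(phi), z)
    }
    for (j in seq_len(n_s)) for (i in seq_len(n_t)) {
      a <- id(i, j); b <- id(i + 1, j); c2 <- id(i + 1, j + 1); d <- id(i, j + 1)
      tris <- rbind(tris, c(a, b, c2), c(a, c2, d))
    }
    fixed <- c(fixed, id(seq_len(n_t + 1), 1))
    pts <- rbind(pts, p)
  }
  d <- dedupe_nodes(pts)
  tris[] <- d$index[tris]
  fixed <- unique(d$index[fixed])
  # drop degenerate triangles (collapsed at commissures)
  a <- d$nodes[tris[, 1], ]; b <- d$nodes[tris[, 2], ]; c2 <- d$nodes[tris[, 3], ]
  cr <- cross3(b - a, c2 - a)
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > 1e-9 * r_co^2
  tris <- tris[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]
  # orient normals downward (pressure push direction)
  flip <- cr[, 3] > 0
  tris[flip, ] <- tris[flip, c(1, 3, 2)]
  m <- new_fe_mesh(d$nodes, tris, "tri3")
  attr(m, "fixed_nodes") <- sort(fixed)
  attr(m, "r_co") <- r_co
  m
}

cross3 <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, 1)
  if (is.null(dim(v))) v <- matrix(v, 1)
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Element centroids
#'
#' @param mesh An `fe_mesh`.
#' @return Matrix (n_elements x 3) of centroid coordinates in mm.
#' @export
element_centroids <- function(mesh) {
  t(apply(mesh$elems, 1, function(conn) colMeans(mesh$nodes[conn, , drop = FALSE])))
}

# element volumes (hex8, Jacobian-based 2x2x2 quadrature) / areas (tri3)
element_measures <- function(mesh) {
  if (mesh$type == "tri3") {
    a <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
    b <- mesh$nodes[mesh$elems[, 2], , drop = FALSE]
    c2 <- mesh$nodes[mesh$elems[, 3], , drop = FALSE]
    return(0.5 * sqrt(rowSums(cross3(b - a, c2 - a)^2)))
  }
  hex_volumes_cpp(mesh$nodes, mesh$elems)
}

#' Node ids on a coordinate plane
#'
#' Convenience selector for building load programs on structured meshes:
#' all nodes whose `axis` coordinate equals `value` within tolerance.
#'
#' @param mesh An `fe_mesh`.
#' @param axis Coordinate axis (1, 2 or 3).
#' @param value Plane position in mm.
#' @param tol Relative tolerance; default 1e-8.
#' @return Integer node ids.
#' @export
nodes_on_plane <- function(mesh, axis, value, tol = 1e-8) {
  which(abs(mesh$nodes[, axis] - value) < tol * (1 + abs(value)))
}

#' Boundary quad faces of a hex mesh on a coordinate plane
#'
#' Extracts the quad faces of a structured hexahedral mesh lying on the
#' plane `axis == value`, oriented so the right-hand-rule normal points
#' along `normal_sign` times the axis unit vector (the push direction for
#' a pressure load).
#'
#' @param mesh An `fe_mesh` of hexahedra.
#' @param axis Coordinate axis (1, 2 or 3).
#' @param value Plane position in mm.
#' @param normal_sign +1 or -1.
#' @param tol Relative tolerance; default 1e-8.
#' @return Integer matrix (n_faces x 4) of node ids.
#' @export
hex_plane_faces <- function(mesh, axis, value, normal_sign, tol = 1e-8) {
  # local faces of the hex (outward): -x:(1,5,8,4) +x:(2,3,7,6)
  # -y:(1,2,6,5) +y:(4,8,7,3) -z:(1,4,3,2) +z:(5,6,7,8)
  loc <- list(
    `1-` = c(1, 5, 8, 4), `1+` = c(2, 3, 7, 6),
    `2-` = c(1, 2, 6, 5), `2+` = c(4, 8, 7, 3),
    `3-` = c(1, 4, 3, 2), `3+` = c(5, 6, 7, 8)
  )
  out <- NULL
  for (key in names(loc)) {
    ax <- as.integer(substr(key, 1, 1))
    if (ax != axis) next
    f <- loc[[key]]
    faces <- mesh$elems[, f, drop = FALSE]
    on <- apply(faces, 1, function(cc) all(abs(mesh$nodes[cc, axis] - value) < tol * (1 + abs(value))))
    out <- rbind(out, faces[on, , drop = FALSE])
  }
  if (is.null(out) || nrow(out) == 0) return(matrix(integer(), 0, 4))
  # orientation: outward local faces have normal along the face's outward axis;
  # flip if requested normal sign disagrees
  a <- mesh$nodes[out[, 1], , drop = FALSE]
  b <- mesh$nodes[out[, 2], , drop = FALSE]
  d <- mesh$nodes[out[, 4], , drop = FALSE]
  nrm <- cross3(b - a, d - a)
  flip <- nrm[, axis] * normal_sign < 0
  out[flip, ] <- out[flip, c(1, 4, 3, 2)]
  out
}
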