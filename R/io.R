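# Plain-text interchange: trajectory CSV files (comma-separated, header
# row, '#' metadata comments, full float precision), legacy ASCII VTK
# meshes with a `region` cell field, and JSON case configurations. File
# formats use 0-based node and step ids; the in-memory API is 1-based.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a keypoint trajectory to CSV
#'
#' Columns: `step` (0-based load step), `node_id` (0-based), then one
#' column per tracked displacement component (`ux`, `uy`, `uz` subset).
#' Metadata is stored in leading `# key=value` comment lines.
#'
#' @param D Trajectory array (steps x keypoints x components), mm.
#' @param tracking The [tracking_set()] the trajectory was extracted with.
#' @param file Output path.
#' @param meta Named list of metadata scalars for the header.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(D, tracking, file, meta = list()) {
  comps <- c("ux", "uy", "uz")[tracking$comps]
  con <- file(file, open = "wb")
  on.exit(close(con))
  wline <- function(s) writeLines(s, con, sep = "\n")
  for (nm in names(meta)) wline(sprintf("# %s=%s", nm, as.character(meta[[nm]])))
  wline(paste(c("step", "node_id", comps), collapse = ","))
  ns <- dim(D)[1]; nk <- dim(D)[2]
  for (s in seq_len(ns)) for (k in seq_len(nk)) {
    wline(paste(c(s - 1, tracking$nodes[k] - 1, fmt_num(D[s, k, ])), collapse = ","))
  }
  invisible(file)
}

#' Read a keypoint trajectory CSV
#'
#' @param file Path written by [write_trajectory_csv()].
#' @return List with `D` (trajectory array), `tracking` (a
#'   [tracking_set()]) and `meta` (named character list).
#' @export
read_trajectory_csv <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- read.csv(file, comment.char = "#")
  comps <- match(intersect(c("ux", "uy", "uz"), names(df)), c("ux", "uy", "uz"))
  nodes <- unique(df$node_id) + 1L
  steps <- sort(unique(df$step))
  D <- array(0, dim = c(length(steps), length(nodes), length(comps)))
  cn <- c("ux", "uy", "uz")[comps]
  for (i in seq_len(nrow(df))) {
    s <- match(df$step[i], steps)
    k <- match(df$node_id[i] + 1L, nodes)
    D[s, k, ] <- as.numeric(df[i, cn])
  }
  list(D = D, tracking = tracking_set(nodes, comps), meta = meta)
}

#' Write a full displacement history to CSV
#'
#' One row per (step, node): columns `step`, `node_id`, `ux`, `uy`, `uz`,
#' 0-based ids, full float precision.
#'
#' @param history A `displacement_history`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_history_csv <- function(history, file) {
  ns <- dim(history)[1]; nn <- dim(history)[2]
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines("step,node_id,ux,uy,uz", con)
  for (s in seq_len(ns)) {
    block <- history[s, , , drop = TRUE]
    lines <- paste(s - 1, seq_len(nn) - 1,
                   fmt_num(block[, 1]), fmt_num(block[, 2]), fmt_num(block[, 3]),
                   sep = ",")
    writeLines(lines, con)
  }
  invisible(file)
}

#' Export a mesh as legacy ASCII VTK
#'
#' Writes an unstructured grid with an integer `region` cell field (0 =
#' base, 1 = abnormal) and, optionally, a nodal `displacement` vector
#' field. Connectivity is 0-based as VTK requires.
#'
#' @param mesh An `fe_mesh`.
#' @param file Output path (conventionally `.vtk`).
#' @param displacement Optional `n_nodes x 3` matrix (e.g. one step of a
#'   history).
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, file, displacement = NULL) {
  con <- file(file, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems); npe <- ncol(mesh$elems)
  w("# vtk DataFile Version 3.0")
  w("softinverse mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", nn))
  writeLines(apply(mesh$nodes, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  w(sprintf("CELLS %d %d", ne, ne * (npe + 1)))
  writeLines(apply(mesh$elems, 1, function(e) paste(c(npe, e - 1), collapse = " ")), con)
  w(sprintf("CELL_TYPES %d", ne))
  writeLines(rep(if (mesh$type == "hex8") "12" else "5", ne), con)
  w(sprintf("CELL_DATA %d", ne))
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(as.integer(mesh$region == "abnormal")), con)
  if (!is.null(displacement)) {
    w(sprintf("POINT_DATA %d", nn))
    w("VECTORS displacement double")
    writeLines(apply(displacement, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  }
  invisible(file)
}

#' Export a displacement history as a VTK time series
#'
#' Writes one legacy VTK file per load step (`<base>_0000.vtk`,
#' `<base>_0001.vtk`, ...), each carrying the mesh, its region labels and
#' the nodal displacement of that step.
#'
#' @param mesh The `fe_mesh` the history belongs to.
#' @param history A `displacement_history`.
#' @param base Path prefix for the series.
#' @return Character vector of the written paths, invisibly.
#' @export
write_history_vtk <- function(mesh, history, base) {
  paths <- character(dim(history)[1])
  for (s in seq_len(dim(history)[1])) {
    paths[s] <- sprintf("%s_%04d.vtk", base, s - 1)
    write_mesh_vtk(mesh, paths[s], displacement = history[s, , , drop = TRUE])
  }
  invisible(paths)
}

#' Write a binary mask as PNG
#'
#' Stores the mask as an 8-bit grayscale image (0/255).
#'
#' @param mask A `binary_mask`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, file) {
  if (!requireNamespace("png", quietly = TRUE)) {
    si_stop("the 'png' package is required for PNG export", "invalid_config")
  }
  png::writePNG(pmin(pmax(unclass(mask), 0), 1), file)
  invisible(file)
}

#' Write a binary mask as CSV
#'
#' @param mask A `binary_mask`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mask_csv <- function(mask, file) {
  write.table(unclass(mask), file, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a case configuration to JSON
#'
#' @param config A named list (case name, mesh preset, optimizer block,
#'   noise block, overrides).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_case_config <- function(config, file) {
  jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a case configuration from JSON
#'
#' @param file Path to a JSON configuration.
#' @return The configuration list.
#' @export
read_case_config <- function(file) {
  if (!file.exists(file)) si_stop(paste("config file not found:", file), "schema_error")
  cfg <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(cfg$case)) si_stop("config is missing required field 'case'", "schema_error")
  cfg
}
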