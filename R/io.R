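#' Write a tube mesh as Wavefront OBJ
#'
#' Faces are written as polygon loops (lateral cells first, then the two
#' caps).
#'
#' @param mesh a \code{tube_mesh}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chiratube tube mesh", con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(vapply(all_faces(mesh),
                    function(l) paste("f", paste(l, collapse = " ")),
                    character(1)), con)
  invisible(path)
}

#' Read a tube mesh from Wavefront OBJ
#'
#' Inverse of \code{\link{write_mesh_obj}}: the last two faces are taken as
#' the top and bottom caps.
#'
#' @param path OBJ file written by \code{\link{write_mesh_obj}}.
#' @param geometry optional geometry list to attach.
#' @return A \code{tube_mesh}.
#' @export
read_mesh_obj <- function(path, geometry = NULL) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, " +"), function(p)
    as.numeric(p[2:4])))
  colnames(V) <- c("x", "y", "z")
  faces <- lapply(strsplit(fl, " +"), function(p)
    as.integer(sub("/.*", "", p[-1])))
  nf <- length(faces)
  if (nf < 3) stop("OBJ does not contain lateral faces plus two caps")
  mesh <- structure(list(vertices = V, faces = faces[seq_len(nf - 2L)],
                         cap_top = faces[[nf - 1L]],
                         cap_bottom = faces[[nf]],
                         geometry = geometry),
                    class = "tube_mesh")
  if (is.null(geometry))
    mesh$geometry <- list(diameter = 2 * stats::median(
      sqrt(V[mesh$cap_top, 1]^2 + V[mesh$cap_top, 2]^2)),
      rect_width = NA, rect_height = NA,
      z_bottom = min(V[, 3]), z_top = max(V[, 3]))
  mesh
}

#' Write a tube mesh as legacy VTK polydata (for visualization)
#'
#' @param mesh a \code{tube_mesh}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  fl <- all_faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "chiratube tube mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(mesh$vertices))), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", length(fl),
                     length(fl) + sum(lengths(fl))), con)
  writeLines(vapply(fl, function(l)
    paste(c(length(l), l - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' Lossless native JSON state dump for exact restart
#'
#' @param mesh a \code{tube_mesh}.
#' @param path output file.
#' @param params optional \code{\link{model_params}} to embed.
#' @param config_hash optional configuration hash string.
#' @return Invisibly, the path.
#' @export
save_state_json <- function(mesh, path, params = NULL, config_hash = NULL) {
  obj <- list(vertices = unname(mesh$vertices), faces = mesh$faces,
              cap_top = mesh$cap_top, cap_bottom = mesh$cap_bottom,
              geometry = mesh$geometry)
  if (!is.null(params)) obj$params <- unclass(params)
  if (!is.null(config_hash)) obj$config <- config_hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a tube mesh from a JSON state dump
#'
#' @param path file written by \code{\link{save_state_json}}.
#' @return A list: \code{mesh} and (if embedded) \code{params}.
#' @export
load_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(obj$vertices)
  colnames(V) <- c("x", "y", "z")
  faces <- lapply(obj$faces, as.integer)
  mesh <- structure(list(vertices = V, faces = faces,
                         cap_top = as.integer(obj$cap_top),
                         cap_bottom = as.integer(obj$cap_bottom),
                         geometry = obj$geometry),
                    class = "tube_mesh")
  params <- if (!is.null(obj$params)) do.call(model_params, obj$params)
  list(mesh = mesh, params = params)
}

# short stable hash of a configuration string (output provenance tag)
config_hash <- function(s) {
  b <- utf8ToInt(s)
  sprintf("%08x", sum(b * (seq_along(b) %% 31 + 1)) %% 2147483647)
}

#' Shape/sliding analysis of a finished run, written as CSV tables
#'
#' Produces the standard quantification tables from a trajectory:
#' \code{shape_stats.csv} (per-cell axis angle and deviation at first and
#' last saved state), \code{twist_trace.csv}, \code{sliding.csv},
#' \code{tilt_counts.csv} and \code{intercalations.csv}.
#'
#' @param traj a \code{trajectory}.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, \code{out_dir}.
#' @export
analyze_run <- function(traj, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s0 <- shape_stats(mesh_at(traj, 1))
  s1 <- shape_stats(traj$mesh)
  ss <- rbind(cbind(t = traj$times[1], s0$cells),
              cbind(t = max(traj$times), s1$cells))
  utils::write.csv(ss, file.path(out_dir, "shape_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(twist_trace(traj), file.path(out_dir, "twist_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(cell_sliding(traj), file.path(out_dir, "sliding.csv"),
                   row.names = FALSE)
  bt <- boundary_tilt(traj)
  utils::write.csv(data.frame(class = names(bt$counts),
                              count = as.integer(bt$counts)),
                   file.path(out_dir, "tilt_counts.csv"), row.names = FALSE)
  utils::write.csv(detect_intercalation(traj),
                   file.path(out_dir, "intercalations.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
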