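#' Wrap a periodic planar tessellation onto a cylinder
#'
#' Maps the periodic width coordinate to azimuth (\eqn{\phi = 2\pi x / W})
#' at radius \code{diameter/2} and the height coordinate to the tube axis
#' z (posterior at z = 0, anterior at the top). The two rows of boundary
#' vertices become the end rings, from which the two cap faces are built,
#' giving a closed orientable surface (every edge shared by exactly two
#' faces, Euler characteristic 2) with outward-pointing face normals.
#'
#' @param tess a \code{planar_tessellation} (periodic in width).
#' @param diameter nominal tube diameter (default 5.0), used for the wrap
#'   radius.
#' @return A \code{tube_mesh}: \code{vertices} (n x 3), \code{faces}
#'   (lateral cell loops), \code{cap_top}/\code{cap_bottom} (ordered ring
#'   loops) and a \code{geometry} list.
#' @export
wrap_to_cylinder <- function(tess, diameter = 5.0) {
  if (!inherits(tess, "planar_tessellation"))
    stop("'tess' must be a planar_tessellation (periodic in width)")
  if (diameter <= 0) stop("'diameter' must be positive")
  W <- tess$rect_width; H <- tess$rect_height
  r <- diameter / 2
  phi <- 2 * pi * tess$vertices[, 1] / W
  V <- cbind(x = r * cos(phi), y = r * sin(phi), z = tess$vertices[, 2])

  bot <- which(tess$boundary == 1L)
  top <- which(tess$boundary == 2L)
  if (length(bot) < 3 || length(top) < 3)
    stop("degenerate tessellation: fewer than 3 boundary vertices on a ring")
  # cap winding gives outward normals: top cap (+z) counter-clockwise seen
  # from above, bottom cap (-z) clockwise seen from above
  cap_top <- top[order(atan2(V[top, 2], V[top, 1]))]
  cap_bottom <- bot[order(-atan2(V[bot, 2], V[bot, 1]))]

  mesh <- structure(list(
    vertices = V,
    faces = tess$faces,
    cap_top = as.integer(cap_top),
    cap_bottom = as.integer(cap_bottom),
    geometry = list(diameter = diameter, rect_width = W, rect_height = H,
                    z_bottom = 0, z_top = H)),
    class = "tube_mesh")
  validate_tube_mesh(mesh)
  mesh
}

#' Unwrap a tube mesh back to the plane (inverse of the wrap map)
#'
#' Exact inverse of \code{\link{wrap_to_cylinder}} for vertices on the
#' cylinder: azimuth back to the width coordinate (in \code{[0, W)}), z to
#' height. For shape analysis of a deformed tube use
#' \code{\link{project_unroll}}, which first projects radially onto the
#' nominal cylinder.
#'
#' @param mesh a \code{tube_mesh}.
#' @return An n x 2 matrix of planar coordinates.
#' @export
unwrap_to_plane <- function(mesh) {
  W <- mesh$geometry$rect_width
  phi <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])
  x <- (phi * W / (2 * pi)) %% W
  cbind(x = x, y = mesh$vertices[, 3])
}

#' @export
print.tube_mesh <- function(x, ...) {
  ed <- mesh_edge_table(x)
  cat(sprintf("Tube mesh: %d vertices, %d lateral cells + 2 caps, %d edges\n",
              nrow(x$vertices), length(x$faces), nrow(ed$edges)))
  cat(sprintf("  z in [%.3g, %.3g], enclosed volume %.4g\n",
              min(x$vertices[, 3]), max(x$vertices[, 3]),
              enclosed_volume(x)))
  invisible(x)
}

# all faces (lateral then caps) as a list of loops
all_faces <- function(mesh) c(mesh$faces, list(mesh$cap_top, mesh$cap_bottom))

# CSR flattening of face loops, 0-based, for the compiled core
faces_csr <- function(faces) {
  lens <- lengths(faces)
  list(fptr = as.integer(c(0L, cumsum(lens))),
       fvert = as.integer(unlist(faces) - 1L))
}

# Unique undirected edges of the lateral faces with the edge-energy weight
# multiplier emult (so U_L = sigma_L * sum_e emult_e * L_e). Two counting
# conventions for the edge energy are supported:
#   per_cell (default): every cell contributes its own edge sum, so an
#     interior edge is counted through both incident cells (multiplier 2,
#     plus w_special - 1 per cell declaring it special);
#   per_edge: each physical edge carries the energy density once, with
#     weight w_special if it is a special edge of either incident cell.
# 'special' is an optional per-cell list of 2-column vertex-pair matrices.
mesh_edge_table <- function(mesh, special = NULL, w_special = 1,
                            edge_count = "per_cell") {
  a <- integer(0); b <- integer(0)
  for (loop in mesh$faces) {
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
  }
  key <- paste(a, b)
  first <- !duplicated(key)
  edges <- cbind(v1 = a[first], v2 = b[first])
  mult <- as.numeric(table(key)[key[first]])
  nsp <- numeric(nrow(edges))  # how many cells declare the edge special
  if (!is.null(special)) {
    sa <- integer(0); sb <- integer(0)
    for (sp in special) {
      if (is.null(sp) || nrow(sp) == 0) next
      sa <- c(sa, pmin(sp[, 1], sp[, 2]))
      sb <- c(sb, pmax(sp[, 1], sp[, 2]))
    }
    if (length(sa)) {
      add <- table(paste(sa, sb))
      idx <- match(names(add), key[first])
      if (anyNA(idx)) stop("special edge not found among mesh edges")
      nsp[idx] <- as.numeric(add)
    }
  }
  emult <- if (edge_count == "per_cell") {
    mult + (w_special - 1) * nsp
  } else {
    ifelse(nsp > 0, w_special, 1)
  }
  ring <- c(mesh$cap_top, mesh$cap_bottom)
  reco_ok <- !(edges[, 1] %in% ring | edges[, 2] %in% ring) & mult == 2
  list(edges = edges, mult = mult, emult = emult, reco_ok = reco_ok)
}

# Everything the compiled core needs, in one bundle.
mesh_topology <- function(mesh, special = NULL, w_special = 1,
                          edge_count = "per_cell") {
  csr <- faces_csr(all_faces(mesh))
  ed <- mesh_edge_table(mesh, special, w_special, edge_count)
  list(fptr = csr$fptr, fvert = csr$fvert, nlat = length(mesh$faces),
       e1 = as.integer(ed$edges[, 1] - 1L), e2 = as.integer(ed$edges[, 2] - 1L),
       emult = ed$emult, reco_ok = ed$reco_ok, edges = ed$edges,
       topv = as.integer(mesh$cap_top - 1L),
       botv = as.integer(mesh$cap_bottom - 1L))
}

#' Area of a (generally non-planar) polygonal face
#'
#' The area of a face loop in 3D is defined by centroid-fan triangulation:
#' the sum of the triangle areas (centroid, v_k, v_k+1). For a planar face
#' this equals the ordinary polygon area.
#'
#' @param mesh a \code{tube_mesh}.
#' @param face either a face index (into the lateral faces) or an integer
#'   vertex loop.
#' @return The non-negative face area.
#' @export
polygon_area <- function(mesh, face) {
  loop <- if (length(face) == 1L) mesh$faces[[face]] else as.integer(face)
  if (length(loop) < 3) stop("face must have at least 3 vertices")
  if (any(loop == c(loop[-1], loop[1])))
    stop("face has repeated consecutive vertices")
  csr <- faces_csr(list(loop))
  as.numeric(cpp_face_areas(mesh$vertices, csr$fptr, csr$fvert))
}

#' Areas of all lateral faces
#' @param mesh a \code{tube_mesh}.
#' @return Numeric vector of cell areas (centroid-fan definition).
#' @export
cell_areas <- function(mesh) {
  csr <- faces_csr(mesh$faces)
  as.numeric(cpp_face_areas(mesh$vertices, csr$fptr, csr$fvert))
}

#' Enclosed volume of a closed tube mesh
#'
#' Signed volume by the divergence theorem over the centroid-fan
#' triangulation of all faces, caps included; positive when face normals
#' point outward.
#'
#' @param mesh a \code{tube_mesh}.
#' @return The enclosed volume.
#' @export
enclosed_volume <- function(mesh) {
  check_closed(mesh)
  csr <- faces_csr(all_faces(mesh))
  cpp_enclosed_volume(mesh$vertices, csr$fptr, csr$fvert)
}

check_closed <- function(mesh) {
  a <- integer(0); b <- integer(0)
  for (loop in all_faces(mesh)) {
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
  }
  cnt <- table(paste(a, b))
  if (any(cnt != 2))
    stop("mesh is not closed: ", sum(cnt != 2),
         " edge(s) not shared by exactly 2 faces")
  invisible(TRUE)
}

#' Validate the structural invariants of a tube mesh
#'
#' Checks that every face has at least 3 vertices, every edge (caps
#' included) is shared by exactly two faces, the Euler characteristic
#' V - E + F equals 2 (sphere topology), and the enclosed volume is
#' positive (consistent outward winding).
#'
#' @param mesh a \code{tube_mesh}.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_tube_mesh <- function(mesh) {
  fl <- all_faces(mesh)
  if (any(lengths(fl) < 3)) stop("face with fewer than 3 vertices")
  check_closed(mesh)
  a <- integer(0); b <- integer(0)
  for (loop in fl) {
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
  }
  nE <- sum(!duplicated(paste(a, b)))
  nV <- nrow(mesh$vertices)
  nF <- length(fl)
  if (nV - nE + nF != 2)
    stop(sprintf("Euler characteristic V-E+F = %d, expected 2",
                 nV - nE + nF))
  if (enclosed_volume(mesh) <= 0)
    stop("enclosed volume not positive: inconsistent face winding")
  invisible(TRUE)
}

# centroids of the lateral faces (n_lat x 3)
cell_centroids <- function(mesh) {
  t(vapply(mesh$faces,
           function(loop) colMeans(mesh$vertices[loop, , drop = FALSE]),
           numeric(3)))
}

# lateral-cell adjacency (shared edge) as a list of neighbor index vectors
cell_adjacency <- function(faces) {
  a <- integer(0); b <- integer(0); f <- integer(0)
  for (i in seq_along(faces)) {
    loop <- faces[[i]]
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
    f <- c(f, rep.int(i, length(loop)))
  }
  key <- paste(a, b)
  adj <- vector("list", length(faces))
  for (grp in split(f, key)) {
    if (length(grp) == 2L) {
      adj[[grp[1]]] <- c(adj[[grp[1]]], grp[2])
      adj[[grp[2]]] <- c(adj[[grp[2]]], grp[1])
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}
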