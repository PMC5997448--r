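#' Assign polarity vectors to every lateral cell
#'
#' Each cell receives a unit polarity vector lying in its local tangent
#' plane (orthogonal to the outward radial direction at the cell centroid),
#' rotated by \code{deflection_deg} away from the tube (+z, anterior) axis.
#' Positive deflection tilts the vector toward decreasing azimuth, which is
#' leftward when the tube is viewed from outside with anterior up; this is
#' the package's orientation contract linking +30 degrees to leftward cell
#' tilt and a positive (left-handed screw) twist.
#'
#' @param mesh a \code{tube_mesh}.
#' @param deflection_deg deflection angle from the AP axis in degrees,
#'   \code{|deflection_deg| < 90}.
#' @return An n_cells x 3 matrix of unit polarity vectors.
#' @export
assign_polarity <- function(mesh, deflection_deg) {
  if (abs(deflection_deg) >= 90)
    stop("'deflection_deg' must satisfy |deflection_deg| < 90")
  cen <- cell_centroids(mesh)
  rho <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  if (any(rho < 1e-9))
    stop("cell centroid on the tube axis: radial direction undefined")
  # azimuthal unit vector at the centroid
  phihat <- cbind(-cen[, 2] / rho, cen[, 1] / rho)
  d <- deflection_deg * pi / 180
  cbind(-sin(d) * phihat[, 1], -sin(d) * phihat[, 2], rep(cos(d), nrow(cen)))
}

#' Select the two strongly contracting ("special") edges of a cell
#'
#' The plane through the cell centroid perpendicular to the polarity vector
#' crosses exactly two edges of a (convex) cell; these are the edges that
#' undergo the strongest contraction during chirality induction. Selection
#' is a strict sign test of \eqn{p \cdot (v - c)} over the two endpoints of
#' every edge. If a vertex falls exactly on the plane the plane is offset
#' by 1e-9 along the polarity and the test retried once; a persistent
#' failure flags the cell degenerate (no special edges) with a warning.
#'
#' @param mesh a \code{tube_mesh}.
#' @param cell lateral face index.
#' @param polarity unit polarity vector (length 3).
#' @return A 2 x 2 integer matrix of vertex pairs (one row per special
#'   edge), or a 0-row matrix for a degenerate cell.
#' @export
select_special_edges <- function(mesh, cell, polarity) {
  loop <- mesh$faces[[cell]]
  vv <- mesh$vertices[loop, , drop = FALSE]
  cen <- colMeans(vv)
  for (off in c(0, 1e-9)) {
    s <- as.numeric(vv %*% polarity) - sum(cen * polarity) - off
    nx <- c(seq_along(loop)[-1], 1L)
    crossing <- s * s[nx] < 0
    if (sum(crossing) == 2L) {
      k <- which(crossing)
      return(cbind(v1 = loop[k], v2 = loop[nx[k]]))
    }
  }
  warning("cell ", cell, ": polarity plane crosses ", sum(crossing),
          " edges; flagged degenerate (no special edges)")
  matrix(integer(0), 0, 2, dimnames = list(NULL, c("v1", "v2")))
}

# special edges for every lateral cell (list of 2-column matrices)
select_all_special_edges <- function(mesh, polarity) {
  lapply(seq_along(mesh$faces), function(i)
    select_special_edges(mesh, i, polarity[i, ]))
}

#' Imprint chiral cell shapes on a symmetric tube
#'
#' Runs the full vertex dynamics on a freshly wrapped (achiral) tube with
#' the two special edges of each cell carrying weight \code{w_special} and
#' all other edges weight 1, for the protocol's induction duration. The
#' anisotropic contraction elongates each cell along its polarity, tilting
#' cell axes and edges (leftward for positive deflection). Special edges
#' are selected once from the starting geometry; a special edge destroyed
#' by a reconnection is dropped unless \code{reselect = TRUE}. The returned
#' tube is the t = 0 initial state for the relaxation experiments.
#'
#' @param mesh a symmetric \code{tube_mesh} (output of
#'   \code{\link{wrap_to_cylinder}}).
#' @param protocol a \code{\link{chirality_protocol}}.
#' @param params a \code{\link{model_params}}.
#' @param reconnect allow vertex reconnection during induction. Default
#'   FALSE: reconnections during induction consume the strongly contracted
#'   special edges, erasing the imprinted chirality (the t = 0 edge-angle
#'   bias all but vanishes) and reversing the subsequent twist, so the
#'   anisotropic contraction phase runs without junction remodeling.
#' @param reselect re-select a cell's special edges from the current
#'   geometry when a reconnection destroys one (default FALSE: the
#'   destroyed edge is dropped and the cell's anisotropy fades as its
#'   junctions remodel).
#' @param save_every state-recording interval of the induction run.
#' @return A list: \code{mesh} (the chiral tube), \code{polarity},
#'   \code{special} (per-cell special edges at the end of induction) and
#'   \code{trajectory} (the induction run record).
#' @export
build_chiral_tube <- function(mesh, protocol = chirality_protocol("wildtype"),
                              params = model_params(), reconnect = FALSE,
                              reselect = FALSE, save_every = 0.5) {
  polarity <- assign_polarity(mesh, protocol$deflection_deg)
  special <- select_all_special_edges(mesh, polarity)
  traj <- run_dynamics(mesh, params, t_end = protocol$t_induction,
                       reconnect = reconnect, save_every = save_every,
                       chirality = list(polarity = polarity,
                                        special = special,
                                        w_special = protocol$w_special,
                                        reselect = reselect))
  list(mesh = traj$mesh, polarity = polarity,
       special = traj$special, trajectory = traj)
}
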