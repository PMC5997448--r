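#' Project the tube surface onto a cylinder and unroll it
#'
#' Vertices are projected radially onto a geometrical cylinder of the given
#' diameter and the cylinder surface is extended to a flat plane:
#' \code{x = phi * diameter/2} (circumferential, azimuth in the standard
#' mathematical sense so leftward is -x), \code{y = z} (axial). Each face
#' loop is unwrapped locally so seam-crossing polygons stay contiguous.
#' Polygons close to the peripheral parts of the tube -- within two cell
#' rows of either end -- are flagged for exclusion from shape statistics.
#'
#' @param mesh a \code{tube_mesh}.
#' @param diameter projection cylinder diameter (default the mesh's nominal
#'   tube diameter).
#' @return A list: \code{polygons} (per-cell k x 2 planar loops),
#'   \code{centroids} (planar polygon centroids), \code{excluded} (logical
#'   per cell), \code{radius}, and the per-vertex planar \code{vertices}.
#' @export
project_unroll <- function(mesh, diameter = mesh$geometry$diameter) {
  V <- mesh$vertices
  rho <- sqrt(V[, 1]^2 + V[, 2]^2)
  if (any(rho < 1e-9)) stop("vertex on the tube axis: azimuth undefined")
  r <- diameter / 2
  phi <- atan2(V[, 2], V[, 1])
  polys <- lapply(mesh$faces, function(loop) {
    ph <- phi[loop]
    d <- ph - ph[1]
    d <- d - 2 * pi * round(d / (2 * pi))
    cbind(x = (ph[1] + d) * r, y = V[loop, 3])
  })
  cen <- t(vapply(polys, colMeans, numeric(2)))

  ring <- c(mesh$cap_top, mesh$cap_bottom)
  row1 <- vapply(mesh$faces, function(l) any(l %in% ring), logical(1))
  adj <- cell_adjacency(mesh$faces)
  row2 <- vapply(seq_along(adj),
                 function(i) any(row1[adj[[i]]]), logical(1))
  list(polygons = polys, centroids = cen, excluded = row1 | row2,
       radius = r, vertices = cbind(x = phi * r, y = V[, 3]), phi = phi)
}

#' Momental-ellipse axis and deviation of a planar polygon
#'
#' The polygon is approximated by its ellipse of inertia (matching second
#' area moments about the area centroid). The major-axis direction defines
#' the polygon axis; its angle \code{theta} is measured from the axial (y)
#' direction, positive toward +x, folded into (-90, 90]. The deviation from
#' a circle is \code{(d_max - d_min) / (d_max + d_min)} with \code{d_max},
#' \code{d_min} the major/minor axis lengths. For a (near-)circular polygon
#' the axis is undefined and \code{theta} is reported as 0.
#'
#' @param poly a k x 2 matrix of polygon vertices (either winding).
#' @return A list: \code{theta} (degrees), \code{deviation}, \code{d_max},
#'   \code{d_min}.
#' @export
polygon_axis_deviation <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  A <- polygon_area_2d(x, y)
  if (A < 0) { x <- rev(x); y <- rev(y); A <- -A }
  if (A < 1e-12) stop("degenerate polygon: zero area")
  x1 <- c(x[-1], x[1]); y1 <- c(y[-1], y[1])
  cr <- x * y1 - x1 * y
  cx <- sum((x + x1) * cr) / (6 * A)
  cy <- sum((y + y1) * cr) / (6 * A)
  x <- x - cx; y <- y - cy
  x1 <- x1 - cx; y1 <- y1 - cy
  cr <- x * y1 - x1 * y
  sxx <- sum((x^2 + x * x1 + x1^2) * cr) / 12
  syy <- sum((y^2 + y * y1 + y1^2) * cr) / 12
  sxy <- sum((x * y1 + 2 * x * y + 2 * x1 * y1 + x1 * y) * cr) / 24
  J <- matrix(c(sxx, sxy, sxy, syy), 2, 2)
  eg <- eigen(J, symmetric = TRUE)
  lmax <- eg$values[1]; lmin <- eg$values[2]
  d_max <- 4 * sqrt(max(lmax, 0) / A)
  d_min <- 4 * sqrt(max(lmin, 0) / A)
  theta <- if ((lmax - lmin) / max(lmax, 1e-300) < 1e-9) 0 else {
    v <- eg$vectors[, 1]
    fold_angle(atan2(v[1], v[2]) * 180 / pi)
  }
  list(theta = theta,
       deviation = (d_max - d_min) / (d_max + d_min),
       d_max = d_max, d_min = d_min)
}

# fold an angle in degrees into (-90, 90]
fold_angle <- function(a) {
  a <- a - 180 * round(a / 180)
  a[a <= -90 + 1e-12] <- a[a <= -90 + 1e-12] + 180
  a
}

#' Cell-axis and edge-angle statistics of a tube state
#'
#' Applies \code{\link{project_unroll}} and \code{\link{polygon_axis_deviation}}
#' to every non-peripheral cell and measures the angle of every edge of the
#' included cells from the tube axis.
#'
#' @param mesh a \code{tube_mesh}.
#' @param diameter projection cylinder diameter.
#' @param include_peripheral include cells within two rows of the ends.
#' @return A list: \code{cells} data frame (cell, theta, deviation,
#'   excluded) and \code{edge_angles} (numeric vector, degrees in
#'   (-90, 90]).
#' @export
shape_stats <- function(mesh, diameter = mesh$geometry$diameter,
                        include_peripheral = FALSE) {
  pr <- project_unroll(mesh, diameter)
  res <- lapply(pr$polygons, polygon_axis_deviation)
  cells <- data.frame(cell = seq_along(res),
                      theta = vapply(res, `[[`, numeric(1), "theta"),
                      deviation = vapply(res, `[[`, numeric(1), "deviation"),
                      excluded = pr$excluded)
  keep <- if (include_peripheral) rep(TRUE, length(mesh$faces)) else
    !pr$excluded
  a <- integer(0); b <- integer(0)
  for (i in which(keep)) {
    loop <- mesh$faces[[i]]
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
  }
  first <- !duplicated(paste(a, b))
  a <- a[first]; b <- b[first]
  dphi <- pr$phi[b] - pr$phi[a]
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  dx <- dphi * pr$radius
  dy <- mesh$vertices[b, 3] - mesh$vertices[a, 3]
  list(cells = cells,
       edge_angles = fold_angle(atan2(dx, dy) * 180 / pi))
}

#' Percentage histogram and left-right bias of an angle sample
#'
#' @param angles angles in degrees, (-90, 90].
#' @param breaks histogram breaks (default 15-degree bins from -90 to 90).
#' @return A list: \code{mids}, \code{percent} (sums to 100) and
#'   \code{bias}, the fraction of angles in (-90, 0) minus the fraction in
#'   (0, 90) -- positive for a leftward-slanted sample.
#' @export
angle_histogram <- function(angles, breaks = seq(-90, 90, by = 15)) {
  hh <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  n <- length(angles)
  list(mids = hh$mids, percent = 100 * hh$counts / n,
       bias = (sum(angles > -90 & angles < 0) - sum(angles > 0 & angles < 90)) / n)
}

# unwrap angle time series (rows = time) so per-step changes < pi accumulate
unwrap_time <- function(ph) {
  if (nrow(ph) < 2) return(ph)
  dd <- ph[-1, , drop = FALSE] - ph[-nrow(ph), , drop = FALSE]
  dd <- dd - 2 * pi * round(dd / (2 * pi))
  cs <- apply(dd, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  rbind(ph[1, ], sweep(cs, 2, ph[1, ], "+"))
}

# azimuth measured counter-clockwise viewed from the posterior (-z) end;
# the package's positive twist direction (left-handed screw) increases it
posterior_azimuth <- function(V) -atan2(V[, 2], V[, 1])

#' Twist angle between two states of the same tube
#'
#' The per-vertex azimuth change (measured counter-clockwise viewed from
#' the posterior end, so a left-handed screw is positive) is averaged over
#' the top ring and over the bottom ring; the twist is the top mean minus
#' the bottom mean, in degrees. Rigid rotations of the whole tube cancel.
#' Per-vertex changes are wrapped to (-180, 180]; use
#' \code{\link{twist_trace}} for accumulated twists beyond half a turn.
#'
#' @param mesh current \code{tube_mesh}.
#' @param ref_mesh reference (t = 0) mesh sharing the ring topology.
#' @return Twist angle in degrees.
#' @export
twist_angle <- function(mesh, ref_mesh) {
  if (!identical(mesh$cap_top, ref_mesh$cap_top) ||
      !identical(mesh$cap_bottom, ref_mesh$cap_bottom))
    stop("meshes do not share ring topology")
  d <- posterior_azimuth(mesh$vertices) - posterior_azimuth(ref_mesh$vertices)
  d <- d - 2 * pi * round(d / (2 * pi))
  (mean(d[mesh$cap_top]) - mean(d[mesh$cap_bottom])) * 180 / pi
}

#' Twist-angle cross-check by axial regression
#'
#' Alternative twist statistic: slope of the per-vertex azimuth change
#' against z over all vertices, times the tube height.
#'
#' @inheritParams twist_angle
#' @return Twist angle in degrees.
#' @export
twist_angle_regression <- function(mesh, ref_mesh) {
  d <- posterior_azimuth(mesh$vertices) - posterior_azimuth(ref_mesh$vertices)
  d <- d - 2 * pi * round(d / (2 * pi))
  z <- ref_mesh$vertices[, 3]
  slope <- stats::cov(z, d) / stats::var(z)
  slope * (max(z) - min(z)) * 180 / pi
}

#' Twist-angle trace of a trajectory
#'
#' Ring azimuths are unwrapped along time (saved states are dense enough
#' that per-interval changes stay far below half a turn), so twists beyond
#' 180 degrees accumulate correctly.
#'
#' @param traj a \code{trajectory}.
#' @return A data frame with columns \code{t} and \code{twist} (degrees).
#' @export
twist_trace <- function(traj) {
  ring_top <- traj$mesh$cap_top; ring_bot <- traj$mesh$cap_bottom
  unwrap_rows <- function(ids) {
    ph <- matrix(vapply(traj$states,
                        function(V) posterior_azimuth(V[ids, , drop = FALSE]),
                        numeric(length(ids))),
                 ncol = length(ids), byrow = TRUE)
    rowMeans(unwrap_time(ph))
  }
  top <- unwrap_rows(ring_top); bot <- unwrap_rows(ring_bot)
  data.frame(t = traj$times,
             twist = ((top - top[1]) - (bot - bot[1])) * 180 / pi)
}

#' Apply a synthetic helical (twist) map to a tube
#'
#' Rotates every vertex about the tube axis by \code{c_deg * z} in the
#' positive twist direction (counter-clockwise viewed from the posterior
#' end), so \code{\link{twist_angle}} against the original mesh returns
#' exactly \code{c_deg * (z_top - z_bottom)}.
#'
#' @param mesh a \code{tube_mesh}.
#' @param c_deg twist rate in degrees per unit length.
#' @return The twisted mesh.
#' @export
apply_helical_twist <- function(mesh, c_deg) {
  V <- mesh$vertices
  ang <- -(c_deg * pi / 180) * V[, 3]  # posterior-ccw = standard cw
  x <- V[, 1] * cos(ang) - V[, 2] * sin(ang)
  y <- V[, 1] * sin(ang) + V[, 2] * cos(ang)
  mesh$vertices <- cbind(x = x, y = y, z = V[, 3])
  mesh
}

# mirror image of a tube (x -> -x); loops reversed to keep outward winding
mirror_mesh <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- lapply(mesh$faces, rev)
  mesh$cap_top <- rev(mesh$cap_top)
  mesh$cap_bottom <- rev(mesh$cap_bottom)
  mesh
}

#' Centroid tracks of all cells on the unrolled plane
#'
#' Cell centroids are projected onto the nominal cylinder and unrolled;
#' the circumferential coordinate is unwrapped along time per cell so
#' displacements accumulate across the seam.
#'
#' @param traj a \code{trajectory}.
#' @param diameter projection cylinder diameter.
#' @return A list: \code{t}, \code{x} and \code{y} (saved-states x cells
#'   matrices of circumferential/axial centroid coordinates).
#' @export
cell_tracks <- function(traj, diameter = traj$mesh$geometry$diameter) {
  r <- diameter / 2
  nsave <- length(traj$states)
  ncell <- length(traj$mesh$faces)
  ph <- matrix(0, nsave, ncell)
  yy <- matrix(0, nsave, ncell)
  for (k in seq_len(nsave)) {
    m <- mesh_at(traj, k)
    cen <- cell_centroids(m)
    ph[k, ] <- atan2(cen[, 2], cen[, 1])
    yy[k, ] <- cen[, 3]
  }
  list(t = traj$times, x = unwrap_time(ph) * r, y = yy)
}

# (upper, subjacent) cell pairs: for every cell, the adjacent neighbor
# below it with the best axial alignment, from the t = 0 topology
column_pairs <- function(traj, diameter = traj$mesh$geometry$diameter) {
  m0 <- mesh_at(traj, 1)
  adj <- cell_adjacency(m0$faces)
  cen <- cell_centroids(m0)
  r <- diameter / 2
  phi <- atan2(cen[, 2], cen[, 1])
  up <- integer(0); sub <- integer(0)
  for (i in seq_along(adj)) {
    cand <- adj[[i]][cen[adj[[i]], 3] < cen[i, 3] - 1e-9]
    if (!length(cand)) next
    dphi <- phi[cand] - phi[i]
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    dx <- dphi * r; dy <- cen[cand, 3] - cen[i, 3]
    best <- cand[which.max(abs(dy) / sqrt(dx^2 + dy^2))]
    up <- c(up, i); sub <- c(sub, best)
  }
  cbind(upper = up, subjacent = sub)
}

#' Relative circumferential sliding of axially adjacent cells
#'
#' For every (upper, subjacent) cell pair -- the subjacent cell is the
#' posteriorly adjacent neighbor in the same axial column -- the subjacent
#' cell is taken as the origin and the relative displacement of the upper
#' cell in the circumferential (x) direction over the interval is measured.
#' Negative values are leftward sliding under the package orientation
#' contract, the wild-type direction.
#'
#' @param traj a \code{trajectory}.
#' @param interval time interval (default the whole run).
#' @param diameter projection cylinder diameter.
#' @return A data frame: \code{upper}, \code{subjacent}, \code{t_start},
#'   \code{dx}.
#' @export
cell_sliding <- function(traj, interval = NULL,
                         diameter = traj$mesh$geometry$diameter) {
  tr <- cell_tracks(traj, diameter)
  pairs <- column_pairs(traj, diameter)
  tt <- tr$t
  if (is.null(interval)) interval <- max(tt) - min(tt)
  starts <- tt[tt + interval <= max(tt) + 1e-9]
  out <- list()
  for (t0 in starts) {
    k0 <- which.min(abs(tt - t0))
    k1 <- which.min(abs(tt - (t0 + interval)))
    if (k1 <= k0) next
    dxu <- tr$x[k1, pairs[, "upper"]] - tr$x[k0, pairs[, "upper"]]
    dxs <- tr$x[k1, pairs[, "subjacent"]] - tr$x[k0, pairs[, "subjacent"]]
    out[[length(out) + 1L]] <- data.frame(
      upper = pairs[, "upper"], subjacent = pairs[, "subjacent"],
      t_start = t0, dx = dxu - dxs)
  }
  do.call(rbind, out)
}

#' Classify the tilting of cell-cell boundaries
#'
#' For every boundary between an (upper, subjacent) column pair, the angle
#' of the shared-edge segment on the unrolled plane is followed over the
#' interval and the change classified: counter-clockwise (\code{ccw}) if it
#' exceeds \code{tol_deg}, clockwise (\code{cw}) if below \code{-tol_deg},
#' unchanged (\code{uc}) otherwise. Pairs whose boundary disappears (by
#' reconnection) are skipped.
#'
#' @param traj a \code{trajectory}.
#' @param interval time interval (default whole run).
#' @param tol_deg unchanged-tolerance in degrees (default 2).
#' @param diameter projection cylinder diameter.
#' @return A list: \code{counts} (named ccw/uc/cw) and the per-boundary
#'   \code{angles} data frame.
#' @export
boundary_tilt <- function(traj, interval = NULL, tol_deg = 2,
                          diameter = traj$mesh$geometry$diameter) {
  m0 <- mesh_at(traj, 1)
  pairs <- column_pairs(traj, diameter)
  tt <- traj$times
  if (is.null(interval)) interval <- max(tt) - min(tt)
  k0 <- 1L
  k1 <- which.min(abs(tt - (tt[1] + interval)))
  r <- diameter / 2
  seg_angle <- function(V, v1, v2) {
    dphi <- atan2(V[v2, 2], V[v2, 1]) - atan2(V[v1, 2], V[v1, 1])
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    atan2(V[v2, 3] - V[v1, 3], dphi * r) * 180 / pi
  }
  mend <- mesh_at(traj, k1)
  adj_end <- cell_adjacency(mend$faces)
  res <- list()
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, "upper"]; j <- pairs[q, "subjacent"]
    shared <- intersect(m0$faces[[i]], m0$faces[[j]])
    if (length(shared) != 2L) next
    if (!(j %in% adj_end[[i]]) ||
        length(intersect(mend$faces[[i]], mend$faces[[j]])) != 2L) next
    a0 <- seg_angle(traj$states[[k0]], shared[1], shared[2])
    a1 <- seg_angle(traj$states[[k1]], shared[1], shared[2])
    d <- a1 - a0
    d <- d - 180 * round(d / 180)
    res[[length(res) + 1L]] <- data.frame(upper = i, subjacent = j,
                                          delta_deg = d)
  }
  ang <- do.call(rbind, res)
  cls <- if (is.null(ang)) character(0) else
    ifelse(ang$delta_deg > tol_deg, "ccw",
           ifelse(ang$delta_deg < -tol_deg, "cw", "uc"))
  counts <- c(ccw = sum(cls == "ccw"), uc = sum(cls == "uc"),
              cw = sum(cls == "cw"))
  list(counts = counts, angles = ang)
}

#' Detect cell-intercalation events from tracked adjacency
#'
#' An intercalation is recorded when two cells of an axial column that were
#' initially in contact become separated by an intervening third cell that
#' is adjacent to both. The direction reports the side the intervening cell
#' came from (by its centroid x relative to the pair line at the last save
#' before separation): \code{"left"}, \code{"right"}, or
#' \code{"undetermined"} when within 1e-6 of the line.
#'
#' @param traj a \code{trajectory}.
#' @param window maximum time after separation within which the intervening
#'   contact must exist (default Inf).
#' @param diameter projection cylinder diameter.
#' @return A data frame: \code{t}, \code{upper}, \code{subjacent},
#'   \code{intervening}, \code{direction}.
#' @export
detect_intercalation <- function(traj, window = Inf,
                                 diameter = traj$mesh$geometry$diameter) {
  pairs <- column_pairs(traj, diameter)
  tr <- cell_tracks(traj, diameter)
  tt <- traj$times
  adjs <- lapply(traj$topologies, function(tp) cell_adjacency(tp$faces))
  out <- list()
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, "upper"]; j <- pairs[q, "subjacent"]
    sep <- NA_integer_
    for (k in seq_along(tt)) {
      if (!(j %in% adjs[[traj$topo_id[k]]][[i]])) { sep <- k; break }
    }
    if (is.na(sep)) next
    kmax <- max(which(tt <= tt[sep] + window))
    found <- NA_integer_; kf <- NA_integer_
    for (k in sep:kmax) {
      aa <- adjs[[traj$topo_id[k]]]
      inter <- setdiff(intersect(aa[[i]], aa[[j]]), c(i, j))
      if (length(inter)) {
        zc <- tr$y[k, inter]
        ok <- inter[zc > min(tr$y[k, c(i, j)]) & zc < max(tr$y[k, c(i, j)])]
        found <- if (length(ok)) ok[1] else inter[1]
        kf <- k
        break
      }
    }
    if (is.na(found)) next
    kprev <- max(1L, sep - 1L)
    xi <- tr$x[kprev, i]; xj <- tr$x[kprev, j]
    yi <- tr$y[kprev, i]; yj <- tr$y[kprev, j]
    yc <- tr$y[kprev, found]
    xline <- if (abs(yj - yi) < 1e-12) (xi + xj) / 2 else
      xi + (xj - xi) * (yc - yi) / (yj - yi)
    dxc <- tr$x[kprev, found] - xline
    dxc <- dxc - (pi * diameter) * round(dxc / (pi * diameter))
    dir <- if (abs(dxc) < 1e-6) "undetermined" else
      if (dxc < 0) "left" else "right"
    out[[length(out) + 1L]] <- data.frame(
      t = tt[kf], upper = i, subjacent = j, intervening = found,
      direction = dir)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(t = numeric(0), upper = integer(0), subjacent = integer(0),
               intervening = integer(0), direction = character(0))
}
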