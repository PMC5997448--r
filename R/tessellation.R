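#' Generate the initial planar tessellation of the tube surface
#'
#' Distributes \code{n_cells} non-overlapping disc centres at random in a
#' rectangle (periodic in the width direction, which becomes the tube
#' circumference) by random sequential adsorption, then computes their
#' Voronoi (Dirichlet) tessellation. Cells are clipped by the top and
#' bottom rectangle edges, whose intersection vertices later become the
#' tube end rings. The defaults are the full-size tube: 452 cells in a
#' 15.75 x 28.7 rectangle with hard-core disc diameter 0.82, giving a mean
#' polygon area of about 1.
#'
#' @param n_cells number of cells.
#' @param rect_width,rect_height rectangle dimensions; the width direction
#'   is periodic.
#' @param disc_diameter hard-core diameter of the packed discs (minimum
#'   centre spacing).
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called so the packing is reproducible.
#' @param max_attempts attempt budget for the sequential adsorption
#'   (default 1e6); an explicit error names the budget on failure.
#'
#' @return A \code{planar_tessellation}: seeds, a global vertex table
#'   (width coordinate canonicalized into \code{[0, rect_width)}), ordered
#'   counter-clockwise face loops with per-vertex periodic shifts, face
#'   areas, and per-vertex boundary flags (0 interior, 1 bottom, 2 top).
#' @export
generate_initial_tessellation <- function(n_cells = 452L,
                                          rect_width = 15.75,
                                          rect_height = 28.7,
                                          disc_diameter = 0.82,
                                          seed = NULL,
                                          max_attempts = 1e6L) {
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  area <- rect_width * rect_height
  if (n_cells * pi * (disc_diameter / 2)^2 >= area)
    stop("packing infeasible: total disc area exceeds the rectangle area")
  if (!is.null(seed)) set.seed(seed)
  seeds <- cpp_rsa_pack(as.integer(n_cells), rect_width, rect_height,
                        disc_diameter, as.integer(max_attempts))
  tess <- voronoi_periodic(seeds, rect_width, rect_height)
  tess$disc_diameter <- disc_diameter
  tot <- sum(tess$areas)
  if (abs(tot - area) > 1e-9 * area)
    stop(sprintf("tessellation areas sum to %.12g, expected %.12g", tot, area))
  tess
}

#' @export
print.planar_tessellation <- function(x, ...) {
  cat(sprintf("Periodic planar tessellation: %d cells in %.4g x %.4g\n",
              length(x$faces), x$rect_width, x$rect_height))
  cat(sprintf("  %d vertices, mean cell area %.4f\n",
              nrow(x$vertices), mean(x$areas)))
  invisible(x)
}

# Voronoi tessellation of seed points in [0,W) x [0,H], periodic in x only,
# clipped at y = 0 and y = H. Each cell is obtained by half-plane clipping
# against nearby seed images; shared vertices are identified topologically
# by the set of defining seeds/boundaries (not by coordinate tolerance), so
# adjacent cells reference the same global vertex exactly.
voronoi_periodic <- function(seeds, W, H) {
  n <- nrow(seeds)
  sx <- seeds[, 1] %% W
  sy <- seeds[, 2]
  # seed images shifted by -W, 0, +W
  img_x <- c(sx - W, sx, sx + W)
  img_y <- rep(sy, 3L)
  img_orig <- rep(seq_len(n), 3L)
  img_shift <- rep(c(-1L, 0L, 1L), each = n)

  cell_polys <- vector("list", n)
  for (i in seq_len(n)) {
    rc <- max(4, 4 * sqrt(W * H / n))
    repeat {
      poly <- clip_voronoi_cell(i, sx[i], sy[i], img_x, img_y, rc, W, H)
      if (!is.null(poly)) break
      rc <- rc * 2
      if (rc > 4 * (W + H)) stop("voronoi cell clipping failed for seed ", i)
    }
    cell_polys[[i]] <- poly
  }

  # global vertex identification: key = normalized multiset of defining
  # seeds (with relative periodic shifts) and boundary lines
  rows_key <- character(0); rows_x <- numeric(0); rows_y <- numeric(0)
  rows_cell <- integer(0); rows_pos <- integer(0); rows_bnd <- integer(0)
  for (i in seq_len(n)) {
    poly <- cell_polys[[i]]
    m <- length(poly$x)
    labin <- poly$lab[c(m, seq_len(m - 1))]  # incoming edge label
    labout <- poly$lab
    for (k in seq_len(m)) {
      labs <- c(labin[k], labout[k])
      # seed entries carry their periodic image shift (normalized to the
      # minimum over seeds, so the key is translation invariant); boundary
      # lines are shift-free tags
      sid <- i; sshift <- 0L; btag <- character(0); bnd <- 0L
      for (q in 1:2) {
        l <- labs[q]
        if (l >= 1) {
          sid <- c(sid, img_orig[l])
          sshift <- c(sshift, img_shift[l])
        } else if (l == -1L) {
          btag <- c(btag, "B"); bnd <- 1L
        } else if (l == -2L) {
          btag <- c(btag, "T"); bnd <- 2L
        } else stop("internal: bounding-box edge survived clipping")
      }
      parts <- sort(c(paste0(sid, "@", sshift - min(sshift)), btag))
      rows_key <- c(rows_key, paste(parts, collapse = "|"))
      rows_x <- c(rows_x, poly$x[k]); rows_y <- c(rows_y, poly$y[k])
      rows_cell <- c(rows_cell, i); rows_pos <- c(rows_pos, k)
      rows_bnd <- c(rows_bnd, bnd)
    }
  }

  xmod <- rows_x %% W
  gid <- integer(length(rows_key))
  vx <- numeric(0); vy <- numeric(0); vb <- integer(0)
  groups <- split(seq_along(rows_key), rows_key)
  for (g in groups) {
    taken <- integer(0)  # global ids used within this key group
    for (r in g) {
      hit <- 0L
      for (t in taken) {
        dx <- abs(xmod[r] - vx[t]); dx <- min(dx, W - dx)
        if (dx < 1e-6 && abs(rows_y[r] - vy[t]) < 1e-6) { hit <- t; break }
      }
      if (hit == 0L) {
        vx <- c(vx, xmod[r]); vy <- c(vy, rows_y[r]); vb <- c(vb, rows_bnd[r])
        hit <- length(vx)
        taken <- c(taken, hit)
      }
      gid[r] <- hit
    }
  }
  # snap boundary vertices exactly onto the clipping lines
  vy[vb == 1L] <- 0
  vy[vb == 2L] <- H

  faces <- vector("list", n)
  xshift <- vector("list", n)
  areas <- numeric(n)
  ord <- order(rows_cell, rows_pos)
  rc2 <- rows_cell[ord]; rp <- rows_pos[ord]; gg <- gid[ord]
  xl <- rows_x[ord]
  for (i in seq_len(n)) {
    sel <- which(rc2 == i)
    loop <- gg[sel][order(rp[sel])]
    xloc <- xl[sel][order(rp[sel])]
    faces[[i]] <- loop
    xshift[[i]] <- as.integer(round((xloc - vx[loop]) / W))
    yloc <- vy[loop]
    xx <- vx[loop] + xshift[[i]] * W
    areas[i] <- polygon_area_2d(xx, yloc)
  }

  structure(list(rect_width = W, rect_height = H, seeds = cbind(sx, sy),
                 vertices = cbind(x = vx, y = vy), boundary = vb,
                 faces = faces, xshift = xshift, areas = areas),
            class = "planar_tessellation")
}

# One Voronoi cell by Sutherland-Hodgman clipping of a generous bounding
# box against the perpendicular bisectors of nearby seed images (ascending
# by distance, with the standard 2*max-vertex-distance early stop) and the
# rectangle's top/bottom lines. Edge labels: image index >= 1 for a
# bisector, -1 bottom, -2 top, -3..-6 bounding box (must not survive).
# Returns NULL if a bounding-box edge survives (caller enlarges rc).
clip_voronoi_cell <- function(i, px, py, img_x, img_y, rc, W, H) {
  ylo <- max(0, py - rc); yhi <- min(H, py + rc)
  lab_bot <- if (ylo == 0) -1L else -5L
  lab_top <- if (yhi == H) -2L else -6L
  poly <- list(x = c(px - rc, px + rc, px + rc, px - rc),
               y = c(ylo, ylo, yhi, yhi),
               lab = c(lab_bot, -4L, lab_top, -3L))

  d2 <- (img_x - px)^2 + (img_y - py)^2
  cand <- which(d2 > 1e-18 & d2 <= rc * rc)
  cand <- cand[order(d2[cand])]
  for (j in cand) {
    vmax2 <- max((poly$x - px)^2 + (poly$y - py)^2)
    if (d2[j] > 4 * vmax2) break
    mx <- (px + img_x[j]) / 2; my <- (py + img_y[j]) / 2
    nx <- img_x[j] - px; ny <- img_y[j] - py
    f <- nx * (poly$x - mx) + ny * (poly$y - my)
    if (all(f <= 0)) next
    poly <- clip_halfplane(poly, f, j)
    if (length(poly$x) < 3) stop("voronoi cell collapsed for seed ", i)
  }
  if (any(poly$lab %in% c(-3L, -4L, -5L, -6L))) return(NULL)
  poly
}

# Clip a labelled polygon by the half-plane {f <= 0}; the new edge along
# the clip line is labelled 'newlab'. f is pre-evaluated per vertex.
clip_halfplane <- function(poly, f, newlab) {
  m <- length(poly$x)
  ox <- numeric(0); oy <- numeric(0); olab <- integer(0)
  for (k in seq_len(m)) {
    k1 <- if (k == m) 1L else k + 1L
    ins_k <- f[k] <= 0; ins_k1 <- f[k1] <= 0
    if (ins_k && ins_k1) {
      ox <- c(ox, poly$x[k]); oy <- c(oy, poly$y[k])
      olab <- c(olab, poly$lab[k])
    } else if (ins_k && !ins_k1) {
      t <- f[k] / (f[k] - f[k1])
      ox <- c(ox, poly$x[k], poly$x[k] + t * (poly$x[k1] - poly$x[k]))
      oy <- c(oy, poly$y[k], poly$y[k] + t * (poly$y[k1] - poly$y[k]))
      olab <- c(olab, poly$lab[k], newlab)
    } else if (!ins_k && ins_k1) {
      t <- f[k] / (f[k] - f[k1])
      ox <- c(ox, poly$x[k] + t * (poly$x[k1] - poly$x[k]))
      oy <- c(oy, poly$y[k] + t * (poly$y[k1] - poly$y[k]))
      olab <- c(olab, poly$lab[k])
    }
  }
  list(x = ox, y = oy, lab = olab)
}

# Shoelace area of a flat polygon given coordinate vectors (ccw positive).
polygon_area_2d <- function(x, y) {
  x1 <- c(x[-1], x[1]); y1 <- c(y[-1], y[1])
  0.5 * sum(x * y1 - x1 * y)
}

# Face loop of a planar tessellation in locally unwrapped coordinates
# (seam-crossing faces get x outside [0, W)).
face_local_coords <- function(tess, i) {
  loop <- tess$faces[[i]]
  cbind(x = tess$vertices[loop, 1] + tess$xshift[[i]] * tess$rect_width,
        y = tess$vertices[loop, 2])
}
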