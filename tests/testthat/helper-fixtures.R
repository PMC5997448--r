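# Shared fixtures and independent oracles, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

fixture_60 <- function() cached("fix60", make_fixture_tube(60L, seed = 42L))
fixture_16 <- function() cached("fix16",
  make_fixture_tube(16L, seed = 3L, rect_width = 4))

# full-size tessellation/tube (the standard geometry)
fullsize_tess <- function() cached("ptess",
  generate_initial_tessellation(seed = 101L))
fullsize_tube <- function() cached("ptube", wrap_to_cylinder(fullsize_tess()))

# independent rasterization oracle for a periodic-in-x Voronoi diagram:
# assign a fine pixel grid to nearest seeds, return areas and the pixel
# adjacency between cells
raster_voronoi <- function(seeds, W, H, npx = 500L) {
  xs <- (seq_len(npx) - 0.5) / npx * W
  ys <- (seq_len(npx) - 0.5) / npx * H
  X <- matrix(xs, npx, npx)
  Y <- matrix(ys, npx, npx, byrow = TRUE)
  best <- matrix(Inf, npx, npx)
  lab <- matrix(0L, npx, npx)
  for (s in seq_len(nrow(seeds))) {
    dx <- abs(X - seeds[s, 1]); dx <- pmin(dx, W - dx)
    d2 <- dx^2 + (Y - seeds[s, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- s
  }
  px_area <- (W / npx) * (H / npx)
  areas <- tabulate(lab, nbins = nrow(seeds)) * px_area
  pairs <- character(0)
  h1 <- lab[-npx, ]; h2 <- lab[-1, ]
  v1 <- lab[, -npx]; v2 <- lab[, -1]
  wrap1 <- lab[npx, ]; wrap2 <- lab[1, ]  # periodic seam in x
  cand <- rbind(cbind(as.vector(h1), as.vector(h2)),
                cbind(as.vector(v1), as.vector(v2)),
                cbind(wrap1, wrap2))
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  keys <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
  tab <- table(keys)
  list(areas = areas, adjacency = tab)
}

# adjacency keys (shared-edge cell pairs) of a planar tessellation
tess_adjacency_keys <- function(tess) {
  n <- length(tess$faces)
  a <- integer(0); b <- integer(0); f <- integer(0)
  for (i in seq_len(n)) {
    loop <- tess$faces[[i]]
    nx <- c(loop[-1], loop[1])
    a <- c(a, pmin(loop, nx)); b <- c(b, pmax(loop, nx))
    f <- c(f, rep.int(i, length(loop)))
  }
  key <- paste(a, b)
  out <- character(0)
  for (grp in split(f, key))
    if (length(grp) == 2L && grp[1] != grp[2])
      out <- c(out, paste(min(grp), max(grp)))
  unique(out)
}

# edge lengths of a planar tessellation (for filtering tiny edges the
# rasterization oracle cannot resolve)
tess_edge_lengths <- function(tess) {
  n <- length(tess$faces)
  res <- list()
  for (i in seq_len(n)) {
    xy <- chiratube:::face_local_coords(tess, i)
    loop <- tess$faces[[i]]
    nx <- c(2:length(loop), 1L)
    len <- sqrt(rowSums((xy - xy[nx, , drop = FALSE])^2))
    for (k in seq_along(loop)) {
      res[[paste(min(loop[k], loop[nx[k]]), max(loop[k], loop[nx[k]]))]] <-
        len[k]
    }
  }
  res
}

# an axis-aligned unit cube as a closed tube_mesh (4 sides + 2 caps)
unit_cube_mesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  colnames(V) <- c("x", "y", "z")
  structure(list(
    vertices = V,
    faces = list(c(1, 2, 6, 5), c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8)),
    cap_top = c(5, 6, 7, 8),
    cap_bottom = c(4, 3, 2, 1),
    geometry = list(diameter = 1, rect_width = 4, rect_height = 1,
                    z_bottom = 0, z_top = 1)),
    class = "tube_mesh")
}

# right prism over a regular n-gon (vertices on a circle of radius r),
# height h: enclosed volume is exactly the polygon area times h
prism_mesh <- function(n = 100L, r = 2.5, h = 28.7) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  V <- rbind(cbind(r * cos(th), r * sin(th), 0),
             cbind(r * cos(th), r * sin(th), h))
  colnames(V) <- c("x", "y", "z")
  sides <- lapply(seq_len(n), function(k) {
    k1 <- if (k == n) 1L else k + 1L
    c(k, k1, n + k1, n + k)
  })
  structure(list(vertices = V, faces = sides,
                 cap_top = n + seq_len(n), cap_bottom = rev(seq_len(n)),
                 geometry = list(diameter = 2 * r, rect_width = 2 * pi * r,
                                 rect_height = h, z_bottom = 0, z_top = h)),
            class = "tube_mesh")
}

# independent tetrahedron-decomposition volume oracle (origin apex over the
# centroid-fan triangulation), coded separately from the compiled path
volume_tetra_oracle <- function(mesh) {
  tot <- 0
  for (loop in c(mesh$faces, list(mesh$cap_top, mesh$cap_bottom))) {
    P <- mesh$vertices[loop, , drop = FALSE]
    cen <- colMeans(P)
    for (k in seq_along(loop)) {
      a <- P[k, ]; b <- P[if (k == length(loop)) 1L else k + 1L, ]
      tot <- tot + det(rbind(cen, a, b)) / 6
    }
  }
  tot
}

# central finite-difference gradient of the potential energy
fd_forces <- function(mesh, params, special = NULL, w_special = 1,
                      eps = 1e-6) {
  F <- matrix(0, nrow(mesh$vertices), 3)
  for (i in seq_len(nrow(mesh$vertices))) {
    for (k in 1:3) {
      m1 <- mesh; m1$vertices[i, k] <- m1$vertices[i, k] + eps
      m2 <- mesh; m2$vertices[i, k] <- m2$vertices[i, k] - eps
      F[i, k] <- -(potential_energy(m1, params, special, w_special)$U -
                     potential_energy(m2, params, special, w_special)$U) /
        (2 * eps)
    }
  }
  F
}
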