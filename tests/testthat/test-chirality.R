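test_that("zero deflection aligns every polarity with the tube axis", {
  m <- fixture_60()$mesh
  p <- assign_polarity(m, 0)
  expect_equal(p[, 3], rep(1, nrow(p)), tolerance = 1e-12)
  expect_lt(max(abs(p[, 1:2])), 1e-12)
})

test_that("polarity vectors are unit, tangent, and correctly deflected", {
  m <- fixture_60()$mesh
  for (d in c(30, -35)) {
    p <- assign_polarity(m, d)
    expect_equal(rowSums(p^2), rep(1, nrow(p)), tolerance = 1e-12)
    cen <- chiratube:::cell_centroids(m)
    radial <- cbind(cen[, 1], cen[, 2], 0)
    radial <- radial / sqrt(rowSums(radial^2))
    expect_lt(max(abs(rowSums(p * radial))), 1e-12)  # tangent plane
    expect_equal(p[, 3], rep(cos(d * pi / 180), nrow(p)),
                 tolerance = 1e-12)  # deflection angle from +z
    # positive deflection tilts toward decreasing azimuth (leftward)
    phihat <- cbind(-cen[, 2], cen[, 1], 0)
    phihat <- phihat / sqrt(rowSums(phihat^2))
    expect_equal(rowSums(p * phihat), rep(-sin(d * pi / 180), nrow(p)),
                 tolerance = 1e-12)
  }
})

test_that("deflection angles at or beyond 90 degrees are rejected", {
  m <- fixture_60()$mesh
  expect_error(assign_polarity(m, 90), "deflection")
  expect_error(assign_polarity(m, -95), "deflection")
})

test_that("special-edge selection equals the exhaustive sign-test oracle", {
  m <- fixture_60()$mesh
  pol <- assign_polarity(m, 30)
  checked <- 0
  for (i in seq_along(m$faces)) {
    got <- suppressWarnings(select_special_edges(m, i, pol[i, ]))
    loop <- m$faces[[i]]
    vv <- m$vertices[loop, , drop = FALSE]
    s <- as.numeric(vv %*% pol[i, ]) - sum(colMeans(vv) * pol[i, ])
    nx <- c(2:length(loop), 1L)
    want <- which(s * s[nx] < 0)
    if (length(want) == 2L) {
      expect_equal(nrow(got), 2L)
      expect_setequal(paste(pmin(got[, 1], got[, 2]),
                            pmax(got[, 1], got[, 2])),
                      paste(pmin(loop[want], loop[nx[want]]),
                            pmax(loop[want], loop[nx[want]])))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)  # nearly all of the 60 cells are non-degenerate
})

test_that("hand-built hexagon and square select the expected edges", {
  # regular hexagon in the x-z plane (vertex-to-vertex axis along z),
  # polarity along +z
  th <- 2 * pi * (0:5) / 6 + pi / 6
  m <- structure(list(vertices = cbind(x = 5 + cos(th), y = rep(0, 6),
                                       z = sin(th)),
                      faces = list(1:6)), class = "tube_mesh")
  got <- select_special_edges(m, 1, c(0, 0, 1))
  # plane z = 0 crosses the two edges whose endpoints straddle z = 0
  s <- sin(th)
  nx <- c(2:6, 1)
  want <- which(s * s[nx] < 0)
  expect_setequal(paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2])),
                  paste(pmin(want, nx[want]), pmax(want, nx[want])))

  # axis-aligned square, polarity along an edge direction: the two edges
  # parallel to the polarity are crossed by the perpendicular plane
  sq <- structure(list(vertices = cbind(x = 5 + c(-0.5, 0.5, 0.5, -0.5),
                                        y = 0,
                                        z = c(-0.5, -0.5, 0.5, 0.5)),
                       faces = list(1:4)), class = "tube_mesh")
  gotsq <- select_special_edges(sq, 1, c(0, 0, 1))
  expect_setequal(paste(pmin(gotsq[, 1], gotsq[, 2]),
                        pmax(gotsq[, 1], gotsq[, 2])),
                  c("2 3", "1 4"))
})

test_that("selection is invariant under polarity negation", {
  m <- fixture_60()$mesh
  pol <- assign_polarity(m, 25)
  for (i in c(3, 17, 42)) {
    a <- suppressWarnings(select_special_edges(m, i, pol[i, ]))
    b <- suppressWarnings(select_special_edges(m, i, -pol[i, ]))
    expect_setequal(paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2])),
                    paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  }
})

test_that("almost all cells get exactly two special edges", {
  m <- fullsize_tube()
  pol <- assign_polarity(m, 30)
  sp <- suppressWarnings(chiratube:::select_all_special_edges(m, pol))
  frac2 <- mean(vapply(sp, nrow, integer(1)) == 2L)
  expect_gte(frac2, 0.98)
})

test_that("mirror tubes receive mirrored polarity", {
  m <- fixture_60()$mesh
  mm <- chiratube:::mirror_mesh(m)
  p <- assign_polarity(m, 30)
  pm <- assign_polarity(mm, -30)
  flip <- cbind(-p[, 1], p[, 2], p[, 3])
  expect_equal(pm, flip, tolerance = 1e-12)
})
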