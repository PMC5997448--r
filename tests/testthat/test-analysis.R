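test_that("cylinder projection unrolls arc lengths exactly", {
  m <- fullsize_tube()
  pr <- project_unroll(m, diameter = 5)
  # widths on the unrolled plane equal arc lengths on the cylinder
  for (i in c(1, 50, 200)) {
    poly <- pr$polygons[[i]]
    loop <- m$faces[[i]]
    phi <- atan2(m$vertices[loop, 2], m$vertices[loop, 1])
    dphi <- diff(phi[1:2])
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    expect_equal(unname(poly[2, 1] - poly[1, 1]), dphi * 2.5,
                 tolerance = 1e-12)
  }
  # peripheral exclusion: the two rows nearest each end, nowhere else
  ring <- c(m$cap_top, m$cap_bottom)
  row1 <- vapply(m$faces, function(l) any(l %in% ring), logical(1))
  expect_true(all(pr$excluded[row1]))
  cen <- chiratube:::cell_centroids(m)
  mid <- abs(cen[, 3] - 28.7 / 2) < 8
  expect_false(any(pr$excluded[mid]))
})

test_that("momental ellipse of a 2:1 rectangle gives deviation 1/3", {
  rect <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-1, -1, 1, 1))
  got <- polygon_axis_deviation(rect)
  expect_equal(got$deviation, 1 / 3, tolerance = 1e-12)
  expect_equal(got$d_max / got$d_min, 2, tolerance = 1e-12)
  expect_equal(got$theta, 0, tolerance = 1e-9)   # long axis along y (axial)
  rect90 <- rect[, 2:1]
  expect_equal(abs(polygon_axis_deviation(rect90)$theta), 90,
               tolerance = 1e-9)
})

test_that("near-circular polygons report zero angle by the tie rule", {
  th <- 2 * pi * (0:63) / 64
  circ <- cbind(cos(th), sin(th))
  got <- polygon_axis_deviation(circ)
  expect_lt(got$deviation, 1e-6)
  expect_equal(got$theta, 0)
})

test_that("polygon axis is rotation equivariant, deviation invariant", {
  set.seed(12)
  r <- runif(7, 0.7, 1.3)
  th <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(r * cos(th), r * sin(th))
  base <- polygon_axis_deviation(poly)
  for (alpha in c(15, 40, -30)) {
    a <- alpha * pi / 180
    # rotating the polygon by +alpha in the (x, y) plane decreases theta
    # (theta is measured from the y axis toward +x)
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    got <- polygon_axis_deviation(poly %*% t(Rm))
    expect_equal(got$deviation, base$deviation, tolerance = 1e-9)
    d <- (base$theta - alpha) - got$theta
    expect_equal(d - 180 * round(d / 180), 0, tolerance = 1e-6)
    # uniform scaling leaves both untouched
    got2 <- polygon_axis_deviation(2.5 * poly)
    expect_equal(got2$deviation, base$deviation, tolerance = 1e-12)
    expect_equal(got2$theta, base$theta, tolerance = 1e-9)
  }
})

test_that("angle histograms sum to 100 percent and measure bias", {
  set.seed(3)
  sym <- c(runif(500, -89, 89))
  hh <- angle_histogram(sym)
  expect_equal(sum(hh$percent), 100, tolerance = 1e-9)
  expect_lt(abs(hh$bias), 0.15)
  left <- c(runif(300, -80, -10), runif(60, 10, 80))
  expect_gt(angle_histogram(left)$bias, 0.5)
})

test_that("twist angle is zero for identical and rigidly rotated meshes", {
  m <- fixture_60()$mesh
  expect_equal(twist_angle(m, m), 0)
  mr <- m
  a <- 0.7
  mr$vertices <- cbind(m$vertices[, 1] * cos(a) - m$vertices[, 2] * sin(a),
                       m$vertices[, 1] * sin(a) + m$vertices[, 2] * cos(a),
                       m$vertices[, 3])
  expect_equal(twist_angle(mr, m), 0, tolerance = 1e-9)
  expect_equal(twist_angle_regression(mr, m), 0, tolerance = 1e-9)
})

test_that("twist angle is exactly calibrated on an analytic helical map", {
  m <- fixture_60()$mesh
  h <- diff(range(m$vertices[, 3]))
  for (cdeg in c(2, -3.5)) {
    mt <- apply_helical_twist(m, cdeg)
    expect_equal(twist_angle(mt, m), cdeg * h, tolerance = 1e-9)
    expect_equal(twist_angle_regression(mt, m), cdeg * h, tolerance = 0.5)
  }
})

test_that("twist trace accumulates beyond half a turn", {
  m <- fixture_60()$mesh
  # synthetic trajectory twisting 30 degrees per saved state
  states <- lapply(0:9, function(k)
    apply_helical_twist(m, 30 * k / diff(range(m$vertices[, 3])))$vertices)
  traj <- structure(list(times = 0:9, states = states,
                         topo_id = rep(1L, 10),
                         topologies = list(list(faces = m$faces,
                                                cap_top = m$cap_top,
                                                cap_bottom = m$cap_bottom)),
                         mesh = m, events = data.frame()),
                    class = "trajectory")
  tw <- twist_trace(traj)
  expect_equal(tw$twist, 30 * (0:9), tolerance = 1e-9)
})

test_that("topology mismatch is rejected", {
  m <- fixture_60()$mesh
  m2 <- m
  m2$cap_top <- rev(m2$cap_top)
  expect_error(twist_angle(m2, m), "topology")
})

test_that("sliding displacement measures relative circumferential motion", {
  m <- fixture_60()$mesh
  # static tube: all displacements zero
  traj0 <- structure(list(times = c(0, 1), states = list(m$vertices,
                                                         m$vertices),
                          topo_id = c(1L, 1L),
                          topologies = list(list(faces = m$faces,
                                                 cap_top = m$cap_top,
                                                 cap_bottom = m$cap_bottom)),
                          mesh = m, events = data.frame()),
                     class = "trajectory")
  sl0 <- cell_sliding(traj0)
  expect_true(all(abs(sl0$dx) < 1e-12))

  # uniform helical displacement: upper cells move left relative to lower
  mt <- apply_helical_twist(m, 3)  # positive twist = leftward slide
  traj1 <- traj0
  traj1$states[[2]] <- mt$vertices
  sl1 <- cell_sliding(traj1)
  expect_lt(mean(sl1$dx), 0)
})

test_that("boundary tilt classification respects the tolerance", {
  m <- fixture_60()$mesh
  traj0 <- structure(list(times = c(0, 1), states = list(m$vertices,
                                                         m$vertices),
                          topo_id = c(1L, 1L),
                          topologies = list(list(faces = m$faces,
                                                 cap_top = m$cap_top,
                                                 cap_bottom = m$cap_bottom)),
                          mesh = m, events = data.frame()),
                     class = "trajectory")
  bt0 <- boundary_tilt(traj0, tol_deg = 2)
  expect_equal(unname(bt0$counts["ccw"] + bt0$counts["cw"]), 0L)
  expect_gt(bt0$counts["uc"], 0L)

  # positive twist tilts the transverse boundaries counter-clockwise on the
  # unrolled plane (leftward shear)
  traj1 <- traj0
  traj1$states[[2]] <- apply_helical_twist(m, 5)$vertices
  bt1 <- boundary_tilt(traj1, tol_deg = 2)
  expect_gt(bt1$counts["ccw"], bt1$counts["cw"])
})

test_that("intercalation detection finds a scripted neighbor exchange", {
  fx <- fixture_60()
  m <- fx$mesh
  # no adjacency change: no events
  traj0 <- structure(list(times = c(0, 1), states = list(m$vertices,
                                                         m$vertices),
                          topo_id = c(1L, 1L),
                          topologies = list(list(faces = m$faces,
                                                 cap_top = m$cap_top,
                                                 cap_bottom = m$cap_bottom)),
                          mesh = m, events = data.frame()),
                     class = "trajectory")
  expect_equal(nrow(detect_intercalation(traj0)), 0L)

  # script a T1 on a column pair's shared edge: the pair separates and the
  # side cells intervene
  pairs <- chiratube:::column_pairs(traj0)
  adj <- chiratube:::cell_adjacency(m$faces)
  done <- FALSE
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, "upper"]; j <- pairs[q, "subjacent"]
    shared <- intersect(m$faces[[i]], m$faces[[j]])
    if (length(shared) != 2L) next
    sw <- try(reconnect_edge(m, shared[1], shared[2], delta = 0.3),
              silent = TRUE)
    if (inherits(sw, "try-error")) next
    traj1 <- traj0
    traj1$states[[2]] <- sw$mesh$vertices
    traj1$topo_id <- c(1L, 2L)
    traj1$topologies <- c(traj1$topologies,
                          list(list(faces = sw$mesh$faces,
                                    cap_top = sw$mesh$cap_top,
                                    cap_bottom = sw$mesh$cap_bottom)))
    ev <- detect_intercalation(traj1)
    expect_gte(nrow(ev), 1L)
    expect_true(any(ev$upper == i & ev$subjacent == j))
    expect_true(all(ev$direction %in% c("left", "right", "undetermined")))
    done <- TRUE
    break
  }
  expect_true(done)
})
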