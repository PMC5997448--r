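test_that("zero parameters give zero force and a stationary step", {
  fx <- fixture_16()
  p0 <- do.call(model_params, utils::modifyList(
    unclass(fx$params),
    list(sigma_L = 0, kappa_S = 0, kappa_V = 0, kappa_B = 0)))
  F <- vertex_forces(fx$mesh, p0)
  expect_true(all(F == 0))
  m1 <- step_rk4(fx$mesh, p0)
  expect_identical(m1$vertices, fx$mesh$vertices)
})

test_that("RK4 matches an adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  fx <- fixture_16()
  m <- fx$mesh
  p <- fx$params
  topo <- chiratube:::mesh_topology(m)
  rhs <- function(t, y, parms) {
    mm <- m
    mm$vertices <- matrix(y, ncol = 3)
    list(as.vector(vertex_forces(mm, p)))
  }
  t_end <- 0.25
  ref <- deSolve::ode(y = as.vector(m$vertices), times = c(0, t_end),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  yref <- matrix(ref[2, -1], ncol = 3)
  tr <- run_dynamics(m, p, t_end = t_end, reconnect = FALSE,
                     save_every = t_end)
  err_h <- max(abs(tr$mesh$vertices - yref))
  expect_lt(err_h, 1e-4)
  # classical 4th order: halving the step shrinks the error ~16x
  p2 <- do.call(model_params, utils::modifyList(unclass(p),
                                                list(h = p$h / 2)))
  tr2 <- run_dynamics(m, p2, t_end = t_end, reconnect = FALSE,
                      save_every = t_end)
  err_h2 <- max(abs(tr2$mesh$vertices - yref))
  expect_lt(err_h2, err_h / 8)
})

test_that("energy is non-increasing along the relaxation (Lyapunov)", {
  fx <- fixture_60()
  tr <- run_dynamics(fx$mesh, fx$params, t_end = 2, reconnect = FALSE,
                     save_every = 0.1)
  U <- tr$energy[, "U"]
  expect_true(all(diff(U) <= 1e-9))
  expect_lt(U[length(U)], U[1])
})

test_that("energy is non-increasing between reconnection events", {
  fx <- fixture_60()
  tr <- run_dynamics(fx$mesh, fx$params, t_end = 2, reconnect = TRUE,
                     save_every = 0.1)
  U <- tr$energy[, "U"]
  tt <- tr$times
  ev <- tr$events$t[!tr$events$skipped]
  for (k in seq_len(length(U) - 1)) {
    if (!any(ev > tt[k] - 1e-9 & ev <= tt[k + 1] + 1e-9))
      expect_lte(U[k + 1], U[k] + 1e-9)
  }
})

test_that("trajectory bookkeeping is consistent", {
  fx <- fixture_60()
  tr <- run_dynamics(fx$mesh, fx$params, t_end = 1, save_every = 0.25)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(length(tr$states), length(tr$times))
  expect_equal(nrow(tr$energy), length(tr$times))
  expect_equal(length(tr$topo_id), length(tr$times))
  expect_silent(validate_tube_mesh(tr$mesh))
})

test_that("identical inputs replay bit-identically", {
  fx1 <- make_fixture_tube(30L, seed = 5L, rect_width = 5)
  fx2 <- make_fixture_tube(30L, seed = 5L, rect_width = 5)
  expect_identical(fx1$mesh$vertices, fx2$mesh$vertices)
  tr1 <- run_dynamics(fx1$mesh, fx1$params, t_end = 0.5, save_every = 0.25)
  tr2 <- run_dynamics(fx2$mesh, fx2$params, t_end = 0.5, save_every = 0.25)
  expect_identical(tr1$mesh$vertices, tr2$mesh$vertices)
  expect_identical(tr1$events, tr2$events)
})

test_that("chirality induction tilts cell axes and edges leftward", {
  fx <- fixture_60()
  chir <- suppressWarnings(build_chiral_tube(
    fx$mesh, chirality_protocol("wildtype"), fx$params, reconnect = FALSE))
  ss <- shape_stats(chir$mesh)
  keep <- !ss$cells$excluded
  expect_lt(mean(ss$cells$theta[keep]), -5)
  expect_gt(angle_histogram(ss$cells$theta[keep])$bias, 0.1)
  expect_gt(angle_histogram(ss$edge_angles)$bias, 0.1)
})

test_that("without edge anisotropy no chirality is imprinted", {
  # at full size (390 analyzed cells) an induction run with w = 1 is plain
  # relaxation and leaves the axis-angle distribution symmetric; fixture
  # scale is too small for this test (sampling noise of ~0.2 in the bias)
  m <- fullsize_tube()
  plain <- chirality_protocol(NULL, deflection_deg = 30, w_special = 1,
                              t_induction = 2)
  chir0 <- suppressWarnings(build_chiral_tube(m, plain, model_params(),
                                              reconnect = FALSE))
  ss0 <- shape_stats(chir0$mesh)
  keep <- !ss0$cells$excluded
  expect_lt(abs(angle_histogram(ss0$cells$theta[keep])$bias), 0.1)
  expect_lt(abs(mean(ss0$cells$theta[keep])), 5)
  expect_lt(abs(angle_histogram(ss0$edge_angles)$bias), 0.1)
})

test_that("relaxation of a symmetric tube produces no bulk twist", {
  # the end rings are a soft mode and wander by several degrees even for
  # an achiral tube; the bulk (regression) twist stays near zero
  for (s in c(42L, 7L)) {
    fx <- make_fixture_tube(60L, seed = s)
    tr <- run_dynamics(fx$mesh, fx$params, t_end = 2, save_every = 1)
    m0 <- chiratube:::mesh_at(tr, 1)
    expect_lt(abs(twist_angle_regression(tr$mesh, m0)), 5)
  }
})

test_that("mirror-image initial states twist oppositely", {
  fx <- fixture_60()
  chir <- suppressWarnings(build_chiral_tube(
    fx$mesh, chirality_protocol("wildtype"), fx$params, reconnect = FALSE))
  m0 <- chir$mesh
  mm <- chiratube:::mirror_mesh(m0)
  tr1 <- run_dynamics(m0, fx$params, t_end = 2, reconnect = FALSE,
                      save_every = 0.5)
  tr2 <- run_dynamics(mm, fx$params, t_end = 2, reconnect = FALSE,
                      save_every = 0.5)
  tw1 <- twist_trace(tr1)$twist
  tw2 <- twist_trace(tr2)$twist
  expect_equal(tw1, -tw2, tolerance = 1e-6)
})

test_that("fixing end rotation suppresses the twist", {
  fx <- fixture_60()
  chir <- suppressWarnings(build_chiral_tube(
    fx$mesh, chirality_protocol("wildtype"), fx$params, reconnect = FALSE))
  trf <- run_dynamics(chir$mesh, fx$params, t_end = 2,
                      fix_end_rotation = TRUE, save_every = 0.5)
  ring <- c(chir$mesh$cap_top, chir$mesh$cap_bottom)
  expect_equal(trf$mesh$vertices[ring, 1:2], chir$mesh$vertices[ring, 1:2],
               tolerance = 1e-12)
  expect_lt(max(abs(twist_trace(trf)$twist)), 1)
})
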