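test_that("zero inlet flow gives the rest state", {
  m <- short_channel_mesh(L = 10)
  ff <- solve_steady(m, bc = boundary_conditions(inlet_velocity = 0,
                                                 outlet_pressure = 5))
  expect_true(ff$converged)
  expect_equal(max(abs(ff$u)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ff$v)), 0, tolerance = 1e-12)
  expect_equal(ff$p, rep(5, length(ff$p)), tolerance = 1e-9)
})

test_that("coarse straight channel reproduces the discrete channel oracle", {
  m <- short_channel_mesh(L = 130)
  ff <- solve_steady(m)
  expect_true(ff$converged)
  # fully developed cross profile matches the 3-cell discrete solution
  u <- matrix(ff$u, nrow = 3)
  mid <- u[, 65]
  beta <- 12 * 0.156 / 11
  expect_equal(mid, beta * c(3 / 4, 5 / 4, 3 / 4), tolerance = 2e-2)
  # developed gradient against the coarse oracle
  grad <- developed_pressure_gradient(ff, m)
  oracle <- coarse_channel_drop(0.0035, 0.156, 0.130, 0.003, 3)
  expect_equal(grad * 0.130, oracle, tolerance = 0.02)
})

test_that("steady solution is symmetric about the channel midline", {
  m <- short_channel_mesh(L = 40)
  ff <- solve_steady(m)
  u <- matrix(ff$u, nrow = 3)
  v <- matrix(ff$v, nrow = 3)
  peak <- max(abs(u))
  expect_lt(max(abs(u[1, ] - u[3, ])) / peak, 1e-6)
  expect_lt(max(abs(v[1, ] + v[3, ])) / peak, 1e-6)
})

test_that("adding a constant to the outlet gauge shifts pressure only", {
  m <- short_channel_mesh(L = 20)
  f0 <- solve_steady(m, bc = boundary_conditions(outlet_pressure = 0))
  f1 <- solve_steady(m, bc = boundary_conditions(outlet_pressure = 250))
  expect_equal(f1$u, f0$u, tolerance = 1e-9)
  expect_equal(f1$v, f0$v, tolerance = 1e-9)
  expect_equal(f1$p - f0$p, rep(250, length(f0$p)), tolerance = 1e-6)
})

test_that("converged runs conserve mass between inlet and outlet", {
  for (spec in list(c(30, 0), c(60, 1))) {
    dm <- design_mesh(spec[1], spec[2], L = 60)
    ff <- solve_steady(dm$mesh)
    expect_true(ff$converged)
    mb <- mass_balance(ff)
    expect_lt(mb$relative_imbalance, 1e-2)
  }
})

test_that("pressure drop converges toward the closed form under refinement", {
  # parabolic inlet removes the entrance defect, isolating discretization
  # error, which must shrink monotonically with observed order >= 1
  bc <- boundary_conditions(inlet_profile = "parabolic")
  exact <- poiseuille_drop(0.0035, 0.156, 0.020, 0.003)
  errs <- vapply(c(1, 0.5, 0.25), function(iv) {
    m <- sweep_mesh(offset_lumen(build_centerline(
      vessel_geometry(30, 0, L = 20)), 3), iv)
    ff <- solve_steady(m, bc = bc)
    abs(pressure_drop(ff, m)$dp_pa - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  order_obs <- log2(errs[1] / errs[2])
  expect_gt(order_obs, 1)
})

test_that("residual history ends below the configured tolerance", {
  m <- short_channel_mesh(L = 20)
  ff <- solve_steady(m)
  h <- residual_history(ff)
  expect_equal(nrow(h), ff$iterations)
  last <- h[nrow(h), c("u", "v", "continuity")]
  expect_true(all(last <= 1e-3))
})

test_that("the laminar guard warns on turbulent inlet conditions", {
  m <- short_channel_mesh(L = 10)
  w <- capture_warnings(
    try(solve_steady(m, bc = boundary_conditions(inlet_velocity = 5),
                     cfg = solver_config(max_iter = 3)), silent = TRUE))
  expect_true(any(grepl("Reynolds", w)))
})

test_that("a constant waveform reproduces the steady solution", {
  m <- short_channel_mesh(L = 20)
  wf <- build_waveform(data.frame(t = 0, v_in = 0.156, p_out = 0),
                       period = 1)
  cfg <- solver_config(dt = 0.05, n_cycles = 2)
  ser <- solve_unsteady(m, waveform = wf, cfg = cfg,
                        snapshot_times = c(0.25))
  sn <- series_snapshot(ser, 0.25, cycle = 2)
  stf <- solve_steady(m)
  expect_equal(sn$u, stf$u, tolerance = 5e-3)
  expect_equal(sn$p, stf$p, tolerance = 1e-2)
  # instantaneous inlet mass flux equals rho * v_in * d per unit depth
  expect_equal(-sum(sn$F_inl), 1050 * 0.156 * 0.003, tolerance = 1e-12)
})

test_that("pulsatile cycles settle into a periodic state", {
  dm <- design_mesh(120, 1, L = 60)
  ser <- solve_unsteady(dm$mesh,
                        cfg = solver_config(relax_u = 0.8, relax_p = 0.5))
  s2 <- series_snapshot(ser, 0.26, cycle = 2)
  s3 <- series_snapshot(ser, 0.26, cycle = 3)
  rel <- sqrt(sum((s2$u - s3$u)^2 + (s2$v - s3$v)^2) /
              sum(s3$u^2 + s3$v^2))
  expect_lt(rel, 0.05)
  # snapshots carry the anchor boundary values: inlet flux at t1
  expect_equal(-sum(s2$F_inl), 1050 * 0.51 * 0.003, tolerance = 1e-12)
})

test_that("missing snapshot requests name the stored times", {
  m <- short_channel_mesh(L = 10)
  wf <- build_waveform(data.frame(t = 0, v_in = 0.1, p_out = 0), period = 0.2)
  ser <- solve_unsteady(m, waveform = wf,
                        cfg = solver_config(dt = 0.05, n_cycles = 2),
                        snapshot_times = 0.1)
  expect_s3_class(series_snapshot(ser, 0.1, 2), "flow_fields")
  expect_error(series_snapshot(ser, 0.15, 2), "stored")
})
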