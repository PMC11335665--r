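test_that("channel flow develops into the plane-Poiseuille solution", {
  ny <- 64
  u_mean <- 1e-4 # inlet Re ~ 2.8: entrance length well inside the channel
  f <- channel_flow(ny, u_mean)
  g <- f$grid
  ref <- poiseuille_reference(g$ny * g$dy, u_mean,
                              f$bc$fluid$dynamic_viscosity)
  expect_true(f$report$converged)

  # downstream transverse profile vs the exact parabola
  i <- round(0.8 * g$nx)
  prof <- f$u[i, ]
  yc <- (seq_len(ny) - 0.5) * g$dy
  expect_lt(max(abs(prof - ref$u_profile(yc))) / ref$u_centerline, 0.01)
  expect_equal(max(prof) / mean(prof), 1.5, tolerance = 0.01)

  # wall shear stress vs 6 mu U / h
  w <- compute_wall_shear_stress(f)
  tau <- w$tau_Pa[which.min(abs(w$x_m - 0.8 * g$nx * g$dx))]
  expect_equal(tau, ref$tau_wall, tolerance = 0.01)

  # net flux through every vertical cross-section equals the inlet flux
  flux <- apply(f$u, 1, sum) * g$dy
  expect_true(all(abs(flux - ref$flux) / ref$flux < 1e-3))
})

test_that("converged fields conserve mass and satisfy continuity", {
  f <- channel_flow(32)
  g <- f$grid
  expect_lt(f$report$mass_imbalance, 1e-3)
  expect_lt(f$report$continuity_residual, 1e-10)

  # baffled geometry at Re ~ 27
  gb <- rasterize_layout(
    geometry_layout(vessel_spec(), list(
      baffle_spec(0.04, "base", 6e-3, thickness = 4e-3),
      baffle_spec(0.08, "top", 6e-3, thickness = 4e-3))), 60, 16)
  fb <- solve_steady_flow(gb, boundary_conditions(5.8946e-3))
  expect_true(fb$report$converged)
  expect_lt(fb$report$mass_imbalance, 1e-3)
})

test_that("Stokes solver is exactly linear in the inlet velocity", {
  g <- channel_grid(48, 16)
  f1 <- solve_stokes(g, boundary_conditions(1e-5))
  f10 <- solve_stokes(g, boundary_conditions(1e-4))
  expect_equal(f10$u, 10 * f1$u, tolerance = 1e-12)
  expect_equal(f10$v, 10 * f1$v, tolerance = 1e-12)

  # zero inflow gives the zero field
  f0 <- solve_stokes(g, boundary_conditions(0))
  expect_true(all(f0$u == 0) && all(f0$v == 0))
})

test_that("Stokes and coupled solvers agree in the creeping regime", {
  g <- channel_grid(48, 16)
  bc <- boundary_conditions(1e-5) # Re ~ 0.28
  ws <- compute_wall_shear_stress(solve_stokes(g, bc))
  wf <- compute_wall_shear_stress(solve_steady_flow(g, bc))
  expect_equal(glance(ws)$mean_wss, glance(wf)$mean_wss, tolerance = 5e-3)
})

test_that("lid-driven cavity at Re 100 matches a fine-grid self-converged reference", {
  # reference: centreline velocities from a 256^2 run of this solver
  # (central-deferred convection), sampled at y, x = k/16
  u_ref <- c(-0.041951, -0.077084, -0.109756, -0.141847, -0.172607,
             -0.198350, -0.212842, -0.209051, -0.182024, -0.131248,
             -0.060281, 0.027807, 0.140336, 0.310455, 0.597363)
  v_ref <- c(0.094723, 0.149131, 0.174226, 0.179132, 0.169033,
             0.145651, 0.108724, 0.057520, -0.007723, -0.083992,
             -0.162887, -0.227672, -0.253618, -0.218581, -0.123265)
  fl <- fluid_properties(density = 1, dynamic_viscosity = 0.01)
  bc <- boundary_conditions(0, fluid = fl, lid_velocity = 1)
  f <- solve_steady_flow(cavity_grid(64), bc,
                         solver_config(convection = "central_deferred"))
  expect_true(f$report$converged)
  k <- 1:15
  u64 <- 0.5 * (f$u[33, 4 * k] + f$u[33, 4 * k + 1])
  v64 <- 0.5 * (f$v[4 * k, 33] + f$v[4 * k + 1, 33])
  l2 <- sqrt(sum((u64 - u_ref)^2 + (v64 - v_ref)^2) /
               sum(u_ref^2 + v_ref^2))
  expect_lt(l2, 0.02)
})

test_that("solves are deterministic", {
  g <- channel_grid(48, 16)
  bc <- boundary_conditions(2e-4)
  f1 <- solve_steady_flow(g, bc)
  f2 <- solve_steady_flow(g, bc)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$p, f2$p)
})

test_that("tidy and glance expose the field and its diagnostics", {
  f <- channel_flow(32)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("x", "y", "u", "v", "p", "speed", "flag"))
  expect_equal(nrow(td), f$grid$nx * f$grid$ny)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_named(gl, c("iterations", "converged", "rel_change",
                     "momentum_residual", "continuity_residual",
                     "mass_imbalance"))
})
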