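test_that("poiseuille reference evaluates the closed forms", {
  r <- poiseuille_reference(1, 1, 1)
  expect_equal(r$tau_wall, 6)
  expect_equal(r$u_centerline, 1.5)
  expect_equal(r$u_profile(0.5), 1.5)
  expect_equal(r$u_profile(c(0, 1)), c(0, 0))
  r2 <- poiseuille_reference(0.02, 0.01, 7.191e-4)
  expect_equal(r2$tau_wall, 2.1573e-3, tolerance = 1e-4)
  expect_equal(r2$flux, 2e-4)
})

test_that("synthetic vortex fields are discretely divergence-free", {
  g <- channel_grid(64, 32)
  f <- synthetic_vortex_field(g, c(0.03, 0.01), 0.012, 3e-4,
                              background_U = 1e-5)
  expect_lt(f$report$continuity_residual, 1e-12)
  # streamfunction round trip is exact
  sf <- compute_streamfunction(f)
  expect_lt(sf$path_error, 1e-12)
  # a patch reaching outside the box is rejected
  expect_error(
    synthetic_vortex_field(g, c(0.001, 0.01), 0.012, 1e-4),
    class = "eddyrisk_domain_error")
  # fixtures are deterministic
  f2 <- synthetic_vortex_field(g, c(0.03, 0.01), 0.012, 3e-4,
                               background_U = 1e-5)
  expect_identical(f$u, f2$u)
})

test_that("grid convergence study observes at least first-order accuracy", {
  gc <- memo("gcs", grid_convergence_study(1e-4, c(16, 32, 64)))
  p <- attr(gc, "observed_order")
  expect_gte(min(p), 1)
  expect_error(grid_convergence_study(1e-4, c(16, 32)),
               class = "eddyrisk_domain_error")
  expect_error(grid_convergence_study(1e-4, c(16, 24, 36)),
               class = "eddyrisk_domain_error")
})
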