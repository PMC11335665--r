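test_that("standard layouts A..K have the documented baffle plans", {
  plans <- list(
    A = list(n = 0),
    B = list(n = 3, h = 2e-3, side = "base", angle = 0),
    C = list(n = 3, h = 4e-3, side = "base", angle = 0),
    D = list(n = 9, h = 2e-3, side = "base", angle = 0),
    E = list(n = 9, h = 4e-3, side = "base", angle = 0),
    F = list(n = 9, h = 2e-3, side = "top", angle = 0),
    G = list(n = 9, h = 4e-3, side = "top", angle = 0),
    H = list(n = 4, h = 4e-3, side = "top", angle = 45),
    J = list(n = 4, h = 4e-3, side = "top", angle = -45)
  )
  for (id in names(plans)) {
    lay <- standard_layout(id)
    p <- plans[[id]]
    expect_length(lay$baffles, p$n)
    if (p$n > 0) {
      expect_true(all(vapply(lay$baffles, `[[`, numeric(1), "height") == p$h))
      expect_true(all(vapply(lay$baffles, `[[`, character(1), "side") == p$side))
      expect_true(all(vapply(lay$baffles, `[[`, numeric(1), "angle") == p$angle))
    }
  }
  # graded designs: one 4 mm fin then three 8 mm fins
  for (id in c("I", "K")) {
    lay <- standard_layout(id)
    hs <- vapply(lay$baffles, `[[`, numeric(1), "height")
    expect_equal(hs, c(4e-3, 8e-3, 8e-3, 8e-3))
    expect_equal(unique(vapply(lay$baffles, `[[`, numeric(1), "angle")),
                 if (id == "I") 45 else -45)
  }
  expect_error(standard_layout("Z"), class = "eddyrisk_config_error")
  # determinism
  expect_identical(standard_layout("E"), standard_layout("E"))
})

test_that("rasterization flags solids by cell-centre inclusion", {
  g0 <- rasterize_layout(standard_layout("A"), 48, 16)
  expect_true(all(g0$fluid))

  # one vertical base fin: solid column of round(h/dy) cells (+-1)
  v <- vessel_spec()
  lay <- geometry_layout(v, list(baffle_spec(0.06, "base", 8e-3,
                                             thickness = 4e-3)))
  g <- rasterize_layout(lay, 120, 25)
  expect_equal(sum(!g$fluid),
               round(8e-3 / g$dy) * round(4e-3 / g$dx), tolerance = 0.3)
  hits <- rowSums(!g$fluid)
  expect_true(all(abs(hits[hits > 0] - round(8e-3 / g$dy)) <= 1))

  # rotating by 45 degrees conserves area to ~20% at equal resolution
  lay45 <- geometry_layout(v, list(baffle_spec(0.06, "base", 8e-3,
                                               angle = 45,
                                               thickness = 4e-3)))
  g45 <- rasterize_layout(lay45, 240, 50)
  g00 <- rasterize_layout(lay, 240, 50)
  expect_lt(abs(sum(!g45$fluid) - sum(!g00$fluid)) / sum(!g00$fluid), 0.2)
})

test_that("rasterized solid area converges to the analytic baffle area", {
  v <- vessel_spec()
  lay <- geometry_layout(v, list(baffle_spec(0.055, "base", 7e-3,
                                             angle = 45, thickness = 4e-3)))
  exact <- 7e-3 * 4e-3 / (0.120 * 0.025)
  errs <- vapply(c(1, 2, 4), function(k) {
    g <- rasterize_layout(lay, 120 * k, 25 * k)
    abs(mean(!g$fluid) - exact) / exact
  }, numeric(1))
  expect_lt(errs[3], errs[1]) # halving dx twice shrinks the error
  expect_lt(errs[3], 0.1)
})

test_that("top designs mirror base designs across the horizontal midline", {
  for (pair in list(c("D", "F"), c("E", "G"))) {
    gb <- rasterize_layout(standard_layout(pair[1]), 240, 50)
    gt <- rasterize_layout(standard_layout(pair[2]), 240, 50)
    expect_identical(gb$fluid[, 50:1], gt$fluid)
  }
})

test_that("geometry validation flood-fills inlet to outlet", {
  expect_true(validate_geometry(
    rasterize_layout(standard_layout("A"), 48, 16))$connected)
  expect_true(validate_geometry(
    rasterize_layout(standard_layout("E"), 240, 50))$connected)

  # a fin spanning (almost) the full height blocks the channel
  v <- vessel_spec()
  lay <- geometry_layout(v, list(baffle_spec(0.06, "base", 0.0249,
                                             thickness = 4e-3)))
  g <- rasterize_layout(lay, 60, 16)
  expect_error(validate_geometry(g), class = "eddyrisk_geometry_error")
})

test_that("resolution and configuration guards fire", {
  expect_error(rasterize_layout(standard_layout("B"), 12, 50),
               class = "eddyrisk_resolution_error")
  # default 1 mm fins need dx, dy <= 0.5 mm
  expect_error(rasterize_layout(standard_layout("B"), 60, 16),
               class = "eddyrisk_resolution_error")
  expect_error(vessel_spec(inlet_center_y = 0.001),
               class = "eddyrisk_geometry_error")
  expect_error(
    geometry_layout(vessel_spec(),
                    list(baffle_spec(0.06, "base", 0.030))),
    class = "eddyrisk_geometry_error") # taller than the vessel
  expect_error(
    geometry_layout(vessel_spec(), list(
      baffle_spec(0.0600, "base", 4e-3),
      baffle_spec(0.0605, "base", 4e-3))),
    class = "eddyrisk_geometry_error") # overlapping fins
})
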