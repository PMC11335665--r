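test_that("Kolmogorov microscale and dissipation estimate evaluate the closed forms", {
  expect_equal(kolmogorov_microscale(1, 1), 1)
  expect_equal(kolmogorov_microscale(2, 8), 1)
  # water-like medium at the lysis-scale dissipation rate of ~1e6 m^2/s^3
  nu <- 0.0007191 / 994
  expect_equal(kolmogorov_microscale(nu, 1e6), (nu^3 / 1e6)^0.25)
  expect_equal(kolmogorov_microscale(nu, 1e6), 7.85e-7,
               tolerance = 1e-3)

  expect_equal(dissipation_estimate(1, 1), 1)
  expect_equal(dissipation_estimate(2, 1), 8)
  expect_equal(dissipation_estimate(0.0589, 0.00331), 0.0589^3 / 0.00331)
  expect_equal(dissipation_estimate(0.0589, 0.00331), 0.0617,
               tolerance = 1e-3)

  expect_error(kolmogorov_microscale(-1, 1), class = "eddyrisk_domain_error")
  expect_error(kolmogorov_microscale(1, 0), class = "eddyrisk_domain_error")
  expect_error(dissipation_estimate(0, 1), class = "eddyrisk_domain_error")
})

test_that("eddy size ratio matches the tabulated Re^(3/4) values", {
  expect_equal(eddy_size_ratio(1), 1)
  expect_equal(eddy_size_ratio(16), 8)
  expect_equal(round(eddy_size_ratio(2.7), 2), 2.11)
  expect_equal(round(eddy_size_ratio(27), 2), 11.84)
  expect_equal(round(eddy_size_ratio(270), 2), 66.61)
  expect_error(eddy_size_ratio(0), class = "eddyrisk_domain_error")
})

test_that("eddy size ratio obeys the power law ratio(k^4) = k^3 exactly", {
  for (k in c(1, 2, 3, 10)) {
    expect_identical(eddy_size_ratio(k^4), k^3)
  }
})

test_that("smallest-eddy prediction is linear and reproduces tabulated rows", {
  expect_equal(predict_smallest_eddy(8, 16), 1)
  expect_equal(round(predict_smallest_eddy(3.1, 2.7), 1), 1.5)
  expect_equal(predict_smallest_eddy(3.1, 2.7), 1.4717, tolerance = 1e-4)
  expect_equal(round(predict_smallest_eddy(25.4, 2.7), 1), 12.1)
  # linearity: doubling the input doubles the output exactly
  for (re in c(2.7, 27, 270)) {
    expect_identical(predict_smallest_eddy(2 * 5.5, re),
                     2 * predict_smallest_eddy(5.5, re))
  }
})

test_that("risk assessment classifies and ratios as tabulated", {
  a <- assess_risk(reynolds = 2.7, largest_eddy_mm = 3.1)
  expect_equal(round(a$smallest_to_cell_ratio, 1), 73.6)
  expect_equal(a$verdict, "safe")

  a2 <- assess_risk(reynolds = 270, largest_eddy_mm = 34.6)
  expect_equal(round(a2$smallest_to_cell_ratio, 1), 26.0)
  expect_equal(a2$verdict, "safe")

  # 0.04 mm eddy at Re 16 cascades to 0.005 mm < cell diameter
  a3 <- assess_risk(reynolds = 16, largest_eddy_mm = 0.04)
  expect_equal(a3$smallest_eddy_mm, 0.005)
  expect_equal(a3$verdict, "at_risk")
})

test_that("risk assessment reproduces every published derived cell at 1 d.p.", {
  tab <- published_eddy_table()
  out <- assess_risk(tab)
  expect_equal(round(out$smallest_eddy_mm, 1), tab$smallest_printed)
  expect_equal(round(out$smallest_to_cell_ratio, 1), tab$ratio_printed)
  expect_true(all(out$verdict == "safe"))
})

test_that("verdict is monotone in largest eddy size at fixed Re", {
  sizes <- sort(10^runif(50, -3, 2))
  for (re in c(2.7, 270)) {
    v <- assess_risk(reynolds = re, largest_eddy_mm = sizes)$verdict
    # once safe, larger eddies stay safe
    expect_true(all(diff(v == "safe") >= 0))
  }
})

test_that("critical curve is the exact risk boundary and is monotone", {
  cc <- critical_eddy_curve(1, 1e4, n_points = 25)
  expect_equal(cc$min_safe_largest_eddy_mm[1], 0.02)            # Re = 1
  expect_equal(cc$min_safe_largest_eddy_mm[25], 20)             # Re = 1e4
  expect_true(all(diff(cc$reynolds) > 0))
  expect_true(all(diff(cc$min_safe_largest_eddy_mm) > 0))
  # points on the curve cascade exactly to the danger scale
  a <- assess_risk(reynolds = cc$reynolds,
                   largest_eddy_mm = cc$min_safe_largest_eddy_mm)
  expect_equal(a$smallest_eddy_mm, rep(0.02, 25), tolerance = 1e-12)
  expect_true(all(a$verdict == "at_risk")) # boundary counts as at risk
  expect_error(critical_eddy_curve(10, 1), class = "eddyrisk_domain_error")
  expect_error(critical_eddy_curve(1, 10, n_points = 1),
               class = "eddyrisk_domain_error")
})

test_that("reynolds_number recovers the tabulated inlet Reynolds numbers", {
  expect_equal(reynolds_number(1, 1, 1), 1)
  nu <- 0.0007191 / 994
  expect_equal(reynolds_number(5.8946e-4, 3.31e-3, nu), 2.70,
               tolerance = 2e-3)
  expect_equal(reynolds_number(5.8946e-2, 3.31e-3, nu), 270,
               tolerance = 2e-3)
  expect_error(reynolds_number(1, -1, 1), class = "eddyrisk_domain_error")
})

test_that("fluid properties derive kinematic viscosity consistently", {
  fl <- fluid_properties()
  expect_equal(fl$kinematic_viscosity * fl$density, fl$dynamic_viscosity,
               tolerance = 1e-12)
  expect_error(fluid_properties(density = 0),
               class = "eddyrisk_domain_error")
})
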