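#' Kolmogorov microscale
#'
#' The length scale at which the turbulent energy cascade terminates and
#' kinetic energy is dissipated as heat by viscosity:
#' `eta = (nu^3 / epsilon)^(1/4)`. Suspended cells whose diameter exceeds the
#' smallest eddies experience opposing velocity gradients across their
#' membrane, so `eta` at or below the cell diameter signals a damage risk.
#'
#' @param nu Kinematic viscosity in m^2/s.
#' @param epsilon Mean turbulent kinetic-energy dissipation rate per unit
#'   mass in m^2/s^3.
#' @return Microscale length `eta` in m (vectorised).
#' @examples
#' kolmogorov_microscale(1, 1)
#' kolmogorov_microscale(7.2344e-7, 1e6) # creeping-scale nu, lysis-scale epsilon
#' @seealso [dissipation_estimate()], [eddy_size_ratio()]
#' @export
kolmogorov_microscale <- function(nu, epsilon) {
  check_positive(nu = nu, epsilon = epsilon)
  (nu^3 / epsilon)^0.25
}

#' Dissipation-rate estimate from macroscopic flow descriptors
#'
#' Order-of-magnitude estimate of the mean dissipation rate obtained by
#' approximating the large-eddy turnover time with `L/U`, giving
#' `epsilon ~ U^3 / L`. The order-one prefactor is taken as exactly 1.
#'
#' @param velocity Flow velocity U in m/s.
#' @param length Characteristic length L in m.
#' @return Estimated dissipation rate in m^2/s^3 (vectorised).
#' @examples
#' dissipation_estimate(2, 1)
#' @export
dissipation_estimate <- function(velocity, length) {
  check_positive(velocity = velocity, length = length)
  velocity^3 / length
}

#' Largest-to-smallest eddy size ratio
#'
#' Combining the Kolmogorov microscale with the `U^3/L` dissipation estimate
#' gives the classical cascade scaling for the ratio of the largest to the
#' smallest eddy in a flow: `L / eta ~ Re^(3/4)`.
#'
#' @param reynolds Reynolds number of the flow (dimensionless, > 0).
#' @return `reynolds^(3/4)` (vectorised).
#' @examples
#' eddy_size_ratio(c(2.7, 27, 270))
#' @export
eddy_size_ratio <- function(reynolds) {
  check_positive(reynolds = reynolds)
  reynolds^0.75
}

#' Predicted smallest eddy after cascade decay
#'
#' Divides an observed (or simulated) largest eddy size by the cascade ratio
#' `Re^(3/4)`. The result has the same length unit as the input.
#'
#' @param largest_eddy Largest observed eddy size (any length unit).
#' @param reynolds Reynolds number of the flow.
#' @return Predicted smallest eddy size in the unit of `largest_eddy`.
#' @examples
#' predict_smallest_eddy(3.1, 2.7) # mm in, mm out
#' @export
predict_smallest_eddy <- function(largest_eddy, reynolds) {
  check_positive(largest_eddy = largest_eddy)
  largest_eddy / eddy_size_ratio(reynolds)
}

#' Damage thresholds for suspended cells
#'
#' Bundles the length and stress thresholds used when classifying flow
#' conditions. Defaults: cell diameter 20 micrometres (0.02 mm, a typical
#' expanded T cell), Kolmogorov danger scale equal to the cell diameter,
#' lethal wall shear stress 3 Pa (30 dyn/cm^2) and lysis threshold 5 Pa
#' (50 dyn/cm^2, the stress equivalent of dissipation rates around 1e6
#' m^2/s^3). A 0.1 Pa reporting level is carried along for flagging
#' conditions that are individually harmless but worth inspection.
#'
#' @param cell_diameter Cell diameter in m.
#' @param kolmogorov_danger_scale Smallest-eddy size in m at or below which
#'   dissipation is considered dangerous.
#' @param lethal_wss Wall shear stress in Pa generally held to cause cell
#'   death.
#' @param lysis_wss Wall shear stress in Pa associated with immediate lysis.
#' @param reporting_wss Reporting level in Pa for flagging elevated but
#'   sub-lethal shear.
#' @return An object of class `risk_thresholds` (a named list, SI units).
#' @examples
#' risk_thresholds()
#' @export
risk_thresholds <- function(cell_diameter = 20e-6,
                            kolmogorov_danger_scale = 20e-6,
                            lethal_wss = 3,
                            lysis_wss = 5,
                            reporting_wss = 0.1) {
  check_positive(cell_diameter = cell_diameter,
                 kolmogorov_danger_scale = kolmogorov_danger_scale,
                 lethal_wss = lethal_wss, lysis_wss = lysis_wss,
                 reporting_wss = reporting_wss)
  structure(
    list(cell_diameter = cell_diameter,
         kolmogorov_danger_scale = kolmogorov_danger_scale,
         lethal_wss = lethal_wss, lysis_wss = lysis_wss,
         reporting_wss = reporting_wss),
    class = "risk_thresholds"
  )
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat("<risk_thresholds>\n")
  cat(sprintf("  cell diameter:        %g mm\n", x$cell_diameter * 1e3))
  cat(sprintf("  eddy danger scale:    %g mm\n",
              x$kolmogorov_danger_scale * 1e3))
  cat(sprintf("  lethal / lysis WSS:   %g / %g Pa\n",
              x$lethal_wss, x$lysis_wss))
  invisible(x)
}

#' Assess cell-death risk from eddy dissipation
#'
#' Applies the cascade scaling to observed largest-eddy sizes: the smallest
#' eddy each observation will decay to is `largest / Re^(3/4)`, and a
#' condition is classified `at_risk` when that smallest eddy is at or below
#' the cell diameter (the boundary case is classified conservatively as at
#' risk). The returned ratio column divides the unrounded smallest eddy by
#' the cell diameter, so values above 1 are safe.
#'
#' @param data A data frame with numeric columns `reynolds` and
#'   `largest_eddy_mm`. Any further columns (e.g. a condition label) are
#'   carried through. May be omitted if `reynolds` and `largest_eddy_mm`
#'   are given directly.
#' @param reynolds,largest_eddy_mm Used to build `data` when it is `NULL`.
#' @param thresholds A [risk_thresholds()] object.
#' @return The input tibble with appended columns `eddy_ratio`
#'   (`Re^(3/4)`), `smallest_eddy_mm`, `smallest_to_cell_ratio` and
#'   `verdict` (`"safe"` or `"at_risk"`).
#' @examples
#' assess_risk(reynolds = 2.7, largest_eddy_mm = 3.1)
#' @export
assess_risk <- function(data = NULL, reynolds = NULL, largest_eddy_mm = NULL,
                        thresholds = risk_thresholds()) {
  if (is.null(data)) {
    if (is.null(reynolds) || is.null(largest_eddy_mm)) {
      abort("Supply `data` or both `reynolds` and `largest_eddy_mm`.",
            class = "eddyrisk_domain_error")
    }
    data <- tibble(reynolds = reynolds, largest_eddy_mm = largest_eddy_mm)
  }
  data <- as_tibble(data)
  for (col in c("reynolds", "largest_eddy_mm")) {
    if (!col %in% names(data)) {
      abort(sprintf("`data` must contain a numeric `%s` column.", col),
            class = "eddyrisk_domain_error")
    }
  }
  stopifnot(inherits(thresholds, "risk_thresholds"))
  cell_mm <- thresholds$cell_diameter * 1e3
  dplyr::mutate(
    data,
    eddy_ratio = eddy_size_ratio(.data$reynolds),
    smallest_eddy_mm = predict_smallest_eddy(.data$largest_eddy_mm,
                                             .data$reynolds),
    smallest_to_cell_ratio = .data$smallest_eddy_mm / cell_mm,
    verdict = ifelse(.data$smallest_eddy_mm <= cell_mm, "at_risk", "safe")
  )
}

#' Critical largest-eddy curve
#'
#' For each Reynolds number the smallest "safe" largest-eddy size is the one
#' whose cascade end point equals the danger scale:
#' `L_min(Re) = danger_scale * Re^(3/4)`. Flows whose measured largest eddy
#' falls below this curve are predicted to dissipate down to cell-sized
#' eddies and hence to risk cell death.
#'
#' @param re_min,re_max Range of Reynolds numbers (0 < re_min < re_max).
#' @param n_points Number of points on the log-spaced grid (>= 2).
#' @param thresholds A [risk_thresholds()] object; only the danger scale is
#'   used.
#' @return A tibble of class `critical_eddy_curve` with columns `reynolds`,
#'   `min_safe_largest_eddy_m` and `min_safe_largest_eddy_mm`, strictly
#'   increasing in `reynolds`.
#' @examples
#' critical_eddy_curve(1, 1e4, n_points = 5)
#' @export
critical_eddy_curve <- function(re_min, re_max, n_points = 200,
                                thresholds = risk_thresholds()) {
  check_positive(re_min = re_min, re_max = re_max)
  if (re_max <= re_min) {
    abort("`re_max` must exceed `re_min`.", class = "eddyrisk_domain_error")
  }
  if (n_points < 2) {
    abort("`n_points` must be at least 2.", class = "eddyrisk_domain_error")
  }
  re <- exp(seq(log(re_min), log(re_max), length.out = n_points))
  out <- tibble(
    reynolds = re,
    min_safe_largest_eddy_m = thresholds$kolmogorov_danger_scale *
      eddy_size_ratio(re),
    min_safe_largest_eddy_mm = thresholds$kolmogorov_danger_scale * 1e3 *
      eddy_size_ratio(re)
  )
  class(out) <- c("critical_eddy_curve", class(out))
  out
}

#' @describeIn critical_eddy_curve Log-log plot of the critical curve; the
#'   region above the line is safe, below it cell-scale dissipation is
#'   predicted.
#' @param object A `critical_eddy_curve`.
#' @param ... Unused.
#' @method autoplot critical_eddy_curve
#' @export
autoplot.critical_eddy_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$reynolds,
                               y = .data$min_safe_largest_eddy_mm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Inlet Reynolds number",
      y = "Minimum safe largest eddy (mm)",
      title = "Critical eddy size for cell-safe dissipation",
      subtitle = "Below the curve the cascade produces cell-scale eddies"
    )
}

#' Bundled largest-eddy measurements for the standard layouts
#'
#' Largest recirculation-zone sizes on the vessel base for the eleven
#' standard baffle layouts at inlet Reynolds numbers 2.7, 27 and 270
#' (feed rates 1, 10 and 100 mL/min), as measured from streamline
#' visualisations of a reference CFD study of the same geometries. Useful
#' for exercising the standalone risk assessor without running the solver.
#'
#' @return A tibble with columns `flow_rate_ml_min`, `reynolds`,
#'   `condition`, `largest_eddy_mm` (33 rows).
#' @examples
#' assess_risk(reference_eddy_measurements())
#' @export
reference_eddy_measurements <- function() {
  path <- system.file("extdata", "reference_eddies.csv",
                      package = "eddyrisk", mustWork = TRUE)
  read_eddy_csv(path)
}
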