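#' Fluid properties of the culture medium
#'
#' Culture media in perfusion systems are usually treated as water-like
#' Newtonian fluids. The default corresponds to aqueous medium at 37 degrees C:
#' density 994 kg/m^3 and dynamic viscosity 7.191e-4 Pa.s.
#'
#' @param density Fluid density in kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity in Pa.s.
#'
#' @return An object of class `fluid_properties`: a list with `density`,
#'   `dynamic_viscosity` and the derived `kinematic_viscosity` (m^2/s).
#' @examples
#' fl <- fluid_properties()
#' fl$kinematic_viscosity
#' @export
fluid_properties <- function(density = 994, dynamic_viscosity = 7.191e-4) {
  check_positive(density = density, dynamic_viscosity = dynamic_viscosity)
  structure(
    list(
      density = density,
      dynamic_viscosity = dynamic_viscosity,
      kinematic_viscosity = dynamic_viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat(sprintf("  density:             %g kg/m^3\n", x$density))
  cat(sprintf("  dynamic viscosity:   %g Pa.s\n", x$dynamic_viscosity))
  cat(sprintf("  kinematic viscosity: %g m^2/s\n", x$kinematic_viscosity))
  invisible(x)
}

#' Reynolds number
#'
#' `Re = U L / nu`, the ratio of inertial to viscous forces. This is the
#' quantity that controls the eddy-cascade scaling `L/eta ~ Re^(3/4)` used by
#' [assess_risk()].
#'
#' @param velocity Flow velocity U in m/s.
#' @param length Characteristic length L in m.
#' @param kinematic_viscosity nu in m^2/s.
#' @return Dimensionless Reynolds number (vectorised).
#' @examples
#' reynolds_number(1, 1, 1)
#' @export
reynolds_number <- function(velocity, length, kinematic_viscosity) {
  check_positive(velocity = velocity, length = length,
                 kinematic_viscosity = kinematic_viscosity)
  velocity * length / kinematic_viscosity
}

#' Mean inlet velocity from a volumetric flow rate
#'
#' Divides the volumetric feed rate by the inlet port cross-section. The
#' default area is a circular port of radius 3 mm, which maps feed rates of
#' 0.1 to 100 mL/min onto mean velocities of 5.8946e-5 to 5.8946e-2 m/s.
#'
#' @param flow_rate_ml_min Feed rate in mL/min.
#' @param inlet_area Port cross-section in m^2. Default `pi * 0.003^2`.
#' @return Mean inlet velocity in m/s (vectorised).
#' @examples
#' inlet_velocity_from_flow_rate(c(0.1, 1, 10, 100))
#' @export
inlet_velocity_from_flow_rate <- function(flow_rate_ml_min,
                                          inlet_area = pi * 0.003^2) {
  check_positive(flow_rate_ml_min = flow_rate_ml_min, inlet_area = inlet_area)
  q_m3_s <- flow_rate_ml_min * 1e-6 / 60
  q_m3_s / inlet_area
}

#' Tabulate flow conditions for a set of feed rates
#'
#' Builds the macroscopic flow descriptors (velocity, characteristic length,
#' Reynolds number) for each requested feed rate. The default characteristic
#' length of 3.31 mm is the inlet dimension that, together with the default
#' port area and water-like medium, yields inlet Reynolds numbers of
#' 2.7 per mL/min of feed.
#'
#' @param flow_rate_ml_min Numeric vector of feed rates in mL/min.
#' @param fluid A [fluid_properties()] object.
#' @param characteristic_length Characteristic length in m used in the inlet
#'   Reynolds number. Default 3.31e-3.
#' @param inlet_area Inlet port area in m^2 passed to
#'   [inlet_velocity_from_flow_rate()].
#' @return A tibble with columns `flow_rate_ml_min`, `flow_rate_m3_s`,
#'   `inlet_velocity`, `characteristic_length`, `reynolds`.
#' @examples
#' flow_conditions(c(0.1, 1, 10, 100))
#' @export
flow_conditions <- function(flow_rate_ml_min,
                            fluid = fluid_properties(),
                            characteristic_length = 3.31e-3,
                            inlet_area = pi * 0.003^2) {
  check_positive(characteristic_length = characteristic_length)
  u <- inlet_velocity_from_flow_rate(flow_rate_ml_min, inlet_area)
  tibble(
    flow_rate_ml_min = flow_rate_ml_min,
    flow_rate_m3_s = flow_rate_ml_min * 1e-6 / 60,
    inlet_velocity = u,
    characteristic_length = characteristic_length,
    reynolds = reynolds_number(u, characteristic_length,
                               fluid$kinematic_viscosity)
  )
}
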