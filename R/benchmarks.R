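#' Analytic plane-Poiseuille reference
#'
#' Closed-form laminar channel flow between parallel plates a distance `h`
#' apart: `u(y) = 6 U_mean (y/h)(1 - y/h)`, wall shear
#' `tau = 6 mu U_mean / h`, flux per unit depth `U_mean h`. Used as the
#' exactly known oracle for solver and WSS verification.
#'
#' @param h Channel height in m.
#' @param u_mean Mean (bulk) velocity in m/s.
#' @param mu Dynamic viscosity in Pa.s.
#' @return An object of class `analytic_case`: fields `h`, `u_mean`,
#'   `mu`, `tau_wall`, `flux`, `u_centerline` and a function
#'   `u_profile(y)`.
#' @examples
#' poiseuille_reference(0.02, 0.01, 7.191e-4)$tau_wall
#' @export
poiseuille_reference <- function(h, u_mean, mu) {
  check_positive(h = h, u_mean = u_mean, mu = mu)
  structure(
    list(
      name = "poiseuille", h = h, u_mean = u_mean, mu = mu,
      tau_wall = 6 * mu * u_mean / h,
      flux = u_mean * h,
      u_centerline = 1.5 * u_mean,
      u_profile = function(y) 6 * u_mean * (y / h) * (1 - y / h)
    ),
    class = "analytic_case"
  )
}

#' Straight-channel grid (plane Poiseuille configuration)
#'
#' Convenience builder for an unbaffled vessel whose inlet and outlet
#' span the full left and right walls, i.e. a plane channel. A uniform
#' inlet profile develops into the parabolic Poiseuille profile within
#' the entrance length (about `0.05 Re h` plus a few channel heights).
#'
#' @param nx,ny Cell counts.
#' @param length,height Channel dimensions in m.
#' @return A [rasterize_layout()] grid.
#' @examples
#' channel_grid(48, 16)
#' @export
channel_grid <- function(nx = 96, ny = 32, length = 0.06, height = 0.02) {
  v <- vessel_spec(length = length, height = height,
                   inlet_height = height, inlet_center_y = height / 2,
                   outlet_height = height, outlet_center_y = height / 2)
  rasterize_layout(geometry_layout(v, list(), design_id = NA), nx, ny)
}

#' Closed square cavity grid (lid-driven verification case)
#'
#' A unit-square closed box with no inlet or outlet; drive it by setting
#' `lid_velocity` in [boundary_conditions()]. The classic lid-driven
#' cavity benchmark for incompressible solvers.
#'
#' @param n Cells per side.
#' @param side Box side length in m.
#' @return A `flagged_grid` with empty inlet/outlet.
#' @examples
#' cavity_grid(16)
#' @export
cavity_grid <- function(n = 64, side = 1) {
  check_positive(n = n, side = side)
  v <- vessel_spec(length = side, height = side,
                   inlet_height = side / 2, outlet_height = side / 2)
  lay <- geometry_layout(v, list(), design_id = NA)
  structure(
    list(nx = as.integer(n), ny = as.integer(n),
         dx = side / n, dy = side / n,
         fluid = matrix(TRUE, n, n),
         solid_side = matrix(NA_character_, n, n),
         inlet_rows = integer(0), outlet_rows = integer(0),
         layout = lay),
    class = "flagged_grid"
  )
}

#' Divergence-free synthetic vortex field
#'
#' Builds a flow field directly from an analytic streamfunction: a
#' uniform background stream `psi = U0 y` plus a compact rotational patch
#' `psi_v = S (1 - (r/R)^2)^2` inside radius `R = diameter/2` (C1 cutoff
#' at the rim). Staggered velocities are obtained by exact differencing
#' of the nodal streamfunction, so the discrete field is divergence-free
#' to machine precision and [compute_streamfunction()] recovers `psi`
#' exactly. Used as the ground-truth fixture for eddy detection: with
#' `strength` well above the closure threshold the marked region spans
#' the patch, so the detected size equals `diameter` to grid resolution.
#'
#' @param grid A `flagged_grid` (typically unbaffled).
#' @param center Patch centre `c(x, y)` in m.
#' @param diameter Patch diameter in m; must fit inside the domain.
#' @param strength Peak streamfunction of the patch in m^2/s (signed:
#'   positive = anticlockwise).
#' @param background_U Uniform background velocity in m/s.
#' @param fluid A [fluid_properties()] object (carried for WSS use).
#' @return A `flow_field` (pressure undefined).
#' @examples
#' g <- channel_grid(64, 32)
#' f <- synthetic_vortex_field(g, c(0.03, 0.01), 0.01, 1e-4)
#' nrow(detect_recirculation_zones(compute_streamfunction(f)))
#' @export
synthetic_vortex_field <- function(grid, center, diameter, strength,
                                   background_U = 0,
                                   fluid = fluid_properties()) {
  stopifnot(inherits(grid, "flagged_grid"))
  check_positive(diameter = diameter)
  nx <- grid$nx; ny <- grid$ny
  lx <- nx * grid$dx; ly <- ny * grid$dy
  r <- diameter / 2
  if (center[1] - r < 0 || center[1] + r > lx ||
      center[2] - r < 0 || center[2] + r > ly) {
    abort("Vortex patch extends outside the domain.",
          class = "eddyrisk_domain_error")
  }
  xn <- (0:nx) * grid$dx
  yn <- (0:ny) * grid$dy
  X <- matrix(xn, nx + 1, ny + 1)
  Y <- matrix(yn, nx + 1, ny + 1, byrow = TRUE)
  s2 <- ((X - center[1])^2 + (Y - center[2])^2) / r^2
  psi <- background_U * Y
  inside <- s2 < 1
  psi[inside] <- psi[inside] + strength * (1 - s2[inside])^2
  u <- (psi[, 2:(ny + 1)] - psi[, 1:ny]) / grid$dy
  v <- -(psi[2:(nx + 1), ] - psi[1:nx, ]) / grid$dx
  div <- (u[2:(nx + 1), ] - u[1:nx, ]) / grid$dx +
    (v[, 2:(ny + 1)] - v[, 1:ny]) / grid$dy
  structure(
    list(u = u, v = v, p = matrix(NA_real_, nx, ny), grid = grid,
         bc = boundary_conditions(max(background_U, 1e-300), fluid = fluid),
         cfg = solver_config(),
         report = list(iterations = 0L, converged = TRUE, rel_change = 0,
                       time_averaged = FALSE, momentum_residual = NA_real_,
                       continuity_residual = max(abs(div)) *
                         min(grid$dx, grid$dy) /
                         max(abs(u), abs(v), 1e-300),
                       mass_imbalance = NA_real_)),
    class = "flow_field"
  )
}

#' Grid-convergence study of mean base wall shear stress
#'
#' Solves the entrance-flow channel case on a sequence of grids, each
#' halving the spacing, and estimates the observed order of accuracy `p`
#' from Richardson analysis of the mean base WSS over the developed
#' downstream region (the singular slip/no-slip inlet corner is excluded):
#' `p = log2(|f1 - f2| / |f2 - f3|)` over consecutive triples.
#'
#' @param u_mean Bulk velocity in m/s.
#' @param resolutions Vector of at least 3 `ny` values (each >= 16), each
#'   double the previous (nx scales proportionally, 3:1 aspect).
#' @param fluid A [fluid_properties()] object.
#' @param cfg A [solver_config()].
#' @return A tibble of class `convergence_table` (`ny`, `mean_wss`) with
#'   attributes `observed_order` (vector of p estimates) and
#'   `monotone` (logical). Non-monotone differences trigger a warning,
#'   not a failure.
#' @examples
#' \donttest{
#' gc <- grid_convergence_study(0.002, c(16, 32, 64))
#' attr(gc, "observed_order")
#' }
#' @export
grid_convergence_study <- function(u_mean, resolutions = c(16, 32, 64),
                                   fluid = fluid_properties(),
                                   cfg = solver_config()) {
  check_positive(u_mean = u_mean)
  if (length(resolutions) < 3) {
    abort("Need at least 3 resolutions for Richardson analysis.",
          class = "eddyrisk_domain_error")
  }
  if (any(abs(diff(log2(resolutions)) - 1) > 1e-9)) {
    abort("Each resolution must double the previous one.",
          class = "eddyrisk_domain_error")
  }
  vals <- purrr::map_dbl(resolutions, function(ny) {
    g <- channel_grid(nx = 3 * ny, ny = ny)
    bc <- boundary_conditions(u_mean, fluid = fluid)
    f <- solve_steady_flow(g, bc, cfg)
    w <- compute_wall_shear_stress(f)
    # mean over the downstream 70% of the base: the slip/no-slip inlet
    # corner is singular and would dominate the whole-base mean
    mean(w$tau_Pa[w$x_m > 0.3 * g$nx * g$dx])
  })
  d <- abs(diff(vals))
  p <- log2(d[-length(d)] / d[-1])
  if (any(diff(vals) == 0) || any(sign(diff(vals)) != sign(diff(vals)[1]))) {
    warn("Grid-convergence differences are non-monotone; order estimate unreliable.")
  }
  out <- tibble(ny = resolutions, mean_wss = vals)
  attr(out, "observed_order") <- p
  attr(out, "monotone") <- all(sign(diff(vals)) == sign(diff(vals)[1]))
  class(out) <- c("convergence_table", class(out))
  out
}
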