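#' Streamfunction of a solved flow field
#'
#' Integrates the staggered velocities into a node-based streamfunction
#' `psi` with `psi = 0` on the base wall: `psi[i, j+1] = psi[i, j] +
#' u[i, j] * dy` up each column. Because the discrete field is
#' divergence-free, row-wise integration of `-v dx` gives the same values;
#' the maximum discrepancy is reported as `path_error` (relative to the
#' through-flux) and must stay below 1 percent.
#'
#' @param field A [solve_steady_flow()] result.
#' @return An object of class `streamfunction`: node matrix `psi`
#'   ((nx+1) x (ny+1), m^2/s), through-flux `flux` (m^2/s), the
#'   through-flow band `band = c(lo, hi)` and `path_error`.
#' @examples
#' g <- rasterize_layout(standard_layout("A"), nx = 48, ny = 16)
#' f <- solve_stokes(g, boundary_conditions(1e-4))
#' sf <- compute_streamfunction(f)
#' sf$flux
#' @export
compute_streamfunction <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$grid
  nx <- g$nx; ny <- g$ny
  psi <- matrix(0, nx + 1, ny + 1)
  psi[, 2:(ny + 1)] <- t(apply(field$u * g$dy, 1, cumsum))
  # cross-check by row integration of -v dx from the left wall
  psi_row <- matrix(0, nx + 1, ny + 1)
  psi_row[1, ] <- psi[1, ]
  psi_row[2:(nx + 1), ] <- rep(psi[1, ], each = nx) -
    apply(field$v * g$dx, 2, cumsum)
  flux <- if (length(g$inlet_rows)) {
    sum(field$u[1, g$inlet_rows]) * g$dy
  } else 0
  scale <- max(abs(flux), max(abs(psi)), 1e-300)
  path_error <- max(abs(psi - psi_row)) / scale
  if (path_error > 0.01) {
    abort(sprintf(
      "Streamfunction is path-dependent (%.2g relative): field not divergence-free.",
      path_error), class = "eddyrisk_consistency_error")
  }
  structure(
    list(psi = psi, grid = g, flux = flux,
         band = range(0, flux), path_error = path_error),
    class = "streamfunction"
  )
}

#' @export
print.streamfunction <- function(x, ...) {
  cat(sprintf("<streamfunction> flux %.4g m^2/s, path error %.2g\n",
              x$flux, x$path_error))
  invisible(x)
}

# connected-component labels on a logical node matrix (4-connectivity),
# by iterative label minimisation (deterministic, no extra deps)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  repeat {
    new <- lab
    new[-1, ] <- pmin(new[-1, ], ifelse(lab[-nr, ] > 0, lab[-nr, ], Inf))
    new[-nr, ] <- pmin(new[-nr, ], ifelse(lab[-1, ] > 0, lab[-1, ], Inf))
    new[, -1] <- pmin(new[, -1], ifelse(lab[, -nc] > 0, lab[, -nc], Inf))
    new[, -nc] <- pmin(new[, -nc], ifelse(lab[, -1] > 0, lab[, -1], Inf))
    new[!mask] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Detect recirculation zones from streamfunction topology
#'
#' In a 2-D steady flow every streamline either threads from inlet to
#' outlet or closes on itself. Through-flow streamlines carry `psi` values
#' between the base and top wall values, so nodes where `psi` falls
#' outside that open interval belong to closed-streamline pockets
#' (eddies). Marked nodes are segmented by 4-connectivity and each region
#' is labelled by the wall it touches (within one cell of the base/top
#' wall or adjacent to a base/top baffle), its rotation sense and its
#' size, defined as the largest bounding-box extent.
#'
#' @param psi A [compute_streamfunction()] result.
#' @param field Optional originating `flow_field` (unused; accepted for
#'   pipeline symmetry).
#' @param tol Absolute tolerance on `psi` for the band test; default
#'   `1e-6` of the band width (or of `max |psi|` for closed domains).
#' @return A tibble of class `eddy_regions`, one row per region:
#'   `region_id`, `surface` ("base", "top", "interior"), `size_m`,
#'   `size_mm`, `width_mm`, `height_mm`, `sign` (+1 anticlockwise),
#'   `n_nodes`, `psi_extremum`. Zero rows when no eddies exist.
#' @examples
#' g <- rasterize_layout(standard_layout("A"), nx = 48, ny = 16)
#' f <- solve_stokes(g, boundary_conditions(1e-4))
#' detect_recirculation_zones(compute_streamfunction(f))
#' @export
detect_recirculation_zones <- function(psi, field = NULL, tol = NULL) {
  stopifnot(inherits(psi, "streamfunction"))
  g <- psi$grid
  lo <- psi$band[1]; hi <- psi$band[2]
  # tolerance scale: band width, or psi deviation from the band for
  # closed domains; invariant to adding a constant to psi and the band
  scale <- max(hi - lo, max(abs(psi$psi - (lo + hi) / 2)), 1e-300)
  if (is.null(tol)) tol <- 1e-6 * scale
  high <- psi$psi > hi + tol
  low <- psi$psi < lo - tol
  out <- dplyr::bind_rows(
    eddy_regions_from_mask(high, g, +1, psi$psi),
    eddy_regions_from_mask(low, g, -1, psi$psi)
  )
  if (nrow(out)) {
    out <- dplyr::arrange(out, dplyr::desc(.data$size_m))
    out$region_id <- seq_len(nrow(out))
  }
  class(out) <- c("eddy_regions", class(out))
  out
}

eddy_regions_from_mask <- function(mask, g, sign, psi_mat) {
  empty <- tibble(region_id = integer(), surface = character(),
                  size_m = numeric(), size_mm = numeric(),
                  width_mm = numeric(), height_mm = numeric(),
                  sign = numeric(), n_nodes = integer(),
                  psi_extremum = numeric())
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  ids <- sort(unique(lab[lab > 0]))
  nx <- g$nx; ny <- g$ny
  side <- g$solid_side
  purrr::map_dfr(ids, function(id) {
    k <- which(lab == id)
    ii <- ((k - 1L) %% (nx + 1L)) + 1L
    jj <- ((k - 1L) %/% (nx + 1L)) + 1L
    width <- (max(ii) - min(ii)) * g$dx
    height <- (max(jj) - min(jj)) * g$dy
    # wall attachment: node within one cell of a wall, or cornering a
    # baffle cell anchored on that wall
    near <- function(which_side) {
      cells_i <- pmin(pmax(c(ii - 1L, ii), 1L), nx)
      cells_j <- pmin(pmax(c(jj - 1L, jj), 1L), ny)
      any(!is.na(side[cbind(cells_i, cells_j)]) &
            side[cbind(cells_i, cells_j)] == which_side)
    }
    surface <- if (any(jj <= 2L) || near("base")) {
      "base"
    } else if (any(jj >= ny) || near("top")) {
      "top"
    } else {
      "interior"
    }
    ext <- if (sign > 0) max(psi_mat[k]) else min(psi_mat[k])
    tibble(region_id = id, surface = surface,
           size_m = max(width, height), size_mm = max(width, height) * 1e3,
           width_mm = width * 1e3, height_mm = height * 1e3,
           sign = sign, n_nodes = length(k), psi_extremum = ext)
  })
}

#' Largest eddy attached to a surface
#'
#' @param regions A [detect_recirculation_zones()] tibble.
#' @param surface Wall of interest, `"base"` (default) or `"top"`.
#' @return Largest `size_m` among matching regions, in m; 0 if none.
#' @examples
#' measure_largest_eddy(detect_recirculation_zones(
#'   compute_streamfunction(solve_stokes(
#'     rasterize_layout(standard_layout("A"), 48, 16),
#'     boundary_conditions(1e-4)))))
#' @export
measure_largest_eddy <- function(regions, surface = "base") {
  stopifnot(is.data.frame(regions))
  hit <- regions$surface == surface
  if (!any(hit)) return(0)
  max(regions$size_m[hit])
}

#' Wall shear stress profile along the base or top wall
#'
#' Extracts `tau(x) = mu |du/dy|` at the wall from the cell-centred
#' streamwise velocity using a one-sided second-order difference through
#' the wall point: `tau = mu (9 u_1 - u_2) / (3 dy)`, with `u_1`, `u_2`
#' the velocities half a cell and one and a half cells off the wall
#' (exact for a parabolic profile). Columns whose wall-adjacent cell is a
#' baffle footprint are excluded; columns whose second cell is solid fall
#' back to the first-order form.
#'
#' @param field A `flow_field`.
#' @param wall `"base"` (default) or `"top"`.
#' @return A tibble of class `wss_profile` with columns `x_m`, `x_mm`,
#'   `tau_Pa`; summary statistics via [glance()] (`mean_wss`, `max_wss`,
#'   `max_location_m`, `n_nodes`).
#' @examples
#' g <- rasterize_layout(standard_layout("A"), nx = 48, ny = 16)
#' f <- solve_stokes(g, boundary_conditions(1e-4))
#' glance(compute_wall_shear_stress(f))
#' @export
compute_wall_shear_stress <- function(field, wall = c("base", "top")) {
  wall <- match.arg(wall)
  stopifnot(inherits(field, "flow_field"))
  g <- field$grid
  nx <- g$nx; ny <- g$ny
  mu <- field$bc$fluid$dynamic_viscosity
  uc <- 0.5 * (field$u[1:nx, ] + field$u[2:(nx + 1), ])
  if (wall == "base") {
    j1 <- 1L; j2 <- 2L
  } else {
    j1 <- ny; j2 <- ny - 1L
  }
  open <- g$fluid[, j1]
  if (!any(open)) {
    abort("Requested wall is fully covered by solids.",
          class = "eddyrisk_domain_error")
  }
  i <- which(open)
  u1 <- uc[cbind(i, rep(j1, length(i)))]
  second_fluid <- g$fluid[cbind(i, rep(j2, length(i)))]
  u2 <- ifelse(second_fluid, uc[cbind(i, rep(j2, length(i)))], NA_real_)
  tau <- ifelse(second_fluid,
                mu * abs(9 * u1 - u2) / (3 * g$dy),
                mu * abs(2 * u1) / g$dy)
  out <- tibble(x_m = (i - 0.5) * g$dx, x_mm = (i - 0.5) * g$dx * 1e3,
                tau_Pa = tau)
  attr(out, "wall") <- wall
  attr(out, "mu") <- mu
  class(out) <- c("wss_profile", class(out))
  out
}

#' @method glance wss_profile
#' @export
glance.wss_profile <- function(x, ...) {
  tibble(
    wall = attr(x, "wall"),
    mean_wss = mean(x$tau_Pa),
    max_wss = max(x$tau_Pa),
    max_location_m = x$x_m[which.max(x$tau_Pa)],
    n_nodes = nrow(x)
  )
}

#' @method autoplot wss_profile
#' @export
autoplot.wss_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_mm, .data$tau_Pa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (mm)", y = "wall shear stress (Pa)",
                  title = sprintf("Wall shear stress along the %s",
                                  attr(object, "wall")))
}

#' Check a wall-shear profile against damage thresholds
#'
#' @param profile A [compute_wall_shear_stress()] tibble.
#' @param thresholds A [risk_thresholds()] object.
#' @return A one-row tibble: `mean_wss`, `max_wss`, `exceeds_reporting`
#'   (above the 0.1 Pa reporting level), `exceeds_lethal` (3 Pa),
#'   `exceeds_lysis` (5 Pa) and a `wss_verdict` string.
#' @examples
#' g <- rasterize_layout(standard_layout("A"), nx = 48, ny = 16)
#' f <- solve_stokes(g, boundary_conditions(1e-4))
#' threshold_check(compute_wall_shear_stress(f))
#' @export
threshold_check <- function(profile, thresholds = risk_thresholds()) {
  s <- glance(profile)
  tibble(
    mean_wss = s$mean_wss,
    max_wss = s$max_wss,
    exceeds_reporting = s$max_wss > thresholds$reporting_wss,
    exceeds_lethal = s$max_wss > thresholds$lethal_wss,
    exceeds_lysis = s$max_wss > thresholds$lysis_wss,
    wss_verdict = dplyr::case_when(
      s$max_wss > thresholds$lysis_wss ~ "lysis",
      s$max_wss > thresholds$lethal_wss ~ "lethal",
      s$max_wss > thresholds$reporting_wss ~ "elevated",
      TRUE ~ "negligible"
    )
  )
}
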