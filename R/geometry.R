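#' Vessel specification for the 2-D bioreactor slice
#'
#' The flow domain is a 2-D longitudinal slice of a generic cuboidal
#' perfusion vessel: a rectangle with an inlet opening on the left wall and
#' an outlet opening on the right wall. Defaults: 120 mm x 25 mm vessel with
#' 3.31 mm inlet/outlet openings centred at mid-height. The inlet opening
#' equals the characteristic length used in the inlet Reynolds number.
#'
#' @param length,height Vessel dimensions in m.
#' @param inlet_height,outlet_height Opening sizes in m.
#' @param inlet_center_y,outlet_center_y Opening centres in m measured from
#'   the base; default mid-height.
#' @return An object of class `vessel_spec`.
#' @examples
#' vessel_spec()
#' @export
vessel_spec <- function(length = 0.120, height = 0.025,
                        inlet_height = 3.31e-3,
                        inlet_center_y = height / 2,
                        outlet_height = inlet_height,
                        outlet_center_y = inlet_center_y) {
  check_positive(length = length, height = height,
                 inlet_height = inlet_height, outlet_height = outlet_height)
  for (nm in c("inlet", "outlet")) {
    h <- get(paste0(nm, "_height"))
    cy <- get(paste0(nm, "_center_y"))
    if (cy - h / 2 < -1e-12 || cy + h / 2 > height + 1e-12) {
      abort(sprintf("%s opening must lie within [0, height].", nm),
            class = "eddyrisk_geometry_error")
    }
  }
  structure(
    list(length = length, height = height,
         inlet_height = inlet_height, inlet_center_y = inlet_center_y,
         outlet_height = outlet_height, outlet_center_y = outlet_center_y),
    class = "vessel_spec"
  )
}

#' Baffle specification
#'
#' A baffle is a thin rectangular fin anchored on the base or top wall,
#' optionally tilted by 45 degrees about its anchor. Positive angles lean
#' the free tip upstream ("into the flow", the inlet being on the left);
#' negative angles lean it downstream ("away from the flow").
#'
#' @param anchor_x Wall-anchor x position in m.
#' @param side `"base"` or `"top"`.
#' @param height Fin length in m, measured along the fin from the wall.
#' @param angle Tilt in degrees relative to the wall normal; one of
#'   0, 45, -45 in the standard designs (any value in (-80, 80) accepted).
#' @param thickness Fin thickness in m (default 1 mm).
#' @return An object of class `baffle_spec`.
#' @examples
#' baffle_spec(0.03, "base", 4e-3)
#' @export
baffle_spec <- function(anchor_x, side = c("base", "top"), height,
                        angle = 0, thickness = 1e-3) {
  side <- match.arg(side)
  check_positive(anchor_x = anchor_x, height = height, thickness = thickness)
  if (abs(angle) >= 80) {
    abort("`angle` must lie in (-80, 80) degrees.",
          class = "eddyrisk_geometry_error")
  }
  structure(
    list(anchor_x = anchor_x, side = side, height = height,
         angle = angle, thickness = thickness),
    class = "baffle_spec"
  )
}

# Condition labels used in reports, one per standard design letter.
design_condition_labels <- c(
  A = "Unbaffled",
  B = "3 x 2", C = "3 x 4", D = "9 x 2", E = "9 x 4",
  F = "Top 9 x 2", G = "Top 9 x 4",
  H = "Top against flow", I = "Top against flow with gradient",
  J = "Top with flow", K = "Top with flow with gradient"
)

#' Standard baffle layouts A to K
#'
#' Builds one of the eleven standard configurations:
#' A unbaffled; B/C three 2/4 mm base baffles; D/E nine 2/4 mm base
#' baffles; F/G nine 2/4 mm top baffles; H four 4 mm top baffles at +45
#' degrees (into the flow); I one 4 mm then three 8 mm top baffles at +45;
#' J and K mirror H and I at -45 degrees (away from the flow). Baffles are
#' evenly spaced over the central 80 percent of the vessel length.
#'
#' @param design_id A single letter `"A"` to `"K"`.
#' @param vessel A [vessel_spec()].
#' @param thickness Baffle thickness in m.
#' @return An object of class `geometry_layout`: list with `vessel`,
#'   `baffles`, `design_id` and the report `condition` label.
#' @examples
#' standard_layout("E")
#' @export
standard_layout <- function(design_id, vessel = vessel_spec(),
                            thickness = 1e-3) {
  if (!is.character(design_id) || length(design_id) != 1 ||
      !design_id %in% LETTERS[1:11]) {
    abort("`design_id` must be a single letter A..K.",
          class = "eddyrisk_config_error")
  }
  plan <- switch(design_id,
    A = list(n = 0),
    B = list(n = 3, h = 2e-3, side = "base", angle = 0),
    C = list(n = 3, h = 4e-3, side = "base", angle = 0),
    D = list(n = 9, h = 2e-3, side = "base", angle = 0),
    E = list(n = 9, h = 4e-3, side = "base", angle = 0),
    F = list(n = 9, h = 2e-3, side = "top", angle = 0),
    G = list(n = 9, h = 4e-3, side = "top", angle = 0),
    H = list(n = 4, h = 4e-3, side = "top", angle = 45),
    I = list(n = 4, h = c(4e-3, 8e-3, 8e-3, 8e-3), side = "top", angle = 45),
    J = list(n = 4, h = 4e-3, side = "top", angle = -45),
    K = list(n = 4, h = c(4e-3, 8e-3, 8e-3, 8e-3), side = "top", angle = -45)
  )
  baffles <- list()
  if (plan$n > 0) {
    xs <- 0.1 * vessel$length +
      0.8 * vessel$length * seq_len(plan$n) / (plan$n + 1)
    hs <- rep_len(plan$h, plan$n)
    baffles <- purrr::map2(xs, hs, function(x, h) {
      baffle_spec(x, plan$side, h, angle = plan$angle, thickness = thickness)
    })
  }
  geometry_layout(vessel, baffles, design_id = design_id)
}

#' Assemble a geometry layout from vessel and baffles
#'
#' @param vessel A [vessel_spec()].
#' @param baffles A list of [baffle_spec()] objects (possibly empty).
#' @param design_id Optional design letter for bookkeeping.
#' @return An object of class `geometry_layout`.
#' @export
geometry_layout <- function(vessel, baffles = list(), design_id = NA) {
  stopifnot(inherits(vessel, "vessel_spec"))
  for (b in baffles) {
    stopifnot(inherits(b, "baffle_spec"))
    if (b$height >= vessel$height) {
      abort("Baffle height must be smaller than the vessel height.",
            class = "eddyrisk_geometry_error")
    }
    span <- b$height * abs(sinpi(b$angle / 180)) + b$thickness
    if (b$anchor_x - span < 0 || b$anchor_x + span > vessel$length) {
      abort("Baffle extends outside the vessel.",
            class = "eddyrisk_geometry_error")
    }
  }
  if (length(baffles) > 1) {
    xs <- sort(vapply(baffles, `[[`, numeric(1), "anchor_x"))
    if (any(diff(xs) <= max(vapply(baffles, `[[`, numeric(1), "thickness")))) {
      abort("Baffle anchors too close: fins would overlap.",
            class = "eddyrisk_geometry_error")
    }
  }
  structure(
    list(vessel = vessel, baffles = baffles, design_id = design_id,
         condition = if (!is.na(design_id) &&
                         design_id %in% names(design_condition_labels)) {
           design_condition_labels[[design_id]]
         } else {
           sprintf("custom (%d baffles)", length(baffles))
         }),
    class = "geometry_layout"
  )
}

#' @export
print.geometry_layout <- function(x, ...) {
  cat(sprintf("<geometry_layout> %s (%s)\n",
              x$design_id, x$condition))
  cat(sprintf("  vessel %g x %g mm, %d baffle(s)\n",
              x$vessel$length * 1e3, x$vessel$height * 1e3,
              length(x$baffles)))
  invisible(x)
}

# TRUE where points (x, y) fall inside the (possibly tilted) fin rectangle
baffle_contains <- function(baffle, vessel, x, y) {
  th <- baffle$angle / 180
  if (baffle$side == "base") {
    anchor_y <- 0
    zeta_hat <- c(-sinpi(th), cospi(th))
    xi_hat <- c(cospi(th), sinpi(th))
  } else {
    anchor_y <- vessel$height
    zeta_hat <- c(-sinpi(th), -cospi(th))
    xi_hat <- c(cospi(th), -sinpi(th))
  }
  dx <- x - baffle$anchor_x
  dy <- y - anchor_y
  xi <- dx * xi_hat[1] + dy * xi_hat[2]
  zeta <- dx * zeta_hat[1] + dy * zeta_hat[2]
  abs(xi) <= baffle$thickness / 2 & zeta >= 0 & zeta <= baffle$height
}

#' Rasterize a layout onto a flagged structured grid
#'
#' Overlays an `nx` by `ny` Cartesian cell grid on the vessel and flags each
#' cell fluid or solid by cell-centre inclusion in the baffle rectangles
#' (tilted fins are therefore stair-stepped). Left-wall cell rows whose
#' centres fall inside the inlet opening are flagged inlet faces, and
#' likewise outlet rows on the right wall.
#'
#' @param layout A [geometry_layout()].
#' @param nx,ny Cell counts (both >= 16); the grid must resolve the
#'   thinnest baffle with at least 2 cells across its thickness.
#' @return An object of class `flagged_grid`: cell sizes `dx`, `dy`, a
#'   logical `fluid` matrix (nx by ny, column j is the j-th cell row from
#'   the base), a `solid_side` character matrix ("base"/"top" for baffle
#'   cells), and integer vectors `inlet_rows`, `outlet_rows`.
#' @examples
#' g <- rasterize_layout(standard_layout("B"), nx = 240, ny = 50)
#' mean(g$fluid)
#' @export
rasterize_layout <- function(layout, nx = 240, ny = 50) {
  stopifnot(inherits(layout, "geometry_layout"))
  if (nx < 16 || ny < 16) {
    abort("`nx` and `ny` must both be at least 16.",
          class = "eddyrisk_resolution_error")
  }
  v <- layout$vessel
  dx <- v$length / nx
  dy <- v$height / ny
  for (b in layout$baffles) {
    t_eff <- b$thickness / cospi(b$angle / 180)
    if (min(dx, dy) > t_eff / 2 + 1e-12) {
      abort(sprintf(
        paste0("Baffle of thickness %.3g mm under-resolved: need nx >= %d ",
               "and ny >= %d to place 2 cells across it."),
        b$thickness * 1e3,
        ceiling(2 * v$length / t_eff), ceiling(2 * v$height / t_eff)),
        class = "eddyrisk_resolution_error")
    }
  }
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  fluid <- matrix(TRUE, nx, ny)
  solid_side <- matrix(NA_character_, nx, ny)
  for (b in layout$baffles) {
    inside <- baffle_contains(b, v, X, Y)
    fluid[inside] <- FALSE
    solid_side[inside] <- b$side
  }
  inlet_rows <- which(yc > v$inlet_center_y - v$inlet_height / 2 &
                      yc < v$inlet_center_y + v$inlet_height / 2)
  outlet_rows <- which(yc > v$outlet_center_y - v$outlet_height / 2 &
                       yc < v$outlet_center_y + v$outlet_height / 2)
  if (length(inlet_rows) == 0 || length(outlet_rows) == 0) {
    abort("Grid too coarse to resolve the inlet/outlet opening.",
          class = "eddyrisk_resolution_error")
  }
  structure(
    list(nx = nx, ny = ny, dx = dx, dy = dy,
         fluid = fluid, solid_side = solid_side,
         inlet_rows = inlet_rows, outlet_rows = outlet_rows,
         layout = layout),
    class = "flagged_grid"
  )
}

#' @export
print.flagged_grid <- function(x, ...) {
  cat(sprintf("<flagged_grid> %d x %d cells (%.3g x %.3g mm), %s\n",
              x$nx, x$ny, x$dx * 1e3, x$dy * 1e3,
              x$layout$condition))
  cat(sprintf("  fluid fraction %.3f; inlet rows %d..%d; outlet rows %d..%d\n",
              mean(x$fluid), min(x$inlet_rows), max(x$inlet_rows),
              min(x$outlet_rows), max(x$outlet_rows)))
  invisible(x)
}

#' Validate a flagged grid
#'
#' Flood-fills the fluid cells from the inlet and errors if the outlet is
#' unreachable (e.g. a fin blocking the full channel height).
#'
#' @param grid A [rasterize_layout()] result.
#' @return Invisibly, a list with `connected` (TRUE), `fluid_fraction`,
#'   `solid_fraction`, `reachable_fraction` (share of fluid cells reachable
#'   from the inlet) and the open inlet/outlet heights in m.
#' @examples
#' validate_geometry(rasterize_layout(standard_layout("A")))
#' @export
validate_geometry <- function(grid) {
  stopifnot(inherits(grid, "flagged_grid"))
  nx <- grid$nx; ny <- grid$ny
  reach <- matrix(FALSE, nx, ny)
  reach[1, grid$inlet_rows] <- grid$fluid[1, grid$inlet_rows]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ny]
    grown[, -ny] <- grown[, -ny] | reach[, -1]
    grown <- grown & grid$fluid
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (!any(reach[nx, grid$outlet_rows])) {
    abort("Fluid domain is disconnected: no path from inlet to outlet.",
          class = "eddyrisk_geometry_error")
  }
  invisible(list(
    connected = TRUE,
    fluid_fraction = mean(grid$fluid),
    solid_fraction = 1 - mean(grid$fluid),
    reachable_fraction = sum(reach) / sum(grid$fluid),
    inlet_open_height = length(grid$inlet_rows) * grid$dy,
    outlet_open_height = length(grid$outlet_rows) * grid$dy
  ))
}

#' @describeIn rasterize_layout Tile plot of the fluid/solid flags.
#' @param object A `flagged_grid`.
#' @param ... Unused.
#' @method autoplot flagged_grid
#' @export
autoplot.flagged_grid <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(object$nx), j = seq_len(object$ny))
  df$x_mm <- (df$i - 0.5) * object$dx * 1e3
  df$y_mm <- (df$j - 0.5) * object$dy * 1e3
  df$flag <- ifelse(object$fluid[cbind(df$i, df$j)], "fluid", "solid")
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$flag)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(fluid = "grey95",
                                          solid = "grey20")) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = object$layout$condition)
}
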