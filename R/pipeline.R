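#' Run the design-by-flow-rate condition matrix
#'
#' Screens every requested baffle layout at every feed rate: rasterize
#' the geometry, solve the flow (creeping-flow solver at and below
#' `stokes_max_ml_min`, the coupled solver above it), detect and measure
#' the largest base-attached eddy, extract base wall shear stress, and
#' classify eddy-dissipation risk from the measured eddy and the inlet
#' Reynolds number. Solver failures are caught and recorded per
#' condition without aborting the sweep.
#'
#' @param designs Character vector of design letters (subset of A..K).
#' @param flow_rates_ml_min Numeric vector of feed rates in mL/min.
#' @param nx,ny Grid resolution for every condition.
#' @param vessel A [vessel_spec()].
#' @param fluid A [fluid_properties()].
#' @param thresholds A [risk_thresholds()].
#' @param cfg A [solver_config()].
#' @param characteristic_length,inlet_area Passed to [flow_conditions()].
#' @param stokes_max_ml_min Feed rates at or below this use the Stokes
#'   solver (default 0.1, where the inlet Re is 0.27 and creeping flow is
#'   expected).
#' @param verbose Emit one progress line per condition stage.
#' @return A tibble of class `run_manifest`, one row per condition:
#'   identity columns (`design_id`, `condition`, `flow_rate_ml_min`,
#'   `inlet_velocity`, `reynolds`), solver diagnostics (`scheme`,
#'   `iterations`, `converged`, `time_averaged`, `mass_imbalance`),
#'   eddy metrics (`largest_eddy_mm`, `eddy_ratio`, `smallest_eddy_mm`,
#'   `smallest_to_cell_ratio`, `verdict`), base-WSS metrics (`mean_wss_Pa`,
#'   `max_wss_Pa`, `wss_verdict`) and `status` ("ok" or the error).
#' @examples
#' \donttest{
#' m <- run_condition_matrix("A", 1, nx = 60, ny = 16)
#' m$verdict
#' }
#' @export
run_condition_matrix <- function(designs = LETTERS[1:11],
                                 flow_rates_ml_min = c(0.1, 1, 10, 100),
                                 nx = 240, ny = 50,
                                 vessel = vessel_spec(),
                                 fluid = fluid_properties(),
                                 thresholds = risk_thresholds(),
                                 cfg = solver_config(max_iterations = 60),
                                 characteristic_length = 3.31e-3,
                                 inlet_area = pi * 0.003^2,
                                 stokes_max_ml_min = 0.1,
                                 verbose = FALSE) {
  if (length(designs) == 0 || !all(designs %in% LETTERS[1:11])) {
    abort("`designs` must be a non-empty subset of A..K.",
          class = "eddyrisk_config_error")
  }
  if (length(flow_rates_ml_min) == 0) {
    abort("`flow_rates_ml_min` must be non-empty.",
          class = "eddyrisk_config_error")
  }
  conds <- flow_conditions(flow_rates_ml_min, fluid = fluid,
                           characteristic_length = characteristic_length,
                           inlet_area = inlet_area)
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  for (des in designs) {
    grid <- tryCatch({
      g <- rasterize_layout(standard_layout(des, vessel = vessel), nx, ny)
      validate_geometry(g)
      g
    }, error = function(e) e)
    for (k in seq_len(nrow(conds))) {
      cond <- conds[k, ]
      id <- sprintf("%s @ %g mL/min", des, cond$flow_rate_ml_min)
      row <- tibble(
        design_id = des,
        condition = design_condition_labels[[des]],
        flow_rate_ml_min = cond$flow_rate_ml_min,
        inlet_velocity = cond$inlet_velocity,
        reynolds = cond$reynolds,
        scheme = NA_character_, iterations = NA_integer_,
        converged = NA, time_averaged = NA, mass_imbalance = NA_real_,
        largest_eddy_mm = NA_real_, eddy_ratio = NA_real_,
        smallest_eddy_mm = NA_real_, smallest_to_cell_ratio = NA_real_,
        verdict = NA_character_,
        mean_wss_Pa = NA_real_, max_wss_Pa = NA_real_,
        wss_verdict = NA_character_,
        status = "ok"
      )
      res <- tryCatch({
        if (inherits(grid, "error")) stop(conditionMessage(grid))
        use_stokes <- cond$flow_rate_ml_min <= stokes_max_ml_min
        run_cfg <- cfg
        if (use_stokes) run_cfg$scheme <- "stokes_direct"
        say("[%s] solving (%s)", id, run_cfg$scheme)
        f <- withCallingHandlers(
          solve_steady_flow(grid, boundary_conditions(
            cond$inlet_velocity, fluid = fluid), run_cfg),
          warning = function(w) {
            say("[%s] %s", id, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        say("[%s] analysing", id)
        sf <- compute_streamfunction(f)
        regions <- detect_recirculation_zones(sf)
        largest_m <- measure_largest_eddy(regions, "base")
        wss <- compute_wall_shear_stress(f, "base")
        wss_chk <- threshold_check(wss, thresholds)
        g1 <- glance(f)
        row$scheme <- run_cfg$scheme
        row$iterations <- g1$iterations
        row$converged <- g1$converged
        row$time_averaged <- f$report$time_averaged
        row$mass_imbalance <- g1$mass_imbalance
        row$largest_eddy_mm <- largest_m * 1e3
        row$mean_wss_Pa <- wss_chk$mean_wss
        row$max_wss_Pa <- wss_chk$max_wss
        row$wss_verdict <- wss_chk$wss_verdict
        if (largest_m > 0) {
          ra <- assess_risk(reynolds = cond$reynolds,
                            largest_eddy_mm = largest_m * 1e3,
                            thresholds = thresholds)
          row$eddy_ratio <- ra$eddy_ratio
          row$smallest_eddy_mm <- ra$smallest_eddy_mm
          row$smallest_to_cell_ratio <- ra$smallest_to_cell_ratio
          row$verdict <- ra$verdict
        } else {
          # no recirculation at all: nothing to cascade to cell scale
          row$eddy_ratio <- eddy_size_ratio(cond$reynolds)
          row$smallest_eddy_mm <- 0
          row$smallest_to_cell_ratio <- NA_real_
          row$verdict <- "safe"
        }
        say("[%s] done: largest eddy %.2f mm, mean WSS %.3g Pa", id,
            row$largest_eddy_mm, row$mean_wss_Pa)
        row
      }, error = function(e) {
        say("[%s] FAILED: %s", id, conditionMessage(e))
        row$status <- paste("failed:", conditionMessage(e))
        row
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (all(out$status != "ok")) {
    abort("All conditions failed.", class = "eddyrisk_pipeline_error")
  }
  class(out) <- c("run_manifest", class(out))
  out
}

#' Rounded eddy-risk report table
#'
#' Formats assessed eddy observations (a [run_condition_matrix()]
#' manifest or an [assess_risk()] result) as the standard report layout:
#' flow rate, inlet Reynolds number, cascade ratio (2 d.p.), condition,
#' largest eddy (mm, 1 d.p.), smallest eddy (mm, 1 d.p.) and
#' smallest-eddy-to-cell ratio (1 d.p., computed from the unrounded
#' smallest eddy). Full precision stays in the input.
#'
#' @param x A data frame with columns `reynolds`, `largest_eddy_mm`,
#'   `eddy_ratio`, `smallest_eddy_mm`, `smallest_to_cell_ratio` and
#'   optionally `condition` / `flow_rate_ml_min` / `verdict`.
#' @param drop_stokes Drop rows at or below 0.1 mL/min (default TRUE:
#'   creeping-flow conditions shed no measurable eddy cascade and are
#'   reported through the WSS summary instead).
#' @return A tibble with the rounded report columns.
#' @examples
#' eddy_risk_table(assess_risk(reference_eddy_measurements()))
#' @export
eddy_risk_table <- function(x, drop_stokes = TRUE) {
  stopifnot(is.data.frame(x))
  df <- as_tibble(x)
  if (drop_stokes && "flow_rate_ml_min" %in% names(df)) {
    df <- dplyr::filter(df, .data$flow_rate_ml_min > 0.1)
  }
  if (!"condition" %in% names(df)) df$condition <- NA_character_
  if (!"flow_rate_ml_min" %in% names(df)) df$flow_rate_ml_min <- NA_real_
  if (!"verdict" %in% names(df)) df$verdict <- NA_character_
  tibble(
    flow_rate_ml_min = df$flow_rate_ml_min,
    reynolds = df$reynolds,
    eddy_ratio = round(df$eddy_ratio, 2),
    condition = df$condition,
    largest_eddy_mm = round(df$largest_eddy_mm, 1),
    smallest_eddy_mm = round(df$smallest_eddy_mm, 1),
    smallest_to_cell_ratio = round(df$smallest_to_cell_ratio, 1),
    verdict = df$verdict
  )
}

#' Wall-shear-stress summary across the condition matrix
#'
#' Per-condition mean and maximum base WSS against feed rate, for the
#' log-log overview plot, with flags against the reporting (0.1 Pa) and
#' cell-lethal (3 Pa) levels.
#'
#' @param manifest A [run_condition_matrix()] result.
#' @param thresholds A [risk_thresholds()].
#' @return A tibble of class `wss_summary` with `design_id`, `condition`,
#'   `flow_rate_ml_min`, `mean_wss_Pa`, `max_wss_Pa`,
#'   `above_reporting`, `above_lethal`.
#' @examples
#' \donttest{
#' m <- run_condition_matrix("A", 1, nx = 60, ny = 16)
#' wss_summary(m)
#' }
#' @export
wss_summary <- function(manifest, thresholds = risk_thresholds()) {
  stopifnot(is.data.frame(manifest))
  ok <- dplyr::filter(as_tibble(manifest), .data$status == "ok")
  out <- dplyr::transmute(
    ok,
    design_id = .data$design_id,
    condition = .data$condition,
    flow_rate_ml_min = .data$flow_rate_ml_min,
    mean_wss_Pa = .data$mean_wss_Pa,
    max_wss_Pa = .data$max_wss_Pa,
    above_reporting = .data$max_wss_Pa > thresholds$reporting_wss,
    above_lethal = .data$max_wss_Pa > thresholds$lethal_wss
  )
  class(out) <- c("wss_summary", class(out))
  out
}

#' @method autoplot wss_summary
#' @param object A `wss_summary`.
#' @param ... Unused.
#' @rdname wss_summary
#' @export
autoplot.wss_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$flow_rate_ml_min, .data$mean_wss_Pa,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.1, 3), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "flow rate (mL/min)", y = "mean base WSS (Pa)",
                  title = "Mean wall shear stress vs feed rate",
                  subtitle = "Dashed: 0.1 Pa reporting and 3 Pa lethal levels")
}

#' Standalone risk table from an eddy-observation CSV
#'
#' Applies the cascade risk model to externally measured largest-eddy
#' sizes without running the solver, reproducing the full report table
#' from its printed inputs.
#'
#' @param path CSV with columns `reynolds`, `largest_eddy_mm` (see
#'   [read_eddy_csv()]).
#' @param thresholds A [risk_thresholds()].
#' @param drop_stokes Passed to [eddy_risk_table()].
#' @return The rounded report tibble.
#' @examples
#' p <- system.file("extdata", "reference_eddies.csv", package = "eddyrisk")
#' run_risk_only(p)
#' @export
run_risk_only <- function(path, thresholds = risk_thresholds(),
                          drop_stokes = TRUE) {
  eddy_risk_table(assess_risk(read_eddy_csv(path), thresholds = thresholds),
                  drop_stokes = drop_stokes)
}
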