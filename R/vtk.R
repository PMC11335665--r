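#' Export fields as legacy VTK structured points
#'
#' Writes cell-centred velocity, pressure and the fluid/solid flag of a
#' flow field (or just the flag of a grid) as an ASCII legacy-VTK
#' STRUCTURED_POINTS dataset, readable by ParaView and friends.
#'
#' @param x A `flow_field` or `flagged_grid`.
#' @param path Output file path (conventionally `.vtk`).
#' @return Invisibly, `path`.
#' @examples
#' g <- rasterize_layout(standard_layout("A"), 48, 16)
#' write_vtk(g, tempfile(fileext = ".vtk"))
#' @export
write_vtk <- function(x, path) {
  UseMethod("write_vtk")
}

vtk_header <- function(grid, title) {
  c("# vtk DataFile Version 3.0", title, "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
    sprintf("ORIGIN %g %g 0", grid$dx / 2, grid$dy / 2),
    sprintf("SPACING %g %g 1", grid$dx, grid$dy),
    sprintf("POINT_DATA %d", grid$nx * grid$ny))
}

vtk_scalar <- function(name, values) {
  c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
    format(values, digits = 9, scientific = TRUE, trim = TRUE))
}

#' @rdname write_vtk
#' @export
write_vtk.flagged_grid <- function(x, path) {
  lines <- c(vtk_header(x, "eddyrisk geometry flags"),
             vtk_scalar("solid", as.numeric(!x$fluid)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vtk
#' @export
write_vtk.flow_field <- function(x, path) {
  g <- x$grid
  nx <- g$nx; ny <- g$ny
  uc <- 0.5 * (x$u[1:nx, ] + x$u[2:(nx + 1), ])
  vc <- 0.5 * (x$v[, 1:ny] + x$v[, 2:(ny + 1)])
  p <- x$p
  p[is.na(p)] <- 0
  lines <- c(vtk_header(g, "eddyrisk flow field"),
             vtk_scalar("u", as.numeric(uc)),
             vtk_scalar("v", as.numeric(vc)),
             vtk_scalar("p", as.numeric(p)),
             vtk_scalar("solid", as.numeric(!g$fluid)))
  writeLines(lines, path)
  invisible(path)
}
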