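#' Define an evaluation grid
#'
#' Axis-aligned sampling grid in the z < 0 half-space.  Each axis argument is
#' either a scalar (the plane's fixed coordinate) or a length-2 range that is
#' sampled at `step_mm`.  A plane has exactly two ranged axes; three ranged
#' axes define a volume (area metrics are only defined on planes).
#'
#' The default is the focal plane used throughout: z = -50 mm,
#' x and y in \[-37.5, 37.5\] mm at 0.25 mm step (75 mm x 75 mm water body,
#' 0.0625 mm^2 per cell).
#'
#' @param x_mm,y_mm,z_mm Scalar coordinate or `c(min, max)` range, mm.
#' @param step_mm Grid step, mm (> 0).
#' @return A list of class `tmaes_grid` with the per-axis sample vectors,
#'   the step, the names of the ranged ("plane") axes and a `points` tibble
#'   (`x_mm`, `y_mm`, `z_mm`) in row-major axis order.
#' @examples
#' g <- field_grid(step_mm = 0.5)
#' nrow(g$points)
#' @export
field_grid <- function(x_mm = c(-37.5, 37.5), y_mm = c(-37.5, 37.5),
                       z_mm = -50, step_mm = 0.25) {
  if (step_mm <= 0) abort("`step_mm` must be > 0.", class = "tmaes_config_error")
  axis_seq <- function(v, nm) {
    if (length(v) == 1) return(v)
    if (length(v) != 2 || v[2] <= v[1]) {
      abort(sprintf("`%s` must be a scalar or an increasing c(min, max).", nm),
            class = "tmaes_config_error")
    }
    seq(v[1], v[2], by = step_mm)
  }
  ax <- list(
    x_mm = axis_seq(x_mm, "x_mm"),
    y_mm = axis_seq(y_mm, "y_mm"),
    z_mm = axis_seq(z_mm, "z_mm")
  )
  plane_axes <- names(ax)[vapply(ax, length, 1L) > 1L]
  if (length(plane_axes) < 2) {
    abort("Grid must extend over at least two axes.",
          class = "tmaes_config_error")
  }
  if (max(ax$z_mm) >= 0) {
    abort("Evaluation grid must lie strictly in the z < 0 half-space.",
          class = "tmaes_config_error")
  }
  points <- tidyr::expand_grid(x_mm = ax$x_mm, y_mm = ax$y_mm, z_mm = ax$z_mm)
  structure(
    list(x_mm = ax$x_mm, y_mm = ax$y_mm, z_mm = ax$z_mm,
         step_mm = step_mm, plane_axes = plane_axes, points = points),
    class = "tmaes_grid"
  )
}

#' @export
print.tmaes_grid <- function(x, ...) {
  dims <- paste(vapply(x[c("x_mm", "y_mm", "z_mm")], length, 1L),
                collapse = " x ")
  cat("<tmaes_grid> ", dims, " samples, step ", x$step_mm, " mm (",
      if (length(x$plane_axes) == 2) "plane" else "volume", ")\n", sep = "")
  invisible(x)
}

# Internal: wrap solver output as a sampled field object.
new_field <- function(grid, amplitude, kind, units, frequency_khz = NA_real_) {
  out <- dplyr::mutate(grid$points, amplitude = amplitude)
  structure(out,
            class = c("tmaes_field", class(out)),
            grid = grid[c("x_mm", "y_mm", "z_mm", "step_mm", "plane_axes")],
            kind = kind, units = units, frequency_khz = frequency_khz)
}

field_attrs <- function(field) {
  attributes(field)[c("grid", "kind", "units", "frequency_khz")]
}

#' @export
print.tmaes_field <- function(x, ...) {
  cat(sprintf("<tmaes_field> %s [%s], %d samples, step %g mm, peak %.4g %s\n",
              attr(x, "kind"), attr(x, "units"), nrow(x),
              attr(x, "grid")$step_mm, max(Mod(x$amplitude)),
              attr(x, "units")))
  NextMethod()
}
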