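#' Tidy a sampled field
#'
#' @param x A `tmaes_field`.
#' @param ... Unused.
#' @return A tibble with `x_mm`, `y_mm`, `z_mm`, `re`, `im`, `abs`.
#' @export
tidy.tmaes_field <- function(x, ...) {
  tibble(x_mm = x$x_mm, y_mm = x$y_mm, z_mm = x$z_mm,
         re = Re(x$amplitude), im = Im(x$amplitude),
         abs = Mod(x$amplitude))
}

#' @rdname tidy.tmaes_field
#' @export
glance.tmaes_field <- function(x, ...) {
  tibble(kind = attr(x, "kind"), units = attr(x, "units"),
         frequency_khz = attr(x, "frequency_khz"),
         n_samples = nrow(x), step_mm = attr(x, "grid")$step_mm,
         peak = max(Mod(x$amplitude)))
}

#' Tidy a focal region
#'
#' @param x A `tmaes_region`.
#' @param ... Unused.
#' @return The per-component tibble (cell counts, areas, peaks).
#' @export
tidy.tmaes_region <- function(x, ...) {
  x$components
}

#' @rdname tidy.tmaes_region
#' @export
glance.tmaes_region <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         total_area_mm2 = sum(x$components$area_mm2),
         threshold = x$threshold, peak_value = x$peak_value,
         drop_db = x$drop_db, step_mm = x$step_mm)
}

#' Tidy a focal-metrics report
#'
#' @param x A `tmaes_metrics` object.
#' @param ... Unused.
#' @return The per-target metrics tibble.
#' @export
tidy.tmaes_metrics <- function(x, ...) {
  x$per_target
}

#' @rdname tidy.tmaes_metrics
#' @export
glance.tmaes_metrics <- function(x, ...) {
  tibble(kind = x$kind, units = x$units, peak_value = x$peak_value,
         threshold = x$threshold, n_components = x$n_components,
         total_area_mm2 = x$total_area_mm2,
         n_side_lobes = nrow(x$side_lobes))
}

#' Tidy a scenario run
#'
#' @param x A `tmaes_scenario`.
#' @param ... Unused.
#' @return Per-target electric-field metrics with a `scenario` column.
#' @export
tidy.tmaes_scenario <- function(x, ...) {
  dplyr::mutate(x$metrics$efield$per_target,
                scenario = x$config$scenario, .before = 1)
}

#' @rdname tidy.tmaes_scenario
#' @export
glance.tmaes_scenario <- function(x, ...) {
  tibble(
    scenario = x$config$scenario,
    frequency_khz = x$config$array$frequency_khz,
    b_tesla = x$config$magnetic_field$b_tesla,
    peak_pressure = x$metrics$pressure$peak_value,
    peak_efield = x$metrics$efield$peak_value,
    total_area_mm2 = x$metrics$efield$total_area_mm2,
    n_components = x$metrics$efield$n_components,
    R = if (!is.null(x$separation)) x$separation$R else NA_real_
  )
}
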