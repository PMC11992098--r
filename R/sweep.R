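#' Frequency sweep of a multi-target scenario
#'
#' Re-runs the full pipeline at each requested frequency (the delay law
#' depends only on geometry and sound speed, so it is shared) and tabulates
#' the separation metrics of the normalised electric field: per-target
#' x-axis focusing length (the -3 dB extent along the y = 0 profile), the
#' distance between the two main peaks, the total -3 dB area and the
#' separation index R.  Rows where the -3 dB region has a single connected
#' component are flagged `separated = FALSE` (with `NA` peak distance).
#'
#' @param config A `tmaes_config`, list or YAML path.  If `frequencies_khz`
#'   is `NULL` the config's `sweep$frequencies_khz` is used.
#' @param frequencies_khz Frequencies to simulate, kHz.
#' @return A tibble of class `tmaes_sweep`, one row per frequency:
#'   `frequency_khz`, one `x_len_<label>_mm` column per target,
#'   `peak_distance_mm`, `total_area_mm2`, `R`, `separated`.
#' @export
frequency_sweep <- function(config, frequencies_khz = NULL) {
  cfg <- as_simulation_config(config)
  frequencies_khz <- frequencies_khz %||% cfg$sweep$frequencies_khz
  if (is.null(frequencies_khz) || length(frequencies_khz) < 1) {
    abort("No sweep frequencies given.", class = "tmaes_config_error")
  }
  labels <- vapply(seq_along(cfg$targets),
                   function(i) cfg$targets[[i]]$label %||% paste0("t", i), "")
  rows <- purrr::map_dfr(frequencies_khz, function(f) {
    cfg_f <- unclass(cfg)
    cfg_f$array$frequency_khz <- f
    cfg_f$scenario <- sprintf("%s@%gkHz", cfg$scenario, f)
    cfg_f$digest <- NULL
    cfg_f$defaults_applied <- NULL
    cfg_f$sweep <- NULL
    res <- run_scenario(cfg_f)
    ef <- res$fields$efield
    # normalise per frequency; all metrics are scale-invariant anyway
    ef <- scale_field(ef, 1 / max(Mod(ef$amplitude)))
    region <- threshold_mask(ef)
    ax_u <- attr(ef, "grid")$plane_axes[1]
    prof <- field_profile(ef, along = ax_u, at = 0)
    ext <- profile_extents(prof, threshold = region$threshold)
    tg_u <- vapply(cfg$targets, function(t) t[[ax_u]] %||% 0, 1)
    x_len <- vapply(seq_along(tg_u), function(j) {
      if (nrow(ext) == 0) return(NA_real_)
      ext$length_mm[which.min(abs(ext$peak_mm - tg_u[j]))]
    }, 1)
    pd <- tryCatch(peak_distance(region),
                   tmaes_not_separated = function(e) NA_real_)
    r_idx <- tryCatch(separation_index(prof)$R, error = function(e) NA_real_)
    out <- tibble(frequency_khz = f)
    for (j in seq_along(labels)) {
      out[[paste0("x_len_", labels[j], "_mm")]] <- x_len[j]
    }
    out$peak_distance_mm <- pd
    out$total_area_mm2 <- sum(region$components$area_mm2)
    out$R <- r_idx
    out$separated <- !is.na(pd)
    out
  })
  structure(rows, class = c("tmaes_sweep", class(rows)),
            sweep_param = "frequency_khz", scenario = cfg$scenario)
}

#' Magnetic-field sweep of a scenario
#'
#' The induced electric field is linear in B for fixed acoustics, so the
#' scenario is simulated once at a reference B and the peak is rescaled to
#' each requested magnitude; -3 dB masks and areas are B-invariant.
#'
#' @param config A `tmaes_config`, list or YAML path.  If `b_tesla` is
#'   `NULL` the config's `sweep$b_tesla_values` is used.
#' @param b_tesla Magnetic field magnitudes, Tesla.
#' @return A tibble of class `tmaes_sweep`: `b_tesla`, `peak_e_v_per_m`,
#'   `total_area_mm2`.
#' @export
b_sweep <- function(config, b_tesla = NULL) {
  cfg <- as_simulation_config(config)
  b_tesla <- b_tesla %||% cfg$sweep$b_tesla_values
  if (is.null(b_tesla) || length(b_tesla) < 1) {
    abort("No sweep B values given.", class = "tmaes_config_error")
  }
  b_ref <- cfg$magnetic_field$b_tesla
  cfg_run <- unclass(cfg)
  cfg_run$sweep <- NULL
  cfg_run$digest <- NULL
  cfg_run$defaults_applied <- NULL
  res <- run_scenario(cfg_run)
  e_ref <- res$metrics$efield$peak_value
  area <- res$metrics$efield$total_area_mm2
  out <- tibble(
    b_tesla = b_tesla,
    peak_e_v_per_m = scale_efield_with_b(e_ref, b_ref, b_tesla),
    total_area_mm2 = area
  )
  structure(out, class = c("tmaes_sweep", class(out)),
            sweep_param = "b_tesla", scenario = cfg$scenario)
}

#' Write a sweep table as CSV
#'
#' @param sweep A [frequency_sweep()] or [b_sweep()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sweep <- function(sweep, path) {
  readr::write_csv(as_tibble(sweep), path)
  invisible(path)
}
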