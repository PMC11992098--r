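#' Load and validate a simulation configuration
#'
#' Reads a YAML scenario file into a validated `tmaes_config`.  Keys carry
#' explicit unit suffixes (`pitch_mm`, `b_tesla`, ...); unknown keys and
#' invalid geometry raise descriptive configuration errors, and every
#' omitted optional key is filled from the documented default and recorded
#' in `defaults_applied`.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `tmaes_config`.
#' @seealso [make_fixtures()] for ready-made scenario files,
#'   [run_scenario()] to execute one.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "tmaes_config_error")
  }
  as_simulation_config(yaml::read_yaml(path))
}

config_defaults <- function() {
  list(
    scenario = "unnamed",
    array = list(rows = 8L, cols = 8L, pitch_mm = 4.5, kerf_mm = 0.2,
                 frequency_khz = 500),
    medium = list(density_kg_m3 = 1000, sound_speed_m_s = 1500,
                  conductivity_s_m = 0.5, attenuation_np_m = 0),
    magnetic_field = list(kind = "uniform", b_tesla = 0.5,
                          direction = c(0, 1, 0)),
    assignment = list(strategy = "block"),
    grid = list(x_mm = c(-37.5, 37.5), y_mm = c(-37.5, 37.5), z_mm = -50,
                step_mm = 0.25),
    solver = list(subsource_spacing_fraction = 0.25),
    drive = list(amplitude = 1, calibrate_peak_pa = NULL)
  )
}

check_keys <- function(x, allowed, section) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown key(s) in `%s`: %s", section,
                  paste(extra, collapse = ", ")),
          class = "tmaes_config_error")
  }
}

#' Normalise a configuration list
#'
#' Accepts a path, a raw list (as read from YAML) or an existing
#' `tmaes_config` and returns a fully validated `tmaes_config` with
#' defaults applied and a content digest.
#'
#' @param x Path, list or `tmaes_config`.
#' @return A `tmaes_config`.
#' @export
as_simulation_config <- function(x) {
  if (inherits(x, "tmaes_config")) return(x)
  if (is.character(x) && length(x) == 1) return(load_config(x))
  if (!is.list(x)) {
    abort("Config must be a file path or a named list.",
          class = "tmaes_config_error")
  }
  check_keys(x, c("scenario", "array", "medium", "magnetic_field", "targets",
                  "assignment", "grid", "solver", "drive", "sweep"),
             "config")
  if (is.null(x$targets) || length(x$targets) == 0) {
    abort("Config must list at least one target.", class = "tmaes_config_error")
  }
  check_keys(x$array %||% list(),
             c("rows", "cols", "pitch_mm", "kerf_mm", "frequency_khz"),
             "array")
  check_keys(x$medium %||% list(),
             c("density_kg_m3", "sound_speed_m_s", "conductivity_s_m",
               "attenuation_np_m"), "medium")
  check_keys(x$magnetic_field %||% list(),
             c("kind", "b_tesla", "direction", "anchors"), "magnetic_field")
  check_keys(x$assignment %||% list(), c("strategy", "counts", "mapping"),
             "assignment")
  check_keys(x$grid %||% list(), c("x_mm", "y_mm", "z_mm", "step_mm"), "grid")
  check_keys(x$solver %||% list(), "subsource_spacing_fraction", "solver")
  check_keys(x$drive %||% list(), c("amplitude", "calibrate_peak_pa"),
             "drive")
  check_keys(x$sweep %||% list(), c("frequencies_khz", "b_tesla_values"),
             "sweep")
  for (i in seq_along(x$targets)) {
    check_keys(x$targets[[i]], c("label", "x_mm", "y_mm", "z_mm"),
               sprintf("targets[%d]", i))
  }

  defaults <- config_defaults()
  applied <- character(0)
  cfg <- defaults
  for (sec in names(defaults)) {
    if (is.null(x[[sec]])) {
      applied <- c(applied, sec)
    } else if (is.list(defaults[[sec]])) {
      applied <- c(applied,
                   paste(sec, setdiff(names(defaults[[sec]]),
                                      names(x[[sec]])), sep = "."))
      cfg[[sec]] <- modifyList(defaults[[sec]], x[[sec]])
    } else {
      cfg[[sec]] <- x[[sec]]
    }
  }
  cfg$targets <- x$targets
  cfg$sweep <- x$sweep
  applied <- applied[!endsWith(applied, ".")]

  a <- cfg$array
  if (a$kerf_mm >= a$pitch_mm || a$pitch_mm <= 0) {
    abort(paste0("Invalid array geometry: need `kerf_mm` < `pitch_mm` and ",
                 "`pitch_mm` > 0 (got kerf_mm = ", a$kerf_mm,
                 ", pitch_mm = ", a$pitch_mm, ")."),
          class = "tmaes_config_error")
  }
  # constructing the objects validates everything else
  objs <- config_objects(cfg)
  cfg$defaults_applied <- sort(applied)
  cfg$digest <- rlang::hash(cfg[c("scenario", "array", "medium",
                                  "magnetic_field", "targets", "assignment",
                                  "grid", "solver", "drive")])
  structure(cfg, class = "tmaes_config")
}

# Internal: instantiate the domain objects described by a config list.
config_objects <- function(cfg) {
  arr <- build_planar_array(cfg$array$rows, cfg$array$cols,
                            pitch_mm = cfg$array$pitch_mm,
                            kerf_mm = cfg$array$kerf_mm,
                            frequency_khz = cfg$array$frequency_khz)
  tg <- focus_targets(
    x_mm = vapply(cfg$targets, function(t) t$x_mm %||% 0, 1),
    y_mm = vapply(cfg$targets, function(t) t$y_mm %||% 0, 1),
    z_mm = vapply(cfg$targets, function(t) t$z_mm %||% -50, 1),
    label = vapply(seq_along(cfg$targets),
                   function(i) cfg$targets[[i]]$label %||% paste0("t", i),
                   "")
  )
  asg <- assign_elements(arr, tg, strategy = cfg$assignment$strategy,
                         counts = cfg$assignment$counts,
                         mapping = cfg$assignment$mapping)
  med <- medium(density = cfg$medium$density_kg_m3,
                sound_speed = cfg$medium$sound_speed_m_s,
                conductivity = cfg$medium$conductivity_s_m,
                attenuation = cfg$medium$attenuation_np_m)
  bf <- if (identical(cfg$magnetic_field$kind, "distance-profile")) {
    magnetic_field_profile(
      distance_mm = vapply(cfg$magnetic_field$anchors,
                           function(a) a$distance_mm, 1),
      b_tesla = vapply(cfg$magnetic_field$anchors, function(a) a$b_tesla, 1))
  } else {
    magnetic_field_uniform(cfg$magnetic_field$b_tesla,
                           direction = unlist(cfg$magnetic_field$direction))
  }
  grd <- field_grid(x_mm = unlist(cfg$grid$x_mm),
                    y_mm = unlist(cfg$grid$y_mm),
                    z_mm = unlist(cfg$grid$z_mm),
                    step_mm = cfg$grid$step_mm)
  list(array = arr, targets = tg, assignment = asg, medium = med,
       bfield = bf, grid = grd)
}

#' @export
print.tmaes_config <- function(x, ...) {
  cat(sprintf(
    "<tmaes_config> '%s': %dx%d array @ %g kHz, %d target(s), digest %s\n",
    x$scenario, x$array$rows, x$array$cols, x$array$frequency_khz,
    length(x$targets), substr(x$digest, 1, 8)))
  invisible(x)
}

#' Run a full simulation scenario
#'
#' Deterministic pipeline: delay law, steady-state pressure field, optional
#' amplitude calibration, magneto-acoustic coupling fields (particle
#' velocity, electric field, current density) and focal metrics.  Identical
#' configurations give byte-identical reports.
#'
#' @param config A `tmaes_config`, config list or YAML path.
#' @return A list of class `tmaes_scenario`: `config`, `delay_law`,
#'   `fields` (`pressure`, `velocity`, `efield`, `current`), `metrics`
#'   (focal metrics of pressure and efield), `separation` (for >= 2
#'   targets), and `report` (a JSON metrics report string).
#' @examples
#' \donttest{
#' cfg_files <- make_fixtures(tempdir())
#' res <- run_scenario(cfg_files[["dual_symmetric"]])
#' res$metrics$efield$total_area_mm2
#' }
#' @export
run_scenario <- function(config) {
  cfg <- as_simulation_config(config)
  obj <- config_objects(cfg)

  stage <- "delay_law"
  res <- tryCatch({
    dl <- compute_delay_law(obj$array, obj$targets, obj$assignment,
                            c0 = obj$medium$sound_speed)
    stage <- "acoustic_solver"
    p <- pressure_field(obj$array, dl, obj$medium, obj$grid,
                        source_amplitude = cfg$drive$amplitude,
                        spacing_fraction = cfg$solver$subsource_spacing_fraction)
    calibrated <- FALSE
    if (!is.null(cfg$drive$calibrate_peak_pa)) {
      p <- scale_field(p, calibrate_amplitude(p, cfg$drive$calibrate_peak_pa))
      calibrated <- TRUE
    }
    stage <- "magnetoacoustic_coupling"
    vf <- particle_velocity(p, obj$medium)
    ef <- efield_from_pressure(p, obj$bfield, obj$medium)
    jf <- current_density(vf, obj$bfield, obj$medium)
    stage <- "focal_metrics"
    mp <- focal_metrics(p, obj$targets)
    me <- focal_metrics(ef, obj$targets)
    sep <- NULL
    if (nrow(obj$targets) >= 2 && length(attr(ef, "grid")$plane_axes) == 2) {
      ax <- attr(ef, "grid")$plane_axes[1]
      sep <- tryCatch(
        separation_index(field_profile(ef, along = ax, at = 0)),
        error = function(e) NULL)
    }
    list(delay_law = dl, pressure = p, velocity = vf, efield = ef,
         current = jf, metrics_p = mp, metrics_e = me, separation = sep,
         calibrated = calibrated)
  }, tmaes_config_error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
          class = "tmaes_config_error")
  }, tmaes_numeric_error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)),
          class = "tmaes_numeric_error")
  })

  report <- metrics_report(cfg, res)
  structure(
    list(config = cfg, delay_law = res$delay_law,
         fields = list(pressure = res$pressure, velocity = res$velocity,
                       efield = res$efield, current = res$current),
         metrics = list(pressure = res$metrics_p, efield = res$metrics_e),
         separation = res$separation,
         report = report),
    class = "tmaes_scenario"
  )
}

#' @export
print.tmaes_scenario <- function(x, ...) {
  cat(sprintf("<tmaes_scenario> '%s'\n", x$config$scenario))
  print(x$metrics$efield)
  invisible(x)
}

# Internal: deterministic JSON metrics report.
metrics_report <- function(cfg, res) {
  per_target_list <- function(m) {
    lapply(seq_len(nrow(m$per_target)), function(i) as.list(m$per_target[i, ]))
  }
  rep <- list(
    scenario = cfg$scenario,
    config_digest = cfg$digest,
    solver = list(
      subsource_spacing_fraction = cfg$solver$subsource_spacing_fraction,
      grid_step_mm = cfg$grid$step_mm
    ),
    calibration = if (res$calibrated) {
      sprintf("absolute pressures matched to reference peak %g Pa",
              cfg$drive$calibrate_peak_pa)
    } else {
      "uncalibrated: amplitudes on an arbitrary linear drive scale"
    },
    defaults_applied = cfg$defaults_applied,
    pressure = list(units = "Pa", peak = res$metrics_p$peak_value,
                    total_area_mm2 = res$metrics_p$total_area_mm2,
                    n_components = res$metrics_p$n_components,
                    per_target = per_target_list(res$metrics_p)),
    efield = list(units = "V/m", peak = res$metrics_e$peak_value,
                  total_area_mm2 = res$metrics_e$total_area_mm2,
                  n_components = res$metrics_e$n_components,
                  per_target = per_target_list(res$metrics_e)),
    separation = if (!is.null(res$separation)) as.list(res$separation)
  )
  as.character(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE, null = "null"))
}

unit_token <- function(units) {
  c("Pa" = "Pa", "V/m" = "V_per_m", "m/s" = "m_per_s",
    "A/m^2" = "A_per_m2")[[units]] %||% gsub("[/^]", "_", units)
}

#' Export a sampled field
#'
#' `format = "csv"` writes flat text with unit-suffixed headers
#' (`x_mm, y_mm, z_mm, re_<unit>, im_<unit>, abs_<unit>`); `format = "rds"`
#' writes the structured-grid object (axes, step, complex values, units) as
#' a binary container.  [read_field()] round-trips both.
#'
#' @param field A `tmaes_field`.
#' @param path Output path.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
export_field <- function(field, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(field = as_tibble(field), attrs = field_attrs(field)), path)
    return(invisible(path))
  }
  tok <- unit_token(attr(field, "units"))
  out <- tibble(
    x_mm = field$x_mm, y_mm = field$y_mm, z_mm = field$z_mm,
    re = Re(field$amplitude), im = Im(field$amplitude),
    abs = Mod(field$amplitude)
  )
  names(out)[4:6] <- paste(c("re", "im", "abs"), tok, sep = "_")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a field exported by [export_field()]
#'
#' @param path File path (`.rds` or `.csv`).
#' @return A `tmaes_field`.
#' @export
read_field <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    f <- obj$field
    attributes(f) <- c(attributes(f), obj$attrs)
    class(f) <- c("tmaes_field", class(obj$field))
    return(f)
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  re_col <- grep("^re_", names(df), value = TRUE)
  im_col <- grep("^im_", names(df), value = TRUE)
  tok <- sub("^re_", "", re_col)
  units <- names(which(vapply(c("Pa", "V/m", "m/s", "A/m^2"), unit_token,
                              "") == tok))
  as_field(tibble(x_mm = df$x_mm, y_mm = df$y_mm, z_mm = df$z_mm,
                  value = complex(real = df[[re_col]],
                                  imaginary = df[[im_col]])),
           units = if (length(units)) units else tok, kind = "imported")
}

#' Coerce a tabular grid scan to a field object
#'
#' Builds a `tmaes_field` from a data frame of samples on a regular plane
#' grid, e.g. a measured hydrophone/electrode scan with columns
#' `x_mm, y_mm, value`.
#'
#' @param df Data frame with `x_mm`, `y_mm`, optional `z_mm`, and a `value`
#'   column (real or complex).
#' @param units Unit string for the values.
#' @param kind Field kind label.
#' @param z_mm Plane depth used when `df` has no `z_mm` column, mm.
#' @return A `tmaes_field`.
#' @export
as_field <- function(df, units = "a.u.", kind = "scan", z_mm = -50) {
  stopifnot(all(c("x_mm", "y_mm", "value") %in% names(df)))
  if (!"z_mm" %in% names(df)) df$z_mm <- z_mm
  xs <- sort(unique(df$x_mm))
  ys <- sort(unique(df$y_mm))
  zs <- sort(unique(df$z_mm))
  steps <- c(diff(xs), diff(ys))
  steps <- steps[steps > 0]
  step <- stats::median(steps)
  if (length(steps) && any(abs(steps - step) > 1e-6 * max(1, step))) {
    abort("Samples are not on a regular grid.", class = "tmaes_config_error")
  }
  plane_axes <- c("x_mm", "y_mm", "z_mm")[c(length(xs), length(ys),
                                            length(zs)) > 1]
  out <- tibble(x_mm = df$x_mm, y_mm = df$y_mm, z_mm = df$z_mm,
                amplitude = as.complex(df$value))
  structure(out,
            class = c("tmaes_field", class(out)),
            grid = list(x_mm = xs, y_mm = ys, z_mm = zs, step_mm = step,
                        plane_axes = plane_axes),
            kind = kind, units = units, frequency_khz = NA_real_)
}

#' Write the scenario fixture files
#'
#' Emits the YAML configuration for each studied scenario family:
#' `single_center`, `dual_symmetric`, `quad` (0.5 T), `quad_b07` (0.7 T),
#' `dual_asymmetric_32_16`, `frequency_sweep` (300-700 kHz) and `b_sweep`
#' (0.2/0.3/0.5 T).
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- list(
    array = list(rows = 8L, cols = 8L, pitch_mm = 4.5, kerf_mm = 0.2,
                 frequency_khz = 500),
    medium = list(density_kg_m3 = 1000, sound_speed_m_s = 1500,
                  conductivity_s_m = 0.5, attenuation_np_m = 0),
    magnetic_field = list(kind = "uniform", b_tesla = 0.5),
    assignment = list(strategy = "block"),
    grid = list(x_mm = c(-37.5, 37.5), y_mm = c(-37.5, 37.5), z_mm = -50,
                step_mm = 0.25),
    solver = list(subsource_spacing_fraction = 0.25),
    drive = list(amplitude = 1)
  )
  tg <- function(x, y, lab) list(label = lab, x_mm = x, y_mm = y, z_mm = -50)
  scenarios <- list(
    single_center = modifyList(base, list(
      scenario = "single_center",
      targets = list(tg(0, 0, "center")))),
    dual_symmetric = modifyList(base, list(
      scenario = "dual_symmetric",
      targets = list(tg(-9, 0, "left"), tg(9, 0, "right")))),
    quad = modifyList(base, list(
      scenario = "quad",
      targets = list(tg(-9, 9, "q1"), tg(9, 9, "q2"),
                     tg(9, -9, "q3"), tg(-9, -9, "q4")))),
    quad_b07 = modifyList(base, list(
      scenario = "quad_b07",
      magnetic_field = list(kind = "uniform", b_tesla = 0.7),
      targets = list(tg(-9, 9, "q1"), tg(9, 9, "q2"),
                     tg(9, -9, "q3"), tg(-9, -9, "q4")))),
    dual_asymmetric_32_16 = modifyList(base, list(
      scenario = "dual_asymmetric_32_16",
      assignment = list(strategy = "explicit_counts", counts = c(32L, 16L)),
      targets = list(tg(-9, 0, "left"), tg(-13.5, 0, "right")))),
    frequency_sweep = modifyList(base, list(
      scenario = "frequency_sweep",
      targets = list(tg(-9, 0, "left"), tg(9, 0, "right")),
      sweep = list(frequencies_khz = c(300, 400, 500, 600, 700)))),
    b_sweep = modifyList(base, list(
      scenario = "b_sweep",
      targets = list(tg(-9, 0, "left"), tg(9, 0, "right")),
      sweep = list(b_tesla_values = c(0.2, 0.3, 0.5))))
  )
  paths <- vapply(names(scenarios), function(nm) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(scenarios[[nm]], p)
    p
  }, "")
  invisible(paths)
}
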