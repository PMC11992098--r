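# Shared scenario runs, computed lazily once per test session.  Everything is
# deterministic, so caching only saves time, never changes results.

.tmaes_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tmaes_cache, inherits = FALSE)) {
    assign(key, expr, envir = .tmaes_cache)
  }
  get(key, envir = .tmaes_cache, inherits = FALSE)
}

fixture_paths <- function() {
  cached("fixtures", make_fixtures(file.path(tempdir(), "tmaes-fixtures")))
}

run_dual <- function() {
  cached("dual", run_scenario(fixture_paths()[["dual_symmetric"]]))
}

run_single <- function() {
  cached("single", run_scenario(fixture_paths()[["single_center"]]))
}

run_quad <- function() {
  cached("quad", run_scenario(fixture_paths()[["quad"]]))
}

# Coarse-grid variant of the dual scenario for cheap unit/property tests:
# same array, targets and physics, smaller sampling problem.
coarse_dual_config <- function(step_mm = 0.75, half_mm = 30) {
  list(
    scenario = "dual_coarse",
    array = list(rows = 8L, cols = 8L, pitch_mm = 4.5, kerf_mm = 0.2,
                 frequency_khz = 500),
    targets = list(
      list(label = "left", x_mm = -9, y_mm = 0, z_mm = -50),
      list(label = "right", x_mm = 9, y_mm = 0, z_mm = -50)
    ),
    grid = list(x_mm = c(-half_mm, half_mm), y_mm = c(-half_mm, half_mm),
                z_mm = -50, step_mm = step_mm)
  )
}

run_dual_coarse <- function() {
  cached("dual_coarse", run_scenario(coarse_dual_config()))
}

# Plane field built from an explicit value matrix (row = y, col = x), for
# metric tests with hand-countable masks.
matrix_field <- function(values, step_mm = 0.25, units = "Pa") {
  nx <- ncol(values)
  ny <- nrow(values)
  xs <- (seq_len(nx) - (nx + 1) / 2) * step_mm
  ys <- (seq_len(ny) - (ny + 1) / 2) * step_mm
  df <- tidyr::expand_grid(x_mm = xs, y_mm = ys)
  df$value <- values[cbind(match(df$y_mm, ys), match(df$x_mm, xs))]
  as_field(df, units = units, kind = "synthetic")
}

# Two-Gaussian synthetic focal plane (separated spots at +-x0).
gaussian_pair_field <- function(x0 = 9, sd_mm = 2, step_mm = 0.5,
                                half_mm = 20) {
  xs <- seq(-half_mm, half_mm, by = step_mm)
  df <- tidyr::expand_grid(x_mm = xs, y_mm = xs)
  df$value <- exp(-((df$x_mm - x0)^2 + df$y_mm^2) / (2 * sd_mm^2)) +
    exp(-((df$x_mm + x0)^2 + df$y_mm^2) / (2 * sd_mm^2))
  as_field(df, units = "V/m", kind = "synthetic")
}
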