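#' Subdivide array elements into radiating sub-sources
#'
#' Each rectangular element is covered by a uniform lattice of point
#' sub-sources whose spacing does not exceed the requested fraction of the
#' wavelength; sub-source areas sum exactly to the element area.
#'
#' @param array A [build_planar_array()] object.
#' @param spacing_fraction Maximum sub-source spacing as a fraction of the
#'   wavelength, in (0, 1].  Default 1/4 (the solver's converged setting).
#' @param sound_speed Sound speed used for the wavelength, m/s.
#' @return A tibble with one row per sub-source: `element`, `x_mm`, `y_mm`,
#'   `z_mm`, `area_mm2`.
#' @examples
#' subs <- subdivide_elements(build_planar_array(1, 1))
#' sum(subs$area_mm2)            # element area 4.3^2
#' @export
subdivide_elements <- function(array, spacing_fraction = 0.25,
                               sound_speed = 1500) {
  if (spacing_fraction <= 0 || spacing_fraction > 1) {
    abort("`spacing_fraction` must be in (0, 1].", class = "tmaes_config_error")
  }
  w <- attr(array, "element_width_mm")
  h <- attr(array, "element_height_mm")
  lambda_mm <- sound_speed / attr(array, "frequency_khz") # (m/s)/kHz = mm
  spacing <- spacing_fraction * lambda_mm
  nx <- max(1L, ceiling(w / spacing))
  ny <- max(1L, ceiling(h / spacing))
  off_x <- (seq_len(nx) - (nx + 1) / 2) * (w / nx)
  off_y <- (seq_len(ny) - (ny + 1) / 2) * (h / ny)
  offs <- tidyr::expand_grid(dx = off_x, dy = off_y)
  out <- tidyr::expand_grid(element = array$element, offs)
  out <- dplyr::left_join(out,
    dplyr::select(as_tibble(array), "element",
                  ex = "x_mm", ey = "y_mm", ez = "z_mm"),
    by = "element")
  tibble(
    element = out$element,
    x_mm = out$ex + out$dx,
    y_mm = out$ey + out$dy,
    z_mm = out$ez,
    area_mm2 = (w / nx) * (h / ny)
  )
}

#' Steady-state complex pressure field of a delayed array
#'
#' Sums free-field monopole contributions of all active sub-sources at every
#' grid sample: each sub-source of area `dA` at distance `R` contributes
#' `amplitude * dA / (2 pi R) * exp(-alpha R) * exp(i (k R + omega tau))`,
#' where `tau` is its element's firing delay.  Within each target's element
#' subset `R/c0 + tau` is constant at the target, so contributions add in
#' phase there.
#'
#' The absolute scale is linear in `source_amplitude` and is not physically
#' calibrated (the drive is arbitrary); use [calibrate_amplitude()] to pin
#' the peak to a reference pressure.
#'
#' @param array A [build_planar_array()] object.
#' @param delay_law A [compute_delay_law()] result (inactive elements,
#'   `NA` delay, contribute nothing).
#' @param medium A [medium()] object.
#' @param grid A [field_grid()].
#' @param source_amplitude Linear drive scale (Pa-equivalent).
#' @param spacing_fraction Sub-source spacing as a fraction of wavelength.
#' @return A `tmaes_field` tibble (`x_mm`, `y_mm`, `z_mm`, complex
#'   `amplitude`), kind `"pressure"`, units `"Pa"`.
#' @export
pressure_field <- function(array, delay_law, medium, grid,
                           source_amplitude = 1, spacing_fraction = 0.25) {
  active <- !is.na(delay_law$delay_us)
  if (!any(active)) {
    abort("No active elements in the delay law.", class = "tmaes_config_error")
  }
  subs <- subdivide_elements(array, spacing_fraction = spacing_fraction,
                             sound_speed = medium$sound_speed)
  subs <- subs[subs$element %in% delay_law$element[active], ]
  delay_us <- delay_law$delay_us[match(subs$element, delay_law$element)]

  f_hz <- attr(array, "frequency_khz") * 1000
  omega <- 2 * pi * f_hz
  k <- omega / medium$sound_speed

  pts <- as.matrix(grid$points) / 1000       # mm -> m
  src <- cbind(subs$x_mm, subs$y_mm, subs$z_mm) / 1000
  amp <- cw_source_sum(pts, src,
                       area = subs$area_mm2 / 1e6,   # mm^2 -> m^2
                       delay_s = delay_us / 1e6,     # us -> s
                       k = k, omega = omega,
                       alpha = medium$attenuation,
                       amplitude = source_amplitude)
  new_field(grid, amp, kind = "pressure", units = "Pa",
            frequency_khz = attr(array, "frequency_khz"))
}

#' Brute-force refined reference field
#'
#' Evaluates the identical source-summation model with the sub-source
#' spacing divided by `refinement`; used to verify discretisation
#' convergence of [pressure_field()].
#'
#' @inheritParams pressure_field
#' @param refinement Integer >= 2 by which the sub-source spacing is divided.
#' @return A `tmaes_field`, as [pressure_field()].
#' @export
oracle_field <- function(array, delay_law, medium, grid,
                         source_amplitude = 1, spacing_fraction = 0.25,
                         refinement = 2) {
  if (refinement < 2) {
    abort("`refinement` must be >= 2.", class = "tmaes_config_error")
  }
  pressure_field(array, delay_law, medium, grid,
                 source_amplitude = source_amplitude,
                 spacing_fraction = spacing_fraction / refinement)
}

#' Calibrate the absolute field scale to a reference peak
#'
#' The element drive amplitude behind reported absolute pressures is not part
#' of the model, so absolute scale is fixed by matching the field peak to a
#' stated reference (e.g. a measured or published peak pressure).
#'
#' @param field A `tmaes_field`.
#' @param reference_peak Desired peak magnitude, in the field's units.
#' @return The scalar factor such that `scale_field(field, factor)` has peak
#'   magnitude exactly `reference_peak`.
#' @examples
#' # factor is reference / current peak:
#' # calibrate_amplitude(field, 2.7e6)
#' @export
calibrate_amplitude <- function(field, reference_peak) {
  peak <- max(Mod(field$amplitude))
  if (peak <= 0) {
    abort("Cannot calibrate an all-zero field.", class = "tmaes_numeric_error")
  }
  reference_peak / peak
}

#' Rescale a field by a constant factor
#'
#' @param field A `tmaes_field`.
#' @param factor Scalar multiplier.
#' @return The rescaled `tmaes_field`.
#' @export
scale_field <- function(field, factor) {
  field$amplitude <- field$amplitude * factor
  field
}

#' Extract a 1-D amplitude profile from a plane field
#'
#' @param field A `tmaes_field` sampled on a plane.
#' @param along Axis of the profile (`"x_mm"`, `"y_mm"` or `"z_mm"`).
#' @param at Fixed coordinate of the other in-plane axis, mm (nearest grid
#'   line is used).
#' @return A tibble with the profile coordinate column and `value`
#'   (amplitude magnitude).
#' @export
field_profile <- function(field, along = "x_mm", at = 0) {
  g <- attr(field, "grid")
  if (length(g$plane_axes) != 2 || !(along %in% g$plane_axes)) {
    abort("`field` must be a plane containing the `along` axis.",
          class = "tmaes_config_error")
  }
  other <- setdiff(g$plane_axes, along)
  other_vals <- g[[other]]
  at_snap <- other_vals[which.min(abs(other_vals - at))]
  rows <- field[[other]] == at_snap
  out <- tibble(coord = field[[along]][rows],
                value = Mod(field$amplitude[rows]))
  names(out)[1] <- along
  dplyr::arrange(out, .data[[along]])
}
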