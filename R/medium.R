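#' Acoustic/electric medium properties
#'
#' Bulk properties of the propagation medium.  Defaults are the tissue-like
#' water bath used throughout: density 1000 kg/m^3, sound speed 1500 m/s,
#' conductivity 0.5 S/m (matching neural tissue), no attenuation.
#'
#' @param density Density rho, kg/m^3.
#' @param sound_speed Sound speed c0, m/s.
#' @param conductivity Electrical conductivity sigma, S/m.
#' @param attenuation Amplitude attenuation alpha, Np/m (default 0: water
#'   over a ~50 mm path).
#' @return A list of class `tmaes_medium`.
#' @examples
#' medium()
#' @export
medium <- function(density = 1000, sound_speed = 1500,
                   conductivity = 0.5, attenuation = 0) {
  if (density <= 0 || sound_speed <= 0) {
    abort("`density` and `sound_speed` must be positive.",
          class = "tmaes_config_error")
  }
  if (conductivity < 0 || attenuation < 0) {
    abort("`conductivity` and `attenuation` must be >= 0.",
          class = "tmaes_config_error")
  }
  structure(list(density = density, sound_speed = sound_speed,
                 conductivity = conductivity, attenuation = attenuation),
            class = "tmaes_medium")
}

#' @export
print.tmaes_medium <- function(x, ...) {
  cat(sprintf(
    "<tmaes_medium> rho %g kg/m^3, c0 %g m/s, sigma %g S/m, alpha %g Np/m\n",
    x$density, x$sound_speed, x$conductivity, x$attenuation))
  invisible(x)
}

#' Static magnetic field models
#'
#' `magnetic_field_uniform()` describes a spatially uniform static field of
#' given magnitude and direction (default along +y, perpendicular to the
#' beam axis).  `magnetic_field_profile()` describes the field of a permanent
#' magnet as a table of (distance from magnet surface, magnitude) anchors,
#' e.g. the measured 0.5 T / 0.3 T / 0.2 T at 0 / 10 / 15 mm.
#'
#' @param b_tesla Field magnitude(s), Tesla (>= 0).
#' @param direction Unit direction 3-vector (normalised internally).
#' @param distance_mm Anchor distances from the magnet surface, mm.
#' @return A list of class `tmaes_bfield`.
#' @examples
#' magnetic_field_uniform(0.5)
#' magnetic_field_profile(c(0, 10, 15), c(0.5, 0.3, 0.2))
#' @export
magnetic_field_uniform <- function(b_tesla = 0.5, direction = c(0, 1, 0)) {
  if (b_tesla < 0) abort("`b_tesla` must be >= 0.", class = "tmaes_config_error")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must be non-zero.", class = "tmaes_config_error")
  structure(list(kind = "uniform", b_tesla = b_tesla,
                 direction = direction / nrm),
            class = "tmaes_bfield")
}

#' @rdname magnetic_field_uniform
#' @export
magnetic_field_profile <- function(distance_mm = c(0, 10, 15),
                                   b_tesla = c(0.5, 0.3, 0.2)) {
  if (length(distance_mm) != length(b_tesla) || length(b_tesla) < 1) {
    abort("`distance_mm` and `b_tesla` must be equal-length anchors.",
          class = "tmaes_config_error")
  }
  if (any(distance_mm < 0) || any(b_tesla < 0)) {
    abort("Anchor distances and magnitudes must be >= 0.",
          class = "tmaes_config_error")
  }
  ord <- order(distance_mm)
  distance_mm <- distance_mm[ord]
  b_tesla <- b_tesla[ord]
  if (is.unsorted(rev(b_tesla))) {
    abort("Profile magnitude must be non-increasing with distance.",
          class = "tmaes_config_error")
  }
  structure(list(kind = "distance-profile",
                 anchors = tibble(distance_mm = distance_mm,
                                  b_tesla = b_tesla)),
            class = "tmaes_bfield")
}

#' @export
print.tmaes_bfield <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("<tmaes_bfield> uniform %g T, direction (%g, %g, %g)\n",
                x$b_tesla, x$direction[1], x$direction[2], x$direction[3]))
  } else {
    cat("<tmaes_bfield> distance profile:\n")
    print(x$anchors)
  }
  invisible(x)
}

#' Magnetic field magnitude at a distance from the magnet
#'
#' Anchor distances return their anchor value exactly; between anchors the
#' magnitude is interpolated piecewise-linearly; beyond the last anchor it is
#' clamped to the last value with a warning.
#'
#' @param profile A `magnetic_field_profile()` model.
#' @param distance_mm Distance(s) from the magnet surface, mm (>= 0).
#' @return Field magnitude(s), Tesla.
#' @examples
#' prof <- magnetic_field_profile()
#' b_at_distance(prof, c(0, 5, 10, 15))   # 0.5 0.4 0.3 0.2
#' @export
b_at_distance <- function(profile, distance_mm) {
  if (!inherits(profile, "tmaes_bfield") || profile$kind != "distance-profile") {
    abort("`profile` must be a distance-profile magnetic field model.",
          class = "tmaes_config_error")
  }
  if (any(distance_mm < 0)) {
    abort("`distance_mm` must be >= 0.", class = "tmaes_config_error")
  }
  a <- profile$anchors
  if (any(distance_mm > max(a$distance_mm))) {
    warn(sprintf(
      "Distance beyond the last anchor (%g mm); clamping to %g T.",
      max(a$distance_mm), a$b_tesla[nrow(a)]))
  }
  if (nrow(a) == 1) return(rep(a$b_tesla, length(distance_mm)))
  approx(a$distance_mm, a$b_tesla, xout = pmin(distance_mm, max(a$distance_mm)),
         rule = 2)$y
}

# Internal: scalar B magnitude for coupling on a field grid (uniform model
# or plain number).
b_magnitude <- function(b) {
  if (is.numeric(b) && length(b) == 1) return(b)
  if (inherits(b, "tmaes_bfield") && b$kind == "uniform") return(b$b_tesla)
  abort(paste0("Coupling on a grid needs a uniform magnetic field ",
               "(use b_at_distance() to evaluate a profile first)."),
        class = "tmaes_config_error")
}
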