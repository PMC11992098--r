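#' Particle velocity from acoustic pressure
#'
#' Plane-wave impedance relation: v = P / (rho c0), applied pointwise on the
#' sampled field (the complex phase is preserved).
#'
#' @param pressure A `tmaes_field` of kind `"pressure"` (Pa).
#' @param med A [medium()] object.
#' @return A `tmaes_field` of kind `"velocity"`, units m/s.
#' @examples
#' # 1.5 MPa in water -> 1 m/s
#' 1.5e6 / (1000 * 1500)
#' @export
particle_velocity <- function(pressure, med) {
  z0 <- med$density * med$sound_speed
  if (z0 <= 0) {
    abort("Characteristic impedance rho*c0 must be positive.",
          class = "tmaes_config_error")
  }
  out <- pressure
  out$amplitude <- out$amplitude / z0
  attr(out, "kind") <- "velocity"
  attr(out, "units") <- "m/s"
  out
}

#' Magneto-acoustically induced electric field
#'
#' Lorentz-force coupling of the vibrating charge carriers with a static
#' magnetic field perpendicular to the particle motion:
#' E = P B / (rho c0), pointwise.  For a B direction oblique to the particle
#' motion the effective magnitude is scaled by the sine of the angle between
#' them (the v x B cross product); the studied case is the perpendicular one
#' (sine = 1).  The E direction (along v x B) is carried as metadata.
#'
#' @param pressure A `tmaes_field` of kind `"pressure"` (Pa).
#' @param b A uniform [magnetic_field_uniform()] model or a plain Tesla
#'   magnitude.
#' @param med A [medium()] object.
#' @return A `tmaes_field` of kind `"efield"`, units V/m.
#' @examples
#' # the coupling scale: 2.7 MPa, 0.5 T, water -> 0.9 V/m
#' 2.7e6 * 0.5 / (1000 * 1500)
#' @export
efield_from_pressure <- function(pressure, b, med) {
  z0 <- med$density * med$sound_speed
  if (z0 <= 0) {
    abort("Characteristic impedance rho*c0 must be positive.",
          class = "tmaes_config_error")
  }
  b_mag <- b_magnitude(b)
  # particle motion is along the propagation axis (-z); an oblique B couples
  # through |v x B| = v B sin(theta)
  sin_theta <- 1
  direction <- c(1, 0, 0)
  if (inherits(b, "tmaes_bfield") && b$kind == "uniform") {
    v_hat <- c(0, 0, -1)
    cr <- c(v_hat[2] * b$direction[3] - v_hat[3] * b$direction[2],
            v_hat[3] * b$direction[1] - v_hat[1] * b$direction[3],
            v_hat[1] * b$direction[2] - v_hat[2] * b$direction[1])
    sin_theta <- sqrt(sum(cr^2))
    direction <- if (sin_theta > 0) cr / sin_theta else c(NA_real_, NA_real_, NA_real_)
  }
  out <- pressure
  out$amplitude <- out$amplitude * (b_mag * sin_theta / z0)
  attr(out, "kind") <- "efield"
  attr(out, "units") <- "V/m"
  attr(out, "e_direction") <- direction
  out
}

#' Current density from particle velocity
#'
#' J = sigma v B, pointwise.
#'
#' @param velocity A `tmaes_field` of kind `"velocity"` (m/s).
#' @param b A uniform magnetic field model or Tesla magnitude.
#' @param med A [medium()] object (its conductivity is used).
#' @return A `tmaes_field` of kind `"current"`, units A/m^2.
#' @export
current_density <- function(velocity, b, med) {
  out <- velocity
  out$amplitude <- out$amplitude * (med$conductivity * b_magnitude(b))
  attr(out, "kind") <- "current"
  attr(out, "units") <- "A/m^2"
  out
}

#' Rescale an induced electric field to a different magnetic field
#'
#' For fixed acoustics E is proportional to B (slope through the origin), so
#' E_new = E_ref * B_new / B_ref.
#'
#' @param e_ref Reference field intensity (V/m), scalar or vector.
#' @param b_ref Magnetic field at which `e_ref` was obtained, Tesla (> 0).
#' @param b_new New magnetic field magnitude(s), Tesla.
#' @return Scaled field intensity, V/m.
#' @examples
#' scale_efield_with_b(0.64, 0.5, 0.7)   # 0.896
#' @export
scale_efield_with_b <- function(e_ref, b_ref, b_new) {
  if (b_ref <= 0) {
    abort("`b_ref` must be positive.", class = "tmaes_config_error")
  }
  e_ref * b_new / b_ref
}
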