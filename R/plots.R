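#' Plot a sampled plane field
#'
#' Raster map of the field magnitude over the two in-plane axes.
#'
#' @param object A `tmaes_field` on a plane.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmaes_field <- function(object, ...) {
  g <- attr(object, "grid")
  u <- g$plane_axes[1]
  v <- g$plane_axes[2]
  df <- tibble(u = object[[u]], v = object[[v]],
               value = Mod(object$amplitude))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "units")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = u, y = v,
                  title = sprintf("%s field magnitude", attr(object, "kind")))
}

#' Plot a -3 dB focal region
#'
#' Mask tiles coloured by component, with component peaks marked.
#'
#' @param object A `tmaes_region`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmaes_region <- function(object, ...) {
  u <- object$axes[1]
  v <- object$axes[2]
  cells <- tibble(u = object$cells[[u]], v = object$cells[[v]],
                  component = factor(object$cells$component))
  peaks <- tibble(u = object$components[[paste0("peak_", u)]],
                  v = object$components[[paste0("peak_", v)]])
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$component),
                       width = object$step_mm, height = object$step_mm) +
    ggplot2::geom_point(data = peaks, shape = 3, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = u, y = v,
                  title = sprintf("-%g dB focal region (%s)",
                                  object$drop_db, object$kind))
}

#' Plot a sweep table
#'
#' Total -3 dB area (frequency sweeps) or peak electric field (B sweeps)
#' against the swept parameter.
#'
#' @param object A `tmaes_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmaes_sweep <- function(object, ...) {
  param <- attr(object, "sweep_param")
  yvar <- if (param == "b_tesla") "peak_e_v_per_m" else "total_area_mm2"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data[[param]], y = .data[[yvar]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("sweep: %s vs %s", yvar, param))
}

#' Plot a 1-D field profile
#'
#' @param field A plane `tmaes_field`.
#' @param along Profile axis, see [field_profile()].
#' @param at Fixed coordinate of the other axis, mm.
#' @return A ggplot object.
#' @export
plot_profile <- function(field, along = "x_mm", at = 0) {
  prof <- field_profile(field, along = along, at = at)
  coord <- setdiff(names(prof), "value")[1]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data[[coord]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = attr(field, "units"), x = coord)
}
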