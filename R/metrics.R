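#' Threshold a plane field into -3 dB focal regions
#'
#' The focus area is the region where the field magnitude stays within a
#' `drop_db` drop of the peak; on amplitude a 3 dB drop is the factor
#' `10^(-3/20) ~ 0.708`.  Cells above threshold are grouped into connected
#' components by edge adjacency (4-connectivity).
#'
#' By default the threshold is taken from the global peak of the plane (one
#' focus-area definition across a multi-target field).  With
#' `reference = "component"` each component found at the global threshold is
#' re-grown from its own peak at a per-component threshold.
#'
#' @param field A `tmaes_field` sampled on a plane (or anything coercible
#'   via [as_field()]).
#' @param drop_db Drop from peak defining the region, dB (default 3).
#' @param reference `"global"` (default) or `"component"`.
#' @return A list of class `tmaes_region`: `cells` (tibble of above-threshold
#'   cells with integer grid indices `iu`, `iv`, plane coordinates, `value`
#'   and `component`), `components` (per-component cell count, area, peak
#'   position and value), `threshold`, `peak_value`, `drop_db`, `step_mm`,
#'   `axes`.
#' @export
threshold_mask <- function(field, drop_db = 3,
                           reference = c("global", "component")) {
  reference <- match.arg(reference)
  g <- attr(field, "grid")
  if (is.null(g) || length(g$plane_axes) != 2) {
    abort("Focal regions are defined on plane fields only.",
          class = "tmaes_config_error")
  }
  u <- g$plane_axes[1]
  v <- g$plane_axes[2]
  value <- Mod(field$amplitude)
  peak <- max(value)
  if (peak <= 0) {
    abort("Cannot threshold an all-zero field.", class = "tmaes_numeric_error")
  }
  factor <- 10^(-drop_db / 20)
  thr <- peak * factor

  cells_all <- tibble(
    iu = match(field[[u]], g[[u]]),
    iv = match(field[[v]], g[[v]]),
    u = field[[u]],
    v = field[[v]],
    value = value
  )
  names(cells_all)[3:4] <- c(u, v)

  cells <- cells_all[value >= thr, ]
  cells$component <- label_components(cells$iu, cells$iv)

  if (reference == "component") {
    comp_ids <- sort(unique(cells$component))
    grown <- vector("list", length(comp_ids))
    for (i in seq_along(comp_ids)) {
      comp_cells <- cells[cells$component == comp_ids[i], ]
      cpk <- comp_cells[which.max(comp_cells$value), ]
      thr_c <- cpk$value * factor
      sub <- cells_all[cells_all$value >= thr_c, ]
      lab <- label_components(sub$iu, sub$iv)
      keep <- lab == lab[sub$iu == cpk$iu & sub$iv == cpk$iv]
      sub <- sub[keep, ]
      sub$component <- i
      grown[[i]] <- sub
    }
    cells <- dplyr::bind_rows(grown)
    cells <- dplyr::distinct(cells, .data$iu, .data$iv, .keep_all = TRUE)
  }

  comps <- dplyr::group_by(cells, .data$component)
  comps <- dplyr::summarise(comps,
    n_cells = dplyr::n(),
    area_mm2 = dplyr::n() * g$step_mm^2,
    peak_value = max(.data$value),
    peak_iu = .data$iu[which.max(.data$value)],
    peak_iv = .data$iv[which.max(.data$value)],
    peak_u = .data[[u]][which.max(.data$value)],
    peak_v = .data[[v]][which.max(.data$value)],
    .groups = "drop"
  )
  names(comps)[names(comps) == "peak_u"] <- paste0("peak_", u)
  names(comps)[names(comps) == "peak_v"] <- paste0("peak_", v)
  comps <- dplyr::arrange(comps, dplyr::desc(.data$area_mm2))

  structure(
    list(cells = cells, components = comps, threshold = thr,
         peak_value = peak, drop_db = drop_db, step_mm = g$step_mm,
         axes = c(u, v), kind = attr(field, "kind"),
         units = attr(field, "units")),
    class = "tmaes_region"
  )
}

# Internal: 4-connectivity labelling of integer lattice cells via igraph.
label_components <- function(iu, iv) {
  n <- length(iu)
  if (n == 0) return(integer(0))
  span <- max(iu) + 2L
  key <- iu + span * iv
  idx_right <- match(key + 1L, key)
  idx_up <- match(key + span, key)
  from <- c(seq_len(n)[!is.na(idx_right)], seq_len(n)[!is.na(idx_up)])
  to <- c(idx_right[!is.na(idx_right)], idx_up[!is.na(idx_up)])
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) {
    gr <- igraph::add_edges(gr, rbind(from, to))
  }
  as.integer(igraph::components(gr)$membership)
}

#' @export
print.tmaes_region <- function(x, ...) {
  cat(sprintf(
    "<tmaes_region> %d component(s), total area %.2f mm^2 (-%g dB of %s peak %.4g %s)\n",
    nrow(x$components), sum(x$components$area_mm2), x$drop_db, x$kind,
    x$peak_value, x$units))
  print(x$components)
  invisible(x)
}

#' Focal-region areas
#'
#' Cell-count areas on the sampling plane: `n_cells * step^2` in total and
#' per connected component.
#'
#' @param region A [threshold_mask()] result.
#' @return A list with `total_mm2` and `per_component` (tibble of
#'   `component`, `n_cells`, `area_mm2`).
#' @export
region_area <- function(region) {
  if (length(region$axes) != 2) {
    abort("Areas are defined on plane grids only.",
          class = "tmaes_config_error")
  }
  list(
    total_mm2 = sum(region$components$area_mm2),
    per_component = dplyr::select(region$components,
                                  "component", "n_cells", "area_mm2")
  )
}

# Internal: length (cells * step) of the contiguous run of `set` containing
# `pivot`, on an integer line.
run_length_through <- function(set, pivot) {
  set <- sort(set)
  i <- match(pivot, set)
  lo <- i
  while (lo > 1 && set[lo - 1] == set[lo] - 1L) lo <- lo - 1
  hi <- i
  while (hi < length(set) && set[hi + 1] == set[hi] + 1L) hi <- hi + 1
  hi - lo + 1L
}

#' Long- and short-axis lengths of a focal component
#'
#' Extents of the component's mask along the two in-plane axis lines through
#' its peak (contiguous cell run times the grid step); the long axis is the
#' larger of the two.
#'
#' @param region A [threshold_mask()] result.
#' @param component Component id (default: all components).
#' @return A tibble: `component`, `len_u_mm`, `len_v_mm` (extents along the
#'   first/second plane axis), `long_axis_mm`, `short_axis_mm`.
#' @export
axis_lengths <- function(region, component = NULL) {
  comps <- region$components
  if (!is.null(component)) {
    comps <- comps[comps$component %in% component, ]
    if (nrow(comps) == 0) {
      abort("Unknown component id.", class = "tmaes_config_error")
    }
  }
  out <- purrr::map_dfr(seq_len(nrow(comps)), function(i) {
    cc <- comps[i, ]
    cells <- region$cells[region$cells$component == cc$component, ]
    len_u <- run_length_through(cells$iu[cells$iv == cc$peak_iv], cc$peak_iu) *
      region$step_mm
    len_v <- run_length_through(cells$iv[cells$iu == cc$peak_iu], cc$peak_iv) *
      region$step_mm
    tibble(component = cc$component, len_u_mm = len_u, len_v_mm = len_v,
           long_axis_mm = max(len_u, len_v),
           short_axis_mm = min(len_u, len_v))
  })
  out
}

#' Distance between the two main focal peaks
#'
#' Euclidean distance (mm) between the peak positions of the two largest
#' connected components.  A single component means the targets are not
#' separated and raises a condition of class `tmaes_not_separated`.
#'
#' @param region A [threshold_mask()] result.
#' @return Peak-to-peak distance, mm.
#' @export
peak_distance <- function(region) {
  comps <- region$components
  if (nrow(comps) < 2) {
    abort("Targets not separated: the -3 dB region has a single component.",
          class = "tmaes_not_separated")
  }
  comps <- comps[order(-comps$area_mm2), ][1:2, ]
  pu <- comps[[paste0("peak_", region$axes[1])]]
  pv <- comps[[paste0("peak_", region$axes[2])]]
  sqrt(diff(pu)^2 + diff(pv)^2)
}

#' Separation index R of a dual-focus profile
#'
#' For an amplitude profile along x through the two foci (at y = 0),
#' `R = (E_max - E(x=0)) / (E_max - E_min)`: R = 1 means the midline dips to
#' the profile minimum (complete separation), R = 0 means the midline equals
#' the peak (merged foci).
#'
#' @param profile A tibble with a coordinate column (e.g. `x_mm`) and a
#'   `value` column, as returned by [field_profile()].
#' @param midline Coordinate at which the between-target value is read,
#'   default 0 (linearly interpolated if not a sample).
#' @return A one-row tibble of class `tmaes_separation`: `e_max`, `e_min`,
#'   `e_midline`, `R`, `peak_distance_mm` (distance between the two largest
#'   local maxima; `NA` when the profile has fewer than two).
#' @examples
#' prof <- tibble::tibble(x_mm = seq(-20, 20, 0.5),
#'                        value = exp(-(seq(-20, 20, 0.5) - 9)^2 / 8) +
#'                                exp(-(seq(-20, 20, 0.5) + 9)^2 / 8))
#' separation_index(prof)$R
#' @export
separation_index <- function(profile, midline = 0) {
  coord_col <- setdiff(names(profile), "value")[1]
  x <- profile[[coord_col]]
  v <- profile$value
  if (max(v) == min(v)) {
    abort("Separation index undefined for a constant profile.",
          class = "tmaes_numeric_error")
  }
  e_max <- max(v)
  e_min <- min(v)
  e_mid <- approx(x, v, xout = midline, rule = 2, ties = "ordered")$y
  r <- (e_max - e_mid) / (e_max - e_min)
  if (r < 0 || r > 1) {
    warn(sprintf("Separation index %.4f outside [0, 1]; clipping.", r))
    r <- min(max(r, 0), 1)
  }
  # interior local maxima (>= both neighbours, > at least one)
  n <- length(v)
  is_pk <- rep(FALSE, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    is_pk[i] <- v[i] >= v[i - 1] & v[i] >= v[i + 1] &
      (v[i] > v[i - 1] | v[i] > v[i + 1])
  }
  pk <- which(is_pk)
  pd <- NA_real_
  if (length(pk) >= 2) {
    top2 <- pk[order(-v[pk])][1:2]
    pd <- abs(diff(x[top2]))
  }
  out <- tibble(e_max = e_max, e_min = e_min, e_midline = e_mid,
                R = r, peak_distance_mm = pd)
  class(out) <- c("tmaes_separation", class(out))
  out
}

#' Full focal-quality report of a plane field
#'
#' Thresholds the field, matches connected components to the set targets
#' (each component to its nearest target; per target the largest-area match
#' is its focal spot, surplus components are reported as side lobes) and
#' assembles per-target areas, axis lengths, peak positions/values and the
#' total area.
#'
#' @param field A plane `tmaes_field`.
#' @param targets A [focus_targets()] tibble.
#' @param drop_db Threshold drop, dB.
#' @param reference Threshold reference, see [threshold_mask()].
#' @return A list of class `tmaes_metrics`: `per_target` tibble (`label`,
#'   set/peak positions, `offset_mm`, `peak_value`, `area_mm2`,
#'   `long_axis_mm`, `short_axis_mm`, `component`), `side_lobes` tibble,
#'   `total_area_mm2`, `n_components`, `peak_value`, `threshold`, `units`,
#'   `kind`, `drop_db`, `step_mm`.
#' @export
focal_metrics <- function(field, targets, drop_db = 3,
                          reference = c("global", "component")) {
  region <- threshold_mask(field, drop_db = drop_db, reference = reference)
  comps <- region$components
  u <- region$axes[1]
  v <- region$axes[2]
  tg_u <- targets[[u]]
  tg_v <- targets[[v]]
  near <- vapply(seq_len(nrow(comps)), function(i) {
    which.min((comps[[paste0("peak_", u)]][i] - tg_u)^2 +
              (comps[[paste0("peak_", v)]][i] - tg_v)^2)
  }, integer(1))
  ax <- axis_lengths(region)

  rows <- vector("list", nrow(targets))
  side <- comps[0, ]
  for (j in seq_len(nrow(targets))) {
    mine <- which(near == j)
    if (length(mine) == 0) {
      rows[[j]] <- tibble(
        label = targets$label[j], target_u = tg_u[j], target_v = tg_v[j],
        peak_u = NA_real_, peak_v = NA_real_, offset_mm = NA_real_,
        peak_value = NA_real_, area_mm2 = 0,
        long_axis_mm = NA_real_, short_axis_mm = NA_real_,
        component = NA_integer_)
      next
    }
    best <- mine[which.max(comps$area_mm2[mine])]
    side <- dplyr::bind_rows(side, comps[setdiff(mine, best), ])
    cc <- comps[best, ]
    aj <- ax[ax$component == cc$component, ]
    rows[[j]] <- tibble(
      label = targets$label[j], target_u = tg_u[j], target_v = tg_v[j],
      peak_u = cc[[paste0("peak_", u)]], peak_v = cc[[paste0("peak_", v)]],
      offset_mm = sqrt((cc[[paste0("peak_", u)]] - tg_u[j])^2 +
                       (cc[[paste0("peak_", v)]] - tg_v[j])^2),
      peak_value = cc$peak_value, area_mm2 = cc$area_mm2,
      long_axis_mm = aj$long_axis_mm, short_axis_mm = aj$short_axis_mm,
      component = cc$component)
  }
  per_target <- dplyr::bind_rows(rows)
  names(per_target)[names(per_target) == "target_u"] <- paste0("target_", u)
  names(per_target)[names(per_target) == "target_v"] <- paste0("target_", v)
  names(per_target)[names(per_target) == "peak_u"] <- paste0("peak_", u)
  names(per_target)[names(per_target) == "peak_v"] <- paste0("peak_", v)

  structure(
    list(per_target = per_target, side_lobes = side,
         total_area_mm2 = sum(comps$area_mm2),
         n_components = nrow(comps),
         peak_value = region$peak_value, threshold = region$threshold,
         units = region$units, kind = region$kind,
         drop_db = drop_db, step_mm = region$step_mm,
         region = region),
    class = "tmaes_metrics"
  )
}

#' @export
print.tmaes_metrics <- function(x, ...) {
  cat(sprintf(
    "<tmaes_metrics> %s field: peak %.4g %s, %d component(s), total -%g dB area %.2f mm^2\n",
    x$kind, x$peak_value, x$units, x$n_components, x$drop_db,
    x$total_area_mm2))
  print(x$per_target)
  invisible(x)
}

#' -3 dB extents of a 1-D profile
#'
#' Runs of the profile at or above `threshold`, used for the per-target
#' x-axis focusing length (the profile along y = 0 thresholded at the
#' plane's global -3 dB level).
#'
#' @param profile A tibble with a coordinate column and `value`.
#' @param threshold Absolute threshold in the profile's units.
#' @return A tibble: `run`, `from_mm`, `to_mm`, `length_mm` (cells * step),
#'   `peak_mm`, `peak_value`.
#' @export
profile_extents <- function(profile, threshold) {
  coord_col <- setdiff(names(profile), "value")[1]
  x <- profile[[coord_col]]
  v <- profile$value
  step <- stats::median(diff(x))
  above <- v >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  purrr::map_dfr(seq_along(keep), function(i) {
    a <- starts[keep[i]]
    b <- ends[keep[i]]
    tibble(run = i, from_mm = x[a], to_mm = x[b],
           length_mm = (b - a + 1) * step,
           peak_mm = x[a:b][which.max(v[a:b])],
           peak_value = max(v[a:b]))
  })
}
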