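#' Build a planar phased-array transducer
#'
#' Constructs a regular grid of rectangular elements in the z = 0 plane,
#' centred on the origin, radiating toward negative z.  The active element
#' size is `pitch - kerf` on each axis.
#'
#' @param rows,cols Number of element rows (y axis) and columns (x axis).
#' @param pitch_mm Centre-to-centre element spacing, mm (both axes).
#' @param kerf_mm Inter-element gap, mm; must be smaller than the pitch.
#' @param frequency_khz Operating frequency, kHz.
#'
#' @return A tibble of class `tmaes_array` with one row per element:
#'   `element`, `row`, `col`, `x_mm`, `y_mm`, `z_mm` (all centres at z = 0).
#'   Geometry is carried in attributes (`pitch_mm`, `kerf_mm`,
#'   `element_width_mm`, `element_height_mm`, `frequency_khz`).
#'
#' @examples
#' arr <- build_planar_array(8, 8, pitch_mm = 4.5, kerf_mm = 0.2,
#'                           frequency_khz = 500)
#' nrow(arr)                       # 64 elements
#' range(arr$x_mm)                 # +/- 15.75 mm
#' @export
build_planar_array <- function(rows, cols, pitch_mm = 4.5, kerf_mm = 0.2,
                               frequency_khz = 500) {
  if (rows < 1 || cols < 1) {
    abort("`rows` and `cols` must both be >= 1.", class = "tmaes_config_error")
  }
  if (pitch_mm <= 0 || frequency_khz <= 0) {
    abort("`pitch_mm` and `frequency_khz` must be positive.",
          class = "tmaes_config_error")
  }
  if (kerf_mm < 0 || kerf_mm >= pitch_mm) {
    abort("`kerf_mm` must satisfy 0 <= kerf_mm < pitch_mm.",
          class = "tmaes_config_error")
  }
  # centres symmetric about the origin: (index - (n+1)/2) * pitch
  cx <- (seq_len(cols) - (cols + 1) / 2) * pitch_mm
  cy <- (seq_len(rows) - (rows + 1) / 2) * pitch_mm
  out <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  out <- dplyr::mutate(out,
    element = dplyr::row_number(),
    x_mm = cx[.data$col],
    y_mm = cy[.data$row],
    z_mm = 0
  )
  out <- dplyr::select(out, "element", "row", "col", "x_mm", "y_mm", "z_mm")
  structure(
    out,
    class = c("tmaes_array", class(out)),
    pitch_mm = pitch_mm,
    kerf_mm = kerf_mm,
    element_width_mm = pitch_mm - kerf_mm,
    element_height_mm = pitch_mm - kerf_mm,
    frequency_khz = frequency_khz
  )
}

#' Define focal targets
#'
#' Targets live in the z < 0 half-space (the transducer face is the z = 0
#' plane and the beam propagates toward negative z).
#'
#' @param x_mm,y_mm,z_mm Target coordinates, mm.  Recycled to a common length.
#' @param label Optional character labels; defaults to `"t1"`, `"t2"`, ...
#'
#' @return A tibble of class `tmaes_targets` with columns
#'   `label`, `x_mm`, `y_mm`, `z_mm`.
#' @examples
#' focus_targets(x_mm = c(-9, 9), y_mm = 0, z_mm = -50,
#'               label = c("left", "right"))
#' @export
focus_targets <- function(x_mm, y_mm = 0, z_mm = -50, label = NULL) {
  n <- max(length(x_mm), length(y_mm), length(z_mm))
  out <- tibble(
    label = label %||% paste0("t", seq_len(n)),
    x_mm = rep_len(x_mm, n),
    y_mm = rep_len(y_mm, n),
    z_mm = rep_len(z_mm, n)
  )
  if (any(out$z_mm >= 0)) {
    abort(
      paste0(
        "All targets must lie at z < 0 (beam propagates toward negative z); ",
        "offending label(s): ",
        paste(out$label[out$z_mm >= 0], collapse = ", ")
      ),
      class = "tmaes_config_error"
    )
  }
  if (anyDuplicated(out$label)) {
    abort("Target labels must be unique.", class = "tmaes_config_error")
  }
  structure(out, class = c("tmaes_targets", class(out)))
}

#' Partition array elements among focal targets
#'
#' @param array A [build_planar_array()] object.
#' @param targets A [focus_targets()] tibble.
#' @param strategy One of `"block"` (each element goes to its nearest target;
#'   for symmetric target sets this yields contiguous column / quadrant
#'   blocks), `"interleaved"` (round-robin by element index),
#'   `"explicit_counts"` (each target in order takes `counts[i]` of its
#'   nearest still-unassigned elements; the remainder stays inactive) or
#'   `"custom"` (user-supplied `mapping`).
#' @param counts Per-target element counts for `"explicit_counts"`.
#' @param mapping For `"custom"`: a character vector of length
#'   `nrow(array)` of target labels, with `NA` marking inactive elements.
#'
#' @return A tibble of class `tmaes_assignment` with columns `element` and
#'   `target` (`NA` = inactive); the strategy and target table are carried as
#'   attributes.
#' @examples
#' arr <- build_planar_array(8, 8)
#' tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
#' table(assign_elements(arr, tg, "block")$target)           # 32 / 32
#' @export
assign_elements <- function(array, targets,
                            strategy = c("block", "interleaved",
                                         "explicit_counts", "custom"),
                            counts = NULL, mapping = NULL) {
  strategy <- match.arg(strategy)
  n <- nrow(array)
  m <- nrow(targets)
  if (m < 1 || m > n) {
    abort("Need 1 <= number of targets <= number of elements.",
          class = "tmaes_config_error")
  }
  # element-to-target Euclidean distances, mm (n x m)
  d <- vapply(seq_len(m), function(j) {
    sqrt((array$x_mm - targets$x_mm[j])^2 +
         (array$y_mm - targets$y_mm[j])^2 +
         (array$z_mm - targets$z_mm[j])^2)
  }, numeric(n))
  d <- matrix(d, nrow = n)

  target <- switch(strategy,
    block = {
      # nearest target; ties broken toward the lower target index
      targets$label[apply(d, 1L, which.min)]
    },
    interleaved = targets$label[(array$element - 1L) %% m + 1L],
    explicit_counts = {
      if (is.null(counts) || length(counts) != m) {
        abort("`counts` must give one element count per target.",
              class = "tmaes_config_error")
      }
      if (any(counts < 1)) {
        abort("Every target needs at least one element (zero count given).",
              class = "tmaes_config_error")
      }
      if (sum(counts) > n) {
        abort(sprintf(
          "Requested counts sum to %d but the array only has %d elements.",
          sum(counts), n), class = "tmaes_config_error")
      }
      lab <- rep(NA_character_, n)
      free <- rep(TRUE, n)
      for (j in seq_len(m)) {
        ord <- order(d[, j], array$element)
        take <- head(ord[free[ord]], counts[j])
        lab[take] <- targets$label[j]
        free[take] <- FALSE
      }
      lab
    },
    custom = {
      if (is.null(mapping) || length(mapping) != n) {
        abort("`mapping` must supply a label (or NA) for every element.",
              class = "tmaes_config_error")
      }
      bad <- setdiff(unique(mapping[!is.na(mapping)]), targets$label)
      if (length(bad)) {
        abort(paste0("Unknown target label(s) in mapping: ",
                     paste(bad, collapse = ", ")),
              class = "tmaes_config_error")
      }
      as.character(mapping)
    }
  )
  if (!all(targets$label %in% target)) {
    missing_t <- setdiff(targets$label, target)
    abort(paste0("Target(s) with no assigned element: ",
                 paste(missing_t, collapse = ", ")),
          class = "tmaes_config_error")
  }
  out <- tibble(element = array$element, target = target)
  structure(out,
            class = c("tmaes_assignment", class(out)),
            strategy = strategy,
            targets = targets)
}

#' Time of flight from element centres to a focal target
#'
#' Euclidean distance divided by the sound speed.
#'
#' @param element_center A length-3 vector or an n x 3 matrix of centres, mm.
#' @param target A length-3 vector (mm) or a single-row target tibble.
#' @param c0 Sound speed, m/s.
#' @return Time(s) of flight in microseconds.
#' @examples
#' time_of_flight(c(0, 0, 0), c(0, 0, -50))          # 33.333 us
#' @export
time_of_flight <- function(element_center, target, c0 = 1500) {
  if (c0 <= 0) abort("`c0` must be positive.", class = "tmaes_config_error")
  ec <- if (is.matrix(element_center)) element_center else
    matrix(element_center, ncol = 3, byrow = TRUE)
  tp <- if (is.data.frame(target)) {
    unlist(target[1, c("x_mm", "y_mm", "z_mm")], use.names = FALSE)
  } else {
    as.numeric(target)
  }
  d_mm <- sqrt((ec[, 1] - tp[1])^2 + (ec[, 2] - tp[2])^2 + (ec[, 3] - tp[3])^2)
  d_mm * 1000 / c0 # mm / (m/s) -> us
}

#' Compute the multi-target delay law
#'
#' Per-element firing delays that make each element subset arrive in phase at
#' its assigned target.  The reference element is the active element with the
#' globally longest time of flight; it fires at delay 0 and all other active
#' elements are delayed so that `delay + time_of_flight` equals the reference
#' time of flight within each target subset.
#'
#' @param array A [build_planar_array()] object.
#' @param targets A [focus_targets()] tibble.
#' @param assignment An [assign_elements()] result.
#' @param c0 Sound speed, m/s.
#' @return A tibble of class `tmaes_delay_law`: `element`, `x_mm`, `y_mm`,
#'   `target`, `tof_us`, `delay_us` (`NA` for inactive elements), with the
#'   reference element index in `attr(, "reference_element")`.
#' @examples
#' arr <- build_planar_array(8, 8)
#' tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
#' dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
#' dl[attr(dl, "reference_element"), ]
#' @export
compute_delay_law <- function(array, targets, assignment, c0 = 1500) {
  stopifnot(nrow(assignment) == nrow(array))
  tg_idx <- match(assignment$target, targets$label)
  active <- !is.na(tg_idx)
  if (!any(active)) {
    abort("Delay law undefined: no active elements.",
          class = "tmaes_config_error")
  }
  tof <- rep(NA_real_, nrow(array))
  for (j in unique(tg_idx[active])) {
    rows <- which(!is.na(tg_idx) & tg_idx == j)
    tof[rows] <- time_of_flight(
      cbind(array$x_mm[rows], array$y_mm[rows], array$z_mm[rows]),
      targets[j, ], c0 = c0)
  }
  t_max <- max(tof[active])
  reference <- which(active & tof == t_max)[1L]
  delay <- ifelse(active, t_max - tof, NA_real_)
  out <- tibble(
    element = array$element,
    x_mm = array$x_mm,
    y_mm = array$y_mm,
    target = assignment$target,
    tof_us = tof,
    delay_us = delay
  )
  structure(out,
            class = c("tmaes_delay_law", class(out)),
            reference_element = reference,
            c0 = c0,
            targets = targets)
}

#' Export a delay law as CSV
#'
#' Writes `element_index, x_mm, y_mm, target_label, tof_us, delay_us`.
#'
#' @param delay_law A [compute_delay_law()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_delay_law <- function(delay_law, path) {
  out <- tibble(
    element_index = delay_law$element,
    x_mm = delay_law$x_mm,
    y_mm = delay_law$y_mm,
    target_label = delay_law$target,
    tof_us = delay_law$tof_us,
    delay_us = delay_law$delay_us
  )
  readr::write_csv(out, path)
  invisible(path)
}
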