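test_that("planar array geometry matches the 8x8 / 4.5 mm / 0.2 mm design", {
  arr <- build_planar_array(8, 8, pitch_mm = 4.5, kerf_mm = 0.2,
                            frequency_khz = 500)
  expect_equal(nrow(arr), 64)
  expect_equal(attr(arr, "element_width_mm"), 4.3)
  expect_equal(attr(arr, "element_height_mm"), 4.3)
  expect_setequal(unique(arr$x_mm), c(-15.75, -11.25, -6.75, -2.25,
                                      2.25, 6.75, 11.25, 15.75))
  expect_setequal(unique(arr$y_mm), unique(arr$x_mm))
  expect_true(all(arr$z_mm == 0))
  # symmetry about the origin
  expect_equal(sort(arr$x_mm), sort(-arr$x_mm))

  one <- build_planar_array(1, 1, 4.5, 0.2, 500)
  expect_equal(one[, c("x_mm", "y_mm", "z_mm")],
               tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 0),
               ignore_attr = TRUE)
  two <- build_planar_array(2, 2, 4.5, 0.2, 500)
  expect_setequal(two$x_mm, c(-2.25, 2.25))
  expect_setequal(two$y_mm, c(-2.25, 2.25))
})

test_that("invalid array geometry raises configuration errors", {
  expect_error(build_planar_array(8, 8, pitch_mm = -1),
               class = "tmaes_config_error")
  expect_error(build_planar_array(8, 8, pitch_mm = 4.5, kerf_mm = 4.5),
               class = "tmaes_config_error")
  expect_error(build_planar_array(8, 8, frequency_khz = 0),
               class = "tmaes_config_error")
  expect_error(build_planar_array(0, 8), class = "tmaes_config_error")
})

test_that("targets must lie in the z < 0 half-space", {
  expect_error(focus_targets(0, 0, 0), class = "tmaes_config_error")
  expect_error(focus_targets(c(-9, -9), c(9, -9), c(-50, 50)),
               class = "tmaes_config_error")
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
  expect_equal(tg$label, c("left", "right"))
})

test_that("block assignment partitions the dual array 32/32 by nearest target", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
  asg <- assign_elements(arr, tg, "block")
  expect_equal(sum(asg$target == "left"), 32)
  expect_equal(sum(asg$target == "right"), 32)
  # brute-force nearest-target check against the assignment
  d_left <- sqrt((arr$x_mm + 9)^2 + arr$y_mm^2 + 2500)
  d_right <- sqrt((arr$x_mm - 9)^2 + arr$y_mm^2 + 2500)
  expect_equal(asg$target, ifelse(d_left <= d_right, "left", "right"))
  # left block is contiguous: the four left columns
  expect_true(all(arr$x_mm[asg$target == "left"] < 0))
})

test_that("quad block assignment gives 16 elements per quadrant", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9, 9, -9), c(9, 9, -9, -9), -50)
  asg <- assign_elements(arr, tg, "block")
  expect_equal(as.integer(table(asg$target)), rep(16L, 4))
})

test_that("explicit-counts honours 32/16 and leaves the remainder inactive", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, -13.5), 0, -50, label = c("left", "right"))
  asg <- assign_elements(arr, tg, "explicit_counts", counts = c(32, 16))
  expect_equal(sum(asg$target == "left", na.rm = TRUE), 32)
  expect_equal(sum(asg$target == "right", na.rm = TRUE), 16)
  expect_equal(sum(is.na(asg$target)), 16)
})

test_that("assignment rejects invalid counts and strategies", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9), 0, -50)
  expect_error(assign_elements(arr, tg, "explicit_counts", counts = c(60, 30)),
               class = "tmaes_config_error")
  expect_error(assign_elements(arr, tg, "explicit_counts", counts = c(64, 0)),
               class = "tmaes_config_error")
  expect_error(assign_elements(arr, tg, "custom", mapping = rep("nope", 64)),
               class = "tmaes_config_error")
})

test_that("interleaved assignment round-robins by element index", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("a", "b"))
  asg <- assign_elements(arr, tg, "interleaved")
  expect_equal(asg$target[1:4], c("a", "b", "a", "b"))
  expect_equal(as.integer(table(asg$target)), c(32L, 32L))
})

test_that("time of flight is Euclidean distance over sound speed", {
  expect_equal(time_of_flight(c(0, 0, 0), c(0, 0, -50), 1500),
               33.3333, tolerance = 1e-5)
  expect_equal(time_of_flight(c(-15.75, 15.75, 0), c(9, 0, -50), 1500),
               sqrt(24.75^2 + 15.75^2 + 50^2) * 1000 / 1500)
  expect_equal(round(time_of_flight(c(-15.75, 15.75, 0), c(9, 0, -50), 1500),
                     3), 38.647)
  expect_equal(time_of_flight(c(2.25, 2.25, 0), c(2.25, 2.25, -50), 1500),
               33.3333, tolerance = 1e-5)
  # coincident element and target is valid (zero time)
  expect_equal(time_of_flight(c(1, 2, -3), c(1, 2, -3)), 0)
  expect_error(time_of_flight(c(0, 0, 0), c(0, 0, -50), c0 = -1),
               class = "tmaes_config_error")
})

test_that("delay law: delay + time of flight is constant per target subset", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
  dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
  expect_true(all(dl$delay_us >= 0))
  ref <- attr(dl, "reference_element")
  expect_equal(dl$delay_us[ref], 0)
  expect_equal(dl$tof_us[ref], max(dl$tof_us))
  for (lab in c("left", "right")) {
    arrivals <- dl$delay_us[dl$target == lab] + dl$tof_us[dl$target == lab]
    expect_equal(max(arrivals) - min(arrivals), 0, tolerance = 1e-12)
  }
  # one shared clock: both subsets arrive at the same global instant
  expect_equal(unique(round(dl$delay_us + dl$tof_us, 10)),
               round(max(dl$tof_us), 10))
})

test_that("mirroring targets through x = 0 mirrors the delay map", {
  arr <- build_planar_array(8, 8)
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
  tg_m <- focus_targets(c(9, -9), 0, -50, label = c("left", "right"))
  dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
  dl_m <- compute_delay_law(arr, tg_m, assign_elements(arr, tg_m, "block"))
  # delay at (x, y) in the original equals delay at (-x, y) in the mirror
  key <- paste(dl$x_mm, dl$y_mm)
  key_m <- paste(-dl_m$x_mm, dl_m$y_mm)
  expect_equal(dl$delay_us, dl_m$delay_us[match(key, key_m)])
  # and the symmetric dual config is itself mirror-symmetric
  expect_equal(dl$delay_us, dl$delay_us[match(paste(-dl$x_mm, dl$y_mm), key)])
})

test_that("single-element delay law is zero and empty active sets error", {
  arr <- build_planar_array(1, 1)
  tg <- focus_targets(0, 0, -50)
  dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
  expect_equal(dl$delay_us, 0)
  arr8 <- build_planar_array(8, 8)
  tg2 <- focus_targets(c(-9, 9), 0, -50, label = c("l", "r"))
  asg <- assign_elements(arr8, tg2, "block")
  asg$target[] <- NA_character_
  expect_error(compute_delay_law(arr8, tg2, asg),
               class = "tmaes_config_error")
})

test_that("delay-law export writes the documented CSV schema", {
  arr <- build_planar_array(2, 2)
  tg <- focus_targets(0, 0, -50)
  dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
  p <- withr::local_tempfile(fileext = ".csv")
  export_delay_law(dl, p)
  df <- readr::read_csv(p, show_col_types = FALSE)
  expect_named(df, c("element_index", "x_mm", "y_mm", "target_label",
                     "tof_us", "delay_us"))
  expect_equal(nrow(df), 4)
})
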