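test_that("-3 dB threshold is peak times 10^(-3/20)", {
  vals <- matrix(0.1e6, 21, 21)
  vals[11, 11] <- 2.5e6
  vals[11, 10:12] <- 2.5e6
  f <- matrix_field(vals)
  r <- threshold_mask(f)
  expect_equal(r$threshold, 2.5e6 * 10^(-3 / 20))
  expect_equal(r$threshold, 1.7699e6, tolerance = 1e-4)
  expect_error(threshold_mask(scale_field(f, 0)),
               class = "tmaes_numeric_error")
})

test_that("uniform fields give one all-true component; disjoint spots give two", {
  uni <- matrix_field(matrix(1, 9, 9))
  r <- threshold_mask(uni)
  expect_equal(nrow(r$components), 1)
  expect_equal(nrow(r$cells), 81)

  two <- threshold_mask(gaussian_pair_field())
  expect_equal(nrow(two$components), 2)
  # peaks sit at the set spot centres
  expect_setequal(two$components$peak_x_mm, c(-9, 9))
  expect_equal(two$components$peak_y_mm, c(0, 0))
})

test_that("region area is cell count times step squared", {
  # 65 x 16 rectangle of hot cells at 0.25 mm step -> 1040 cells, 65.0 mm^2
  vals <- matrix(0, 80, 80)
  vals[33:48, 8:72] <- 1
  f <- matrix_field(vals, step_mm = 0.25)
  r <- threshold_mask(f)
  a <- region_area(r)
  expect_equal(sum(a$per_component$n_cells), 1040)
  expect_equal(a$total_mm2, 65.0)
  expect_equal(a$per_component$area_mm2, 65.0)
})

test_that("axis lengths count contiguous runs through the component peak", {
  # elliptical mask 8 x 4 cells at 0.25 mm -> extents (2.0, 1.0) mm
  vals <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (j in 1:20) {
      if (((j - 10.5) / 4)^2 + ((i - 10.5) / 2)^2 <= 1) vals[i, j] <- 1
    }
  }
  vals[10, 10] <- 1.2  # peak inside the ellipse; 1.2 * 10^(-3/20) < 1 keeps
                       # the whole ellipse above threshold
  f <- matrix_field(vals, step_mm = 0.25)
  r <- threshold_mask(f, drop_db = 3)
  ax <- axis_lengths(r)
  expect_equal(ax$long_axis_mm, 2.0)
  expect_equal(ax$short_axis_mm, 1.0)
  expect_true(all(ax$long_axis_mm >= ax$short_axis_mm))

  # circular spot: both extents equal within one grid step
  g <- gaussian_pair_field(x0 = 20, sd_mm = 2, half_mm = 30)
  rg <- threshold_mask(g)
  axg <- axis_lengths(rg, component = rg$components$component[1])
  expect_lte(abs(axg$long_axis_mm - axg$short_axis_mm), 0.5)
})

test_that("separation index matches its defining ratio and edge cases", {
  x <- seq(-20, 20, by = 0.5)
  # complete separation: midline at the minimum
  v1 <- pmax(0.8 * exp(-(abs(x) - 9)^2 / 2), 0.1)
  s1 <- separation_index(tibble::tibble(x_mm = x, value = v1))
  expect_equal(s1$R, 1)
  # merged peaks: midline value is the maximum
  v2 <- exp(-x^2 / 50)
  s2 <- separation_index(tibble::tibble(x_mm = x, value = v2))
  expect_equal(s2$R, 0)
  # generic: R = (Emax - E0) / (Emax - Emin)
  v3 <- exp(-(x - 9)^2 / 8) + exp(-(x + 9)^2 / 8)
  s3 <- separation_index(tibble::tibble(x_mm = x, value = v3))
  expect_equal(s3$R, (max(v3) - v3[x == 0]) / (max(v3) - min(v3)))
  expect_equal(s3$peak_distance_mm, 18, tolerance = 0.5)
  expect_error(
    separation_index(tibble::tibble(x_mm = x, value = rep(1, length(x)))),
    class = "tmaes_numeric_error")
})

test_that("separation index is invariant under affine profile rescaling", {
  x <- seq(-20, 20, by = 0.5)
  v <- exp(-(x - 9)^2 / 8) + exp(-(x + 9)^2 / 8)
  r0 <- separation_index(tibble::tibble(x_mm = x, value = v))$R
  r1 <- separation_index(tibble::tibble(x_mm = x, value = 3.7 * v + 2))$R
  expect_equal(r1, r0)
})

test_that("peak distance needs two components and measures their peaks", {
  r2 <- threshold_mask(gaussian_pair_field())
  expect_equal(peak_distance(r2), 18)
  one <- threshold_mask(gaussian_pair_field(x0 = 1))
  expect_equal(nrow(one$components), 1)
  expect_error(peak_distance(one), class = "tmaes_not_separated")
  expect_error(peak_distance(one), "not separated")
})

test_that("metrics are invariant under positive rescaling of the field", {
  f <- gaussian_pair_field()
  r1 <- threshold_mask(f)
  r2 <- threshold_mask(scale_field(f, 137.4))
  expect_equal(r2$cells[, c("iu", "iv", "component")],
               r1$cells[, c("iu", "iv", "component")])
  expect_equal(region_area(r2)$total_mm2, region_area(r1)$total_mm2)
  expect_equal(axis_lengths(r2), axis_lengths(r1))
  expect_equal(peak_distance(r2), peak_distance(r1))
})

test_that("focal metrics match components to their nearest set target", {
  f <- gaussian_pair_field()
  tg <- focus_targets(c(-9, 9), 0, -50, label = c("left", "right"))
  m <- focal_metrics(f, tg)
  expect_equal(m$per_target$label, c("left", "right"))
  expect_equal(m$per_target$peak_x_mm, c(-9, 9))
  expect_equal(m$per_target$offset_mm, c(0, 0))
  expect_equal(m$total_area_mm2, sum(m$per_target$area_mm2))
  expect_equal(nrow(m$side_lobes), 0)
  g <- glance(m)
  expect_equal(g$n_components, 2)
  expect_equal(g$total_area_mm2, m$total_area_mm2)
})

test_that("per-component thresholding grows each spot from its own peak", {
  # unequal twin spots: the weaker one is larger under its own reference
  x <- seq(-20, 20, by = 0.5)
  df <- tidyr::expand_grid(x_mm = x, y_mm = x)
  df$value <- exp(-((df$x_mm - 9)^2 + df$y_mm^2) / 8) +
    0.8 * exp(-((df$x_mm + 9)^2 + df$y_mm^2) / 8)
  f <- as_field(df, units = "V/m", kind = "synthetic")
  r_glob <- threshold_mask(f, reference = "global")
  r_comp <- threshold_mask(f, reference = "component")
  a_glob <- r_glob$components$area_mm2[order(r_glob$components$peak_x_mm)]
  a_comp <- r_comp$components$area_mm2[order(r_comp$components$peak_x_mm)]
  expect_gt(a_comp[1], a_glob[1])       # weaker (left) spot grows
  expect_equal(a_comp[2], a_glob[2])    # spot holding the global peak fixed
})

test_that("profile extents report -3 dB runs with peaks", {
  x <- seq(-20, 20, by = 0.5)
  v <- exp(-(x - 9)^2 / 8) + exp(-(x + 9)^2 / 8)
  ext <- profile_extents(tibble::tibble(x_mm = x, value = v),
                         threshold = max(v) * 10^(-3 / 20))
  expect_equal(nrow(ext), 2)
  expect_equal(ext$peak_mm, c(-9, 9))
  expect_equal(ext$length_mm[1], ext$length_mm[2])
})

test_that("volume grids are rejected by the region machinery", {
  arr <- build_planar_array(2, 2)
  tg <- focus_targets(0, 0, -50)
  dl <- compute_delay_law(arr, tg, assign_elements(arr, tg, "block"))
  g <- field_grid(x_mm = c(-4, 4), y_mm = c(-4, 4), z_mm = c(-52, -48),
                  step_mm = 2)
  f <- pressure_field(arr, dl, medium(), g)
  expect_error(threshold_mask(f), class = "tmaes_config_error")
})
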