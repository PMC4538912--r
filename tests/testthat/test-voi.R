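test_that("mean dose over masks", {
  d <- voxel_grid(array(0, c(4, 4, 4)))
  d$values[1:32] <- 20 # half the voxels at 20 Gy, half at 0
  all_mask <- array(TRUE, c(4, 4, 4))
  expect_equal(mean_dose(d, all_mask), 10)
  uni <- with_values(d, array(10, c(4, 4, 4)))
  expect_equal(mean_dose(uni, all_mask), 10)
  one <- array(FALSE, c(4, 4, 4)); one[2, 3, 1] <- TRUE
  expect_equal(mean_dose(d, one), d$values[2, 3, 1])
  expect_error(mean_dose(d, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("cumulative DVH: normalisation, shape and mean consistency", {
  set.seed(41)
  d <- voxel_grid(array(rgamma(1000, 2, 0.05), c(10, 10, 10)))
  m <- array(TRUE, c(10, 10, 10))
  h <- dvh(d, m, bin_width_Gy = 0.5)
  expect_equal(h$fraction[1], 1)           # DVH(0) = 1
  expect_true(all(diff(h$fraction) <= 0))  # non-increasing
  expect_equal(h$fraction[nrow(h)], 0)     # 0 above the maximum
  expect_equal(dvh_mean(h), mean_dose(d, m), tolerance = 0.25 / mean_dose(d, m))
  # uniform dose: a step from 1 to 0 at D0
  u <- with_values(d, array(7.3, c(10, 10, 10)))
  hu <- dvh(u, m)
  expect_equal(hu$fraction, as.numeric(hu$dose_Gy <= 7.3))
  expect_error(dvh(d, m, bin_width_Gy = 0), "positive")
})

test_that("interface exclusion removes exact layers on a planar slab", {
  dims <- c(9, 9, 20)
  liver <- array(0, dims); liver[, , 1:10] <- 1
  lung <- array(0, dims); lung[, , 11:20] <- 1
  lv <- voxel_grid(liver, 4.8); lg <- voxel_grid(lung, 4.8)
  ex <- interface_exclusion(lv, lg, 30)
  # centres at 2.4 ... 28.8 mm: exactly 6 layers excluded per side
  expect_equal(sum(ex$excluded_liver$values), 81 * 6)
  expect_equal(sum(ex$excluded_lung$values), 81 * 6)
  expect_equal(sum(ex$remainder_liver$values), 81 * 4)
  # margin 0 excludes nothing
  ex0 <- interface_exclusion(lv, lg, 0)
  expect_equal(ex0$remainder_liver$values, lv$values)
  expect_equal(ex0$remainder_lung$values, lg$values)
  # set contracts
  expect_true(all(ex$remainder_lung$values <= lg$values))
  expect_true(all(ex$remainder_lung$values * ex$excluded_lung$values == 0))
  # monotone shrink with margin
  ex1 <- interface_exclusion(lv, lg, 10)
  ex2 <- interface_exclusion(lv, lg, 20)
  expect_true(all(ex2$remainder_lung$values <= ex1$remainder_lung$values))
  expect_true(all(ex$remainder_lung$values <= ex2$remainder_lung$values))
  # overlapping masks refused; disconnected masks warn
  expect_error(interface_exclusion(lv, lv, 10), "overlap")
  apart <- array(0, dims); apart[, , 15:20] <- 1
  apart[, , 11:14] <- 0
  lg_apart <- voxel_grid(apart, 4.8)
  lv_small <- voxel_grid(array(c(rep(1, 81), rep(0, 81 * 19)), dims), 4.8)
  expect_warning(interface_exclusion(lv_small, lg_apart, 10), "adjacent")
})

test_that("sensitivity regression of original on remainder means", {
  x <- c(10, 20, 30, 40)
  f <- sensitivity_fit(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_equal(f$mean_pct_change, 0)
  f2 <- sensitivity_fit(x, x / 2)
  expect_equal(f2$slope, 2)
  expect_equal(f2$mean_pct_change, -50)
  expect_error(sensitivity_fit(x, x[1:3]), "equal length")
  expect_error(sensitivity_fit(x[1], x[1]), "at least 2")
  expect_error(sensitivity_fit(x, rep(5, 4)), "degenerate")
})

test_that("threshold region growing segments the seeded component only", {
  dims <- c(9, 9, 20)
  rho <- array(1.04, dims)
  rho[, , 11:20] <- 0.26          # lung slab
  rho[1:3, 1:3, 1:3] <- 0.001     # disconnected air pocket
  g <- voxel_grid(rho, 4.8)
  m <- segment_lung_by_threshold(g, c(5, 5, 15), threshold = 0.7)
  expect_equal(sum(m$values), 81 * 10) # the whole lung slab
  expect_equal(sum(m$values[, , 1:10]), 0) # not the air pocket
  m2 <- segment_lung_by_threshold(g, c(2, 2, 2), threshold = 0.7)
  expect_equal(sum(m2$values), 27)
  expect_error(segment_lung_by_threshold(g, c(5, 5, 5), 0.7), "threshold")
  expect_error(segment_lung_by_threshold(g, c(99, 1, 1), 0.7), "bounds")
})
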