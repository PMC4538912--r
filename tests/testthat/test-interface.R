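test_that("make_slab builds the two-compartment phantom exactly", {
  spec <- slab_spec(dims = 21, margin_voxels = 12, total_activity_Bq = 1)
  sl <- make_slab(spec, "liver")
  zc <- axis_coords(sl$activity, 3)
  liver_z <- zc < 0
  # density 1.04 on the liver side, 0.26 on the lung side of z = 0
  i24 <- which.min(abs(zc - 2.4)); im24 <- which.min(abs(zc + 2.4))
  expect_equal(zc[i24], 2.4); expect_equal(zc[im24], -2.4)
  expect_equal(sl$density$values[1, 1, i24], 0.26)
  expect_equal(sl$density$values[1, 1, im24], 1.04)
  # activity: uniform over liver, zero in lung, sums exactly to the total
  a <- sl$activity$values
  expect_equal(sum(a), 1)
  expect_true(all(a[, , !liver_z] == 0))
  av <- unique(as.numeric(a[, , liver_z]))
  expect_length(av, 1)
  sl2 <- make_slab(spec, "lung")
  expect_true(all(sl2$activity$values[, , liver_z] == 0))
  expect_equal(sum(sl2$activity$values), 1)
  expect_error(slab_spec(margin_voxels = 5), "44")
})

test_that("Gaussian blur conserves activity and has the stated width", {
  nn <- 41
  a_v <- array(0, c(nn, nn, nn)); a_v[21, 21, 21] <- 1
  a <- voxel_grid(a_v, 4.8)
  expect_identical(blur_activity(a, 0), a)
  b <- blur_activity(a, 20)
  expect_equal(sum(b$values), 1, tolerance = 1e-6)
  # measured FWHM of the blurred impulse = 20 +- 0.5 mm
  prof <- b$values[, 21, 21]
  x <- ((1:nn) - 21) * 4.8
  half <- max(prof) / 2
  fine <- seq(-30, 30, by = 0.01)
  pf <- approx(x, prof, fine)$y
  width <- diff(range(fine[pf >= half]))
  expect_equal(width, 20, tolerance = 0.025)
  expect_error(blur_activity(a, -1), "non-negative")
})

test_that("LS superposition weights the compartments by definition", {
  d1 <- voxel_grid(array(runif(7^3), c(7, 7, 7)))
  d2 <- voxel_grid(array(runif(7^3), c(7, 7, 7)))
  expect_equal(combine_ls(d1, d2, 0)$values, d1$values)
  expect_equal(combine_ls(d1, d2, 1)$values, d2$values)
  m <- combine_ls(d1, d2, 0.2)
  expect_equal(m$values, 0.8 * d1$values + 0.2 * d2$values)
  expect_error(combine_ls(d1, d2, 1.2), "\\[0, 1\\]")
  # profile linearity: profile of the mix equals the mix of profiles
  p1 <- extract_profile(d1); p2 <- extract_profile(d2)
  expect_equal(extract_profile(m)$value,
               combine_ls(p1, p2, 0.2)$value)
})

test_that("profiles average the central 7x7 column", {
  d <- voxel_grid(array(5, c(9, 9, 4)), 4.8)
  p <- extract_profile(d)
  expect_equal(p$value, rep(5, 4))
  # mirrored dose map gives the mirrored profile
  set.seed(21)
  dv <- array(runif(9 * 9 * 8), c(9, 9, 8))
  pm <- extract_profile(voxel_grid(dv, 4.8))
  pr <- extract_profile(voxel_grid(dv[, , 8:1], 4.8))
  expect_equal(pr$value, rev(pm$value))
  # default slab core yields a 61-point profile
  spec <- slab_spec()
  sl <- make_slab(spec, "liver")
  expect_equal(nrow(extract_profile(sl$density, z_keep = sl$core)), 61)
  expect_error(extract_profile(voxel_grid(array(0, c(5, 5, 5)))), "7x7")
})

test_that("percent difference against a reference profile", {
  p <- data.frame(position_mm = -3:3, value = rep(2, 7))
  expect_equal(percent_difference(p, p)$value, rep(0, 7))
  q <- p; q$value <- 0.25 * p$value
  expect_equal(percent_difference(q, p)$value, rep(-75, 7))
  q$value <- 1.1 * p$value
  expect_equal(percent_difference(q, p)$value, rep(10, 7))
  bad <- p; bad$value[3] <- 0
  expect_error(percent_difference(p, bad), "truth")
})

test_that("agreement intervals cover the compliant regions at 1 mm", {
  pos <- seq(-50.4, 50.4, by = 4.8)
  # exceeds 10% only for positions in (0, 26)
  pd <- data.frame(position_mm = pos,
                   value = ifelse(pos > 0 & pos < 26, 50, 0))
  iv <- agreement_intervals(pd, 10)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$lower_mm[1], -Inf)
  expect_equal(iv$upper_mm[2], Inf)
  # the gap spans the offending region (linear interpolation widens it
  # by less than a voxel on each side)
  expect_lt(iv$upper_mm[1], 1)
  expect_gt(iv$upper_mm[1], -4.8)
  expect_gt(iv$lower_mm[2], 25 - 4.8)
  expect_lt(iv$lower_mm[2], 26 + 4.8)
  # a perfect profile is compliant everywhere
  perfect <- data.frame(position_mm = pos, value = rep(0, length(pos)))
  iv0 <- agreement_intervals(perfect, 10)
  expect_equal(unname(unlist(iv0)), c(-Inf, Inf))
  # monotonicity: compliance at 10% contains compliance at 5%
  set.seed(31)
  noisy <- data.frame(position_mm = pos, value = rnorm(length(pos), 0, 8))
  g <- seq(-50, 50, by = 1)
  a <- approx(pos, abs(noisy$value), g)$y
  expect_true(all((a <= 5) <= (a <= 10)))
  expect_error(agreement_intervals(pd[0, ], 10), "empty")
})

test_that("a reduced interface study obeys the structural invariants", {
  k <- fixture_kernel()
  spec <- slab_spec(dims = 31, fwhm_mm = c(0, 20), ls = c(0.01, 0.2),
                    margin_voxels = 12)
  st <- run_interface_study(spec, k)
  p <- st$profiles
  # truth vs itself: the RT rows at 0 mm FWHM are identically zero
  rt0 <- p[p$engine == "RT" & p$fwhm_mm == 0, ]
  expect_true(all(abs(rt0$pct_diff) < 1e-9))
  # boundaries table covers engines x fwhm x ls
  expect_equal(nrow(st$boundaries), 4 * 2 * 2)
  # LS monotonicity of the truth: deep-lung RT dose increases with LS,
  # deep-liver dose decreases
  deep_lung <- p$engine == "RT" & p$fwhm_mm == 0 & p$position_mm > 50
  deep_liver <- p$engine == "RT" & p$fwhm_mm == 0 & p$position_mm < -50
  d_lung <- tapply(p$dose[deep_lung], p$ls[deep_lung], mean)
  d_liver <- tapply(p$dose[deep_liver], p$ls[deep_liver], mean)
  expect_gt(d_lung[["0.2"]], d_lung[["0.01"]])
  expect_lt(d_liver[["0.2"]], d_liver[["0.01"]])
  # blur monotonicity: the liver-side spill-out deficit grows with FWHM
  at_m7 <- p$engine == "SKD" & p$ls == 0.2 & abs(p$position_mm + 7.2) < 0.01
  expect_lt(p$pct_diff[at_m7 & p$fwhm_mm == 20],
            p$pct_diff[at_m7 & p$fwhm_mm == 0])
  # deep asymptote: SK sits at -75% deep in lung (0.26/1.04 ratio)
  sk_deep <- p$engine == "SK" & p$fwhm_mm == 20 & p$ls == 0.2 &
    p$position_mm >= 45 & p$position_mm <= 60
  expect_equal(mean(p$pct_diff[sk_deep]), -75, tolerance = 0.03)
})
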