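test_that("phantom activity and masks satisfy the construction contracts", {
  spec <- phantom_spec(ls = 0.12, administered_Bq = 2.81e9)
  ph <- generate_phantom(spec)
  a <- ph$activity$values
  expect_equal(sum(a), 2.81e9)
  lung <- ph$masks$lung$values > 0
  expect_equal(sum(a[lung]) / sum(a), 0.12)
  # NL = liver minus tumors, disjoint from tumors
  liver <- ph$masks$liver$values > 0
  nl <- ph$masks$nl$values > 0
  tum <- ph$masks$tumors[[1]]$values > 0
  expect_true(all((tum | nl) == liver))
  expect_equal(sum(nl & tum), 0)
  # uptake ratio 3 before blurring
  expect_equal(a[which(tum)[1]] / a[which(nl)[1]], 3)
  # densities by region
  expect_true(all(ph$density$values[lung] == 0.26))
  expect_true(all(ph$density$values[!lung] == 1.04))
  # a tumor escaping the liver is refused
  bad <- phantom_spec(tumors = data.frame(x_mm = 10, y_mm = 10, z_mm = 10,
                                          radius_mm = 10, uptake = 3))
  expect_error(generate_phantom(bad), "escapes")
})

test_that("imaging chain: identity without blur, conservation, determinism", {
  ph <- generate_phantom(phantom_spec())
  c0 <- simulate_imaging(ph$activity, fwhm_mm = 0, counts_scale = 1e-3)
  expect_equal(c0$values, ph$activity$values * 1e-3)
  cb <- simulate_imaging(ph$activity, fwhm_mm = 20, counts_scale = 1e-3)
  expect_equal(sum(cb$values), sum(ph$activity$values) * 1e-3,
               tolerance = 1e-5)
  n1 <- simulate_imaging(ph$activity, 20, 1e-3, poisson_noise = TRUE,
                         seed = 33)
  n2 <- simulate_imaging(ph$activity, 20, 1e-3, poisson_noise = TRUE,
                         seed = 33)
  expect_identical(n1$values, n2$values)
  expect_error(simulate_imaging(ph$activity, 20, -1), "positive")
})

test_that("self-calibrated local deposition recovers the analytic dose", {
  # noise off, no blur: LD dose in the uniform NL region equals
  # N * E_avg / (rho * dV) exactly
  spec <- phantom_spec(tumors = NULL, ls = 0.1, psf_fwhm_mm = 0)
  ph <- generate_phantom(spec)
  counts <- simulate_imaging(ph$activity, 0, spec$counts_scale)
  act <- counts_to_activity(counts, spec$administered_Bq)
  n <- activity_to_disintegrations(act)
  d <- dose_ld(n, ph$density)
  nl <- which(ph$masks$nl$values > 0)
  a_vox <- 0.9 * spec$administered_Bq / length(nl)
  expected <- a_vox * (64.1 * 3600 / log(2)) * 0.937 /
    (1.04 * 4.8^3 / 1000) * 1.602176e-10
  expect_equal(d$values[nl], rep(expected, length(nl)), tolerance = 1e-9)
})

test_that("cohort generation is deterministic and hits the cohort counts", {
  cs <- cohort_spec(seed = 7)
  co <- generate_cohort(cs)
  expect_length(co$phantoms, 17)
  expect_equal(sum(co$manifest$n_tumors), 31)
  expect_true(all(co$manifest$ls >= 0.01 & co$manifest$ls <= 0.20))
  expect_true(all(co$manifest$administered_GBq >= 1.13 &
                    co$manifest$administered_GBq <= 5.21))
  co2 <- generate_cohort(cs)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$phantoms[[5]]$activity$values,
                   co2$phantoms[[5]]$activity$values)
  expect_identical(co$phantoms[[9]]$counts$values,
                   co2$phantoms[[9]]$counts$values)
  # a different master seed changes the draws
  co3 <- generate_cohort(cohort_spec(seed = 8))
  expect_false(identical(co$manifest$ls, co3$manifest$ls))
  expect_error(cohort_spec(n = 2, total_tumors = 31,
                           tumors_per_phantom = c(1L, 3L)), "unreachable")
})
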