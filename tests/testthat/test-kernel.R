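test_that("radial kernel carries the mean beta energy and 11 mm support", {
  dpk <- fixture_dpk()
  expect_equal(dpk_energy(dpk), 0.937, tolerance = 1e-9)
  expect_equal(dpk$support_mm, 11)
  expect_equal(dpk$rho_ref, 1.04)
  expect_true(all(dpk$phi >= 0))
  # spectrum sanity: mean energy close to the nominal value before
  # renormalisation
  sp <- y90_beta_spectrum()
  expect_equal(sum(sp$E_MeV * sp$weight), 0.937, tolerance = 0.02)
})

test_that("kernel generation is reproducible for a fixed seed", {
  a <- y90_dpk(n_electrons = 2e4, seed = 5)
  b <- y90_dpk(n_electrons = 2e4, seed = 5)
  expect_identical(a$phi, b$phi)
  c <- y90_dpk(n_electrons = 2e4, seed = 6)
  expect_false(identical(a$phi, c$phi))
})

test_that("the bundled table is the generator's own output", {
  regen <- y90_dpk() # defaults match the shipped table
  dpk <- fixture_dpk()
  expect_equal(dpk$phi, regen$phi, tolerance = 1e-7)
  expect_equal(dpk$radius_mm, regen$radius_mm)
})

test_that("range scaling: 11 mm in soft tissue, 44 mm in lung", {
  dpk <- fixture_dpk()
  expect_equal(kernel_support(dpk, 1.04), 11)
  expect_equal(kernel_support(dpk, 0.26), 44)
  expect_equal(kernel_support(dpk, 2.08), 5.5)
  expect_error(kernel_support(dpk, 0), "positive")
  expect_equal(y90_range_mm(0.26), 44)
})

test_that("voxel kernel conserves 0.937 MeV per decay exactly", {
  k <- fixture_kernel()
  expect_equal(kernel_energy(k), 0.937, tolerance = 1e-12)
  # linearity and zero case of the energy diagnostic
  k2 <- k; k2$values <- 2 * k$values
  expect_equal(kernel_energy(k2), 1.874, tolerance = 1e-12)
  k0 <- k; k0$values <- 0 * k$values
  expect_equal(kernel_energy(k0), 0)
})

test_that("voxel kernel is centre-peaked, symmetric, zero outside support", {
  k <- fixture_kernel()
  K <- k$values; hw <- k$hw; n <- 2 * hw + 1
  expect_equal(which.max(K), (hw + 1) + n * hw + n * n * hw)
  for (off in list(c(1, 2, 3), c(3, 1, 0), c(2, 2, 1))) {
    v <- K[hw + 1 + off[1], hw + 1 + off[2], hw + 1 + off[3]]
    expect_identical(K[hw + 1 - off[1], hw + 1 - off[2], hw + 1 - off[3]], v)
    expect_identical(K[hw + 1 + off[3], hw + 1 + off[1], hw + 1 + off[2]], v)
  }
  # voxel-pair support: a kernel voxel is zero when no point of it lies
  # within the support of any point of the source voxel, i.e. beyond
  # support + one full voxel diagonal of centre distance
  idx <- as.matrix(expand.grid(i = -hw:hw, j = -hw:hw, k = -hw:hw))
  d <- sqrt(rowSums(idx^2)) * k$voxel_mm
  far <- d > k$support_mm + k$voxel_mm * sqrt(3)
  expect_true(all(K[idx[far, , drop = FALSE] + hw + 1] == 0))
})

test_that("quadrature matches an independent Monte Carlo integration oracle", {
  # Importance-sampled MC in the source-target separation variable:
  # uniform radius x isotropic direction, weighted by the exact separable
  # tent difference density times 4*pi*r^2*rcut. Bounded integrand, so
  # 1e6 samples give ~0.2% standard error (plain uniform pairs are
  # heavy-tailed through the 1/r^2 kernel and cannot support this
  # comparison).
  dpk <- fixture_dpk()
  k <- fixture_kernel()
  pc <- y90_constants()
  v <- k$voxel_mm
  tent <- function(x) ifelse(abs(x) >= v, 0, (v - abs(x)) / v^2)
  mc_value <- function(off_vox, n = 1e6, seed = 101) {
    with_seed_test(seed, {
      off <- off_vox * v
      rcut <- sqrt(sum(off^2)) + sqrt(3) * v
      r <- runif(n, 0, rcut)
      w <- matrix(rnorm(3 * n), ncol = 3)
      w <- w / sqrt(rowSums(w^2))
      g <- tent(r * w[, 1] - off[1]) * tent(r * w[, 2] - off[2]) *
        tent(r * w[, 3] - off[3])
      mean(dpk_phi(dpk, r) * 4 * pi * r^2 * g * rcut) * pc$gy_per_mev_per_g
    })
  }
  hw <- k$hw
  # pre-normalisation quadrature values, same scale as the oracle
  norm <- kernel_energy(k) / 0.937 # = 1: kernel already normalised
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1))) {
    quad <- k$values[hw + 1 + off[1], hw + 1 + off[2], hw + 1 + off[3]]
    expect_equal(quad, mc_value(off), tolerance = 5e-3)
  }
})

test_that("kernels at 2.4 and 4.8 mm give the same equilibrium dose", {
  dpk <- fixture_dpk()
  k48 <- fixture_kernel()
  k24 <- build_voxel_kernel(dpk, voxel_mm = 2.4, halfwidth_voxels = 5)
  # same activity concentration on both grids
  conc <- 1e3 / 4.8^3 # decays per mm^3
  eq <- function(k, n) {
    g <- voxel_grid(array(conc * k$voxel_mm^3, c(n, n, n)), k$voxel_mm)
    d <- dose_sk(g, k)
    c0 <- floor((n - 1) / 2) + 1
    d$values[c0, c0, c0]
  }
  expect_equal(eq(k24, 21), eq(k48, 11), tolerance = 0.01)
})

test_that("a kernel grid too small for the support is refused", {
  expect_error(build_voxel_kernel(fixture_dpk(), halfwidth_voxels = 2),
               "too small")
  expect_error(build_voxel_kernel(fixture_dpk(), voxel_mm = -1), "positive")
})
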