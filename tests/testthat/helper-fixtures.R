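# Shared fixtures: the bundled radial kernel and the default 4.8 mm voxel
# kernel are built once per test run.
the <- new.env()

fixture_dpk <- function() {
  if (is.null(the$dpk)) the$dpk <- read_dpk()
  the$dpk
}

fixture_kernel <- function() {
  if (is.null(the$kernel)) the$kernel <- build_voxel_kernel(fixture_dpk())
  the$kernel
}

# evaluate code under a fixed seed without disturbing the session RNG
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# uniform cube phantom at a given density
uniform_phantom <- function(n = 21, rho = 1.04, n_per_voxel = 1e3,
                            spacing = 4.8) {
  list(
    n = voxel_grid(array(n_per_voxel, c(n, n, n)), spacing),
    rho = voxel_grid(array(rho, c(n, n, n)), spacing)
  )
}

# centre-region logical mask
centre_mask <- function(n, half = 1) {
  m <- array(FALSE, c(n, n, n))
  c0 <- floor((n - 1) / 2) + 1
  idx <- (c0 - half):(c0 + half)
  m[idx, idx, idx] <- TRUE
  m
}
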