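test_that("mse identities and hand-computed example", {
  set.seed(30)
  x <- matrix(rnorm(100), 10, 10)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  expect_equal(mse(matrix(c(1, 2)), matrix(c(3, 5))), 6.5)
  expect_equal(mse(x, x + 2), 4)
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("ssim is 1 for identical images, symmetric, and bounded", {
  set.seed(31)
  x <- matrix(rnorm(24 * 24, 1, 0.2), 24, 24)
  y <- matrix(rnorm(24 * 24, 1, 0.2), 24, 24)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x))
  for (cand in list(y, -x, 2 * x + 1, matrix(0, 24, 24))) {
    v <- ssim(x, cand)
    expect_gte(v, -1); expect_lte(v, 1)
  }
  expect_error(ssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("ssim of two constant images matches the closed form", {
  L <- 3
  a <- matrix(0, 16, 16); b <- matrix(L, 16, 16)
  c1 <- (0.01 * L)^2
  # means 0 and L, all (co)variances zero: luminance term only
  expected <- (2 * 0 * L + c1) / (0^2 + L^2 + c1)
  expect_equal(ssim(a, b), expected, tolerance = 1e-12)
  expect_equal(ssim(b, b), 1, tolerance = 1e-12)
})

test_that("evaluate_reconstruction scores per band and aggregates by the mean", {
  cube <- random_cube(nb = 5, rows = 20, cols = 20, seed = 32)
  ev <- evaluate_reconstruction(cube, cube, "fused")
  expect_identical(nrow(ev$per_band), 5L)
  expect_true(all(ev$per_band$mse == 0))
  expect_equal(ev$per_band$ssim, rep(1, 5), tolerance = 1e-12)

  noisy <- cube; set.seed(33); noisy$data <- cube$data + rnorm(length(cube$data), sd = 0.05)
  ev2 <- evaluate_reconstruction(cube, noisy, "interpolated")
  expect_equal(ev2$mean_mse, mean(ev2$per_band$mse))
  expect_equal(ev2$mean_ssim, mean(ev2$per_band$ssim))
  expect_identical(unique(ev2$per_band$method), "interpolated")

  other <- cube; other$wavenumbers <- other$wavenumbers + 1
  expect_error(evaluate_reconstruction(cube, other), "wavenumber")
})

test_that("full-sampling sweep hits the additive-noise MSE floor", {
  spec <- tiny_spec(seed = 34)
  sw <- spacing_sweep(spec, 0.5, n_replicates = 1, base_seed = spec$seed,
                      interp = interp_params(Inf),
                      fusion = fusion_params(fusion_depth = 0))
  m <- mean(sw$values$mse)
  # MSE(interp vs clean) at s = 1 is exactly the realized noise power;
  # noise_sd^2 = 1e-4 with relative sd of the mean ~ sqrt(2 / N)
  n_tot <- spec$rows * spec$cols * length(spec$wavenumbers)
  tol <- 3 * sqrt(2 / n_tot) * spec$noise_sd^2
  expect_lt(abs(m - spec$noise_sd^2), tol)
})

test_that("spacing sweeps are reproducible and carry replicate statistics", {
  spec <- tiny_spec(seed = 35)
  sw1 <- spacing_sweep(spec, c(1, 2), n_replicates = 3, base_seed = 35)
  sw2 <- spacing_sweep(spec, c(1, 2), n_replicates = 3, base_seed = 35)
  expect_identical(sw1$values, sw2$values)
  expect_identical(sort(unique(sw1$values$replicate)), 1:3)
  # summary sd is the n-1 denominator sd of the per-replicate band means
  cell <- subset(sw1$values, spacing == 2 & method == "fused")
  rep_means <- tapply(cell$mse, cell$replicate, mean)
  row <- subset(sw1$summary, spacing == 2 & method == "fused")
  expect_equal(row$mse_mean, mean(rep_means))
  expect_equal(row$mse_sd, stats::sd(rep_means))
  expect_true(all(sw1$values$ssim >= -1 & sw1$values$ssim <= 1))
  expect_true(all(sw1$values$mse >= 0))
  expect_error(spacing_sweep(spec, 0.7), "integer")
})
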