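no_window <- interp_params(Inf)

test_that("the Gaussian frequency window has unit DC gain, half gain at f_c, and is even", {
  for (dims in list(c(40, 8), c(41, 8), c(40, 9), c(33, 11))) {
    nh <- dims[1]; nl <- dims[2]
    w <- gaussian_freq_window(nh, nl, interp_params(1))
    k <- seq.int(-floor(nh / 2), ceiling(nh / 2) - 1)
    expect_equal(w[k == 0], 1)
    f_c <- nl / 2
    if (f_c == round(f_c)) expect_equal(w[k == f_c], 0.5)
    common <- intersect(k, -k)
    expect_equal(w[match(common, k)], w[match(-common, k)])
  }
  expect_true(all(gaussian_freq_window(20, 10, no_window) == 1))
})

test_that("upsampling by factor 1 with the window disabled is the identity", {
  set.seed(1)
  x <- matrix(rnorm(15 * 4), 15, 4)
  expect_lt(max(abs(fft_upsample_y(x, 15, no_window) - x)), 1e-10)
})

test_that("constant images stay constant at any target size (DC preservation)", {
  for (nh in c(7, 8, 12, 33)) {
    up <- fft_upsample_y(matrix(2.5, 5, 3), nh)           # window on
    expect_lt(max(abs(up - 2.5)), 1e-10)
    up2 <- fft_upsample_y(matrix(-0.3, 4, 2), nh, no_window)
    expect_lt(max(abs(up2 + 0.3)), 1e-10)
  }
})

test_that("band-limited signals are reproduced exactly (trigonometric interpolant oracle)", {
  # period-4 sine upsampled 4 -> 8 lands on samples of sin(2 pi r / 8)
  up <- fft_upsample_y(matrix(c(0, 1, 0, -1), 4, 1), 8, no_window)
  expect_lt(max(abs(up - sin(2 * pi * (0:7) / 8))), 1e-8)

  # independent oracle: evaluate the DFT interpolant of an odd-length signal
  set.seed(2)
  n <- 5; nh <- 15
  x <- rnorm(n)
  X <- fft(x)
  kk <- c(0:((n - 1) / 2), -((n - 1) / 2):-1)            # DFT bin frequencies
  oracle <- vapply(0:(nh - 1), function(r) {
    t <- r * n / nh
    Re(sum(X * exp(2i * pi * kk * t / n))) / n
  }, 0)
  up <- fft_upsample_y(matrix(x, n, 1), nh, no_window)
  expect_lt(max(abs(up - oracle)), 1e-8)
})

test_that("interpolation is linear and windowing never adds energy", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 6), 8, 6); y <- matrix(rnorm(8 * 6), 8, 6)
    a <- rnorm(1); b <- rnorm(1)
    lhs <- fft_upsample_y(a * x + b * y, 24)
    rhs <- a * fft_upsample_y(x, 24) + b * fft_upsample_y(y, 24)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    up <- fft_upsample_y(x, 24, interp_params(0.8))
    expect_lte(sum(up^2), (24 / 8) * sum(x^2) * (1 + 1e-12))
  }
})

test_that("interpolate_cube restores shape and reduces to the dense cube at s = 1", {
  cube <- random_cube(nb = 4, rows = 30, cols = 16,
                      wavenumbers = c(1036, 1102, 1660, 1746))
  sp <- subsample_y(cube, sampling_scheme(0.5))
  back <- interpolate_cube(sp, no_window)
  expect_identical(back$wavenumbers, cube$wavenumbers)
  expect_lt(max(abs(back$data - cube$data)), 1e-10)
  expect_identical(validate_cube(back), character(0))

  sp5 <- subsample_y(cube, sampling_scheme(2.5))
  up <- interpolate_cube(sp5)
  expect_identical(cube_dims(up), c(4L, 30L, 16L))
})

test_that("reconstruction error grows with the decimation factor", {
  spec <- tiny_spec(seed = 4)
  ph <- generate_phantom(spec)
  err <- vapply(c(2, 10), function(s) {
    sp <- subsample_y(ph$noisy_cube, sampling_scheme(0.5 * s))
    evaluate_reconstruction(ph$clean_cube, interpolate_cube(sp), "i")$mean_mse
  }, 0)
  expect_gt(err[2], err[1])
})

test_that("degenerate target sizes are rejected", {
  expect_error(fft_upsample_y(matrix(0, 8, 2), 4), "rows_hi")
  expect_error(gaussian_freq_window(8, 1), "rows_lo|rows_hi")
})
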