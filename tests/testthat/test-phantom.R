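test_that("phantom generation is a pure function of its spec", {
  spec <- tiny_spec(seed = 7)
  expect_identical(generate_class_map(spec), generate_class_map(spec))
  expect_identical(generate_spectral_library(spec), generate_spectral_library(spec))
  a <- generate_phantom(spec); b <- generate_phantom(spec)
  expect_identical(a$noisy_cube$data, b$noisy_cube$data)
})

test_that("class maps have the requested classes with sane areas", {
  lab2 <- generate_class_map(tiny_spec(n_classes = 2, seed = 1))
  expect_setequal(unique(as.vector(lab2)), 0:1)
  lab3 <- generate_class_map(tiny_spec(n_classes = 3, seed = 5))
  share <- tabulate(lab3 + 1L, 3) / length(lab3)
  expect_true(all(share >= 0.02 & share <= 0.96))
})

test_that("spectral libraries are nonnegative, well-shaped and class-separable", {
  spec <- tiny_spec(seed = 11)
  lib <- generate_spectral_library(spec)
  expect_identical(dim(lib), c(3L, length(tiny_wavenumbers())))
  expect_true(all(lib >= 0))
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(ang(lib[i, ], lib[j, ]), 5)
})

test_that("rendering honors noise and blur settings", {
  spec0 <- tiny_spec(noise_sd = 0, seed = 2)
  ph0 <- generate_phantom(spec0)
  expect_identical(ph0$noisy_cube$data, ph0$clean_cube$data)

  # single-class map without blur renders constant planes
  flat <- tiny_spec(noise_sd = 0, spatial_blur_sigma = 0, seed = 2)
  lib <- generate_spectral_library(flat)
  lab <- matrix(0L, flat$rows, flat$cols)
  tr <- render_hypercube(lab, lib, flat)
  for (b in seq_along(flat$wavenumbers))
    expect_equal(max(tr$clean_cube$data[b, , ]) - min(tr$clean_cube$data[b, , ]), 0)
})

test_that("rendered noise has the prescribed variance", {
  spec <- phantom_spec(rows = 64, cols = 64, wavenumbers = tiny_wavenumbers(),
                       noise_sd = 0.01, seed = 3)
  ph <- generate_phantom(spec)
  resid <- ph$noisy_cube$data - ph$clean_cube$data
  for (b in seq_along(spec$wavenumbers)) {
    v <- stats::var(as.vector(resid[b, , ]))
    expect_gt(v, 0.7e-4); expect_lt(v, 1.3e-4)
  }
})

test_that("subsample_y follows the row convention including the ceil rule", {
  cube <- random_cube(nb = 2, rows = 100, cols = 12, wavenumbers = c(1036, 1660))
  sp <- subsample_y(cube, sampling_scheme(5))
  expect_identical(dim(sp$sparse_bands)[2], 10L)
  expect_identical(sp$sparse_bands[1, 4, ], cube$data[1, 31, ])  # sparse row 3 <-> dense row 30

  cube101 <- random_cube(nb = 2, rows = 101, cols = 12, wavenumbers = c(1036, 1660))
  expect_identical(dim(subsample_y(cube101, sampling_scheme(5))$sparse_bands)[2], 11L)

  sp1 <- subsample_y(cube, sampling_scheme(0.5))
  expect_identical(sp1$sparse_bands[1, , ], cube$data[1, , ])

  expect_error(subsample_y(cube, sampling_scheme(5, reference_wavenumber = 1500)),
               "1500")
})

test_that("sampling_fraction reproduces the acquisition table and is monotone", {
  expect_equal(sampling_fraction(sampling_scheme(5)), 10)
  expect_equal(sampling_fraction(sampling_scheme(20)), 2.5)
  expect_equal(sampling_fraction(sampling_scheme(0.5)), 100)
  fr <- vapply(c(0.5, 1, 2, 5, 10, 20), function(d) sampling_fraction(sampling_scheme(d)), 0)
  expect_true(all(diff(fr) < 0))
})

test_that("acquisition time follows the row-proportional model", {
  # dense limit: all bands at full resolution
  expect_equal(acquisition_time_estimate(sampling_scheme(0.5), 28, 3000, 0.03),
               0.03 * 3000 * 28)
  # a single band is the full-resolution reference; decimation does not touch it
  expect_equal(acquisition_time_estimate(sampling_scheme(1), 1, 3000, 0.03),
               0.03 * 3000)
  # two bands at factor 2: reference plus one half-row band
  expect_equal(acquisition_time_estimate(sampling_scheme(1), 2, 3000, 0.03),
               0.03 * (3000 + 1500))
  t_sparse <- acquisition_time_estimate(sampling_scheme(5), 28, 3000, 0.03)
  t_dense <- acquisition_time_estimate(sampling_scheme(0.5), 28, 3000, 0.03)
  # 28 bands at s = 10: (1 + 2.7)/28 of the dense time
  expect_equal(t_sparse / t_dense, (3000 + 27 * 300) / (28 * 3000))
  expect_equal(t_sparse / t_dense, 0.1321, tolerance = 1e-3)
})
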