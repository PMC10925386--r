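#' Default O-PTIR discrete-frequency band set
#'
#' The 28 wavenumbers used throughout the package: 27 fingerprint-region
#' bands between 908 and 1786 cm^-1 plus the Amide I reference band at
#' 1660 cm^-1, sorted ascending.
#'
#' @return numeric vector of 28 wavenumbers (cm^-1).
#' @export
optir_wavenumbers <- function() {
  sort(c(908, 974, 984, 1036, 1070, 1102, 1136, 1178, 1238, 1280, 1300,
         1325, 1358, 1396, 1420, 1456, 1482, 1500, 1536, 1556, 1596, 1610,
         1662, 1668, 1682, 1746, 1786, 1660))
}

#' Synthetic tissue-core phantom specification
#'
#' Parameters of the synthetic tissue microarray core used to exercise the
#' reconstruction pipeline with known ground truth: piecewise-constant
#' class regions (epithelium-, stroma- and necrosis-like) with organic blob
#' boundaries, per-class absorbance spectra, spatial blur and additive
#' Gaussian noise. Phantom generation is a pure function of this spec
#' (seed included).
#'
#' @param rows,cols image size in pixels (>= 32 each).
#' @param n_classes number of tissue classes (>= 2; default 3).
#' @param wavenumbers band set; defaults to [optir_wavenumbers()].
#' @param boundary_smoothness correlation length of class boundaries in
#'   micrometres (larger = larger, smoother blobs).
#' @param spatial_blur_sigma optical blur of the rendered planes, in pixels.
#' @param noise_sd additive i.i.d. Gaussian noise, absorbance units.
#' @param dx,dy pixel pitch in micrometres.
#' @param seed integer RNG seed; fixed seed gives fully reproducible output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 96, cols = 96, n_classes = 3,
                         wavenumbers = optir_wavenumbers(),
                         boundary_smoothness = 8, spatial_blur_sigma = 1,
                         noise_sd = 0.01, dx = 0.5, dy = 0.5, seed = 1) {
  if (rows < 32 || cols < 32) stopf("phantom must be at least 32 x 32 (got %d x %d)", rows, cols)
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 n_classes = as.integer(n_classes),
                 wavenumbers = as.numeric(wavenumbers),
                 boundary_smoothness = boundary_smoothness,
                 spatial_blur_sigma = spatial_blur_sigma,
                 noise_sd = noise_sd, dx = dx, dy = dy,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom class label map
#'
#' Smoothed white noise thresholded at class-count quantiles yields
#' connected, organically shaped class blobs reminiscent of tissue-core
#' morphology. Each class must occupy at least 2% of pixels; degenerate
#' draws are retried internally (bounded), advancing the stream
#' deterministically.
#'
#' @param spec a [phantom_spec()].
#' @return integer matrix `rows x cols` with labels `0 .. n_classes - 1`.
#' @export
generate_class_map <- function(spec) {
  sigma_px <- max(spec$boundary_smoothness / spec$dx, 0.5)
  with_seed(stage_seed(spec$seed, "class_map"), {
    for (attempt in 1:20) {
      z <- blur_gaussian(matrix(stats::rnorm(spec$rows * spec$cols),
                                spec$rows, spec$cols), sigma_px)
      q <- stats::quantile(z, probs = seq_len(spec$n_classes - 1) / spec$n_classes)
      lab <- matrix(findInterval(z, q), spec$rows, spec$cols)
      share <- tabulate(lab + 1L, nbins = spec$n_classes) / length(lab)
      if (min(share) >= 0.02) return(lab)
    }
    stopf("could not draw a class map with every class >= 2%% of pixels in 20 attempts")
  })
}

#' Generate a per-class spectral library
#'
#' Each class spectrum is a nonnegative sum of Gaussian absorbance peaks:
#' a shared tissue base spectrum (amide I ~1660, amide II ~1545,
#' carbohydrate ~1036 cm^-1, ...) scaled by a class-specific gain, plus
#' 3-6 smaller class-specific peaks. The shared base reproduces the strong
#' inter-band spatial correlation of real tissue absorbance (all bands are
#' dominated by common protein content), which is the premise of
#' reference-band fusion; the class peaks provide the discriminative
#' chemistry. Pairwise spectral angles between classes are at least 5
#' degrees so classes are separable; draws violating that are retried
#' deterministically.
#'
#' @param spec a [phantom_spec()].
#' @return matrix `[n_classes, n_bands]` of nonnegative absorbances.
#' @export
generate_spectral_library <- function(spec) {
  centers_pool <- c(1036, 1080, 1160, 1240, 1310, 1400, 1455, 1545, 1660, 1740)
  wn <- spec$wavenumbers
  base_ctr <- c(1036, 1080, 1240, 1396, 1456, 1545, 1660, 1740)
  base_hgt <- c(0.35, 0.30, 0.35, 0.30, 0.25, 0.60, 1.00, 0.18)
  base_wid <- c(30, 35, 40, 35, 30, 38, 42, 25)
  base <- colSums(base_hgt * exp(-outer(base_ctr, wn, `-`)^2 / (2 * base_wid^2)))
  draw_one <- function() {
    gain <- stats::runif(1, 0.75, 1.25)
    n_pk <- sample(3:6, 1)
    ctr <- sample(centers_pool, n_pk) + stats::runif(n_pk, -15, 15)
    hgt <- stats::runif(n_pk, 0.08, 0.30)
    wid <- stats::runif(n_pk, 20, 50)
    sp <- gain * base
    for (p in seq_len(n_pk)) sp <- sp + hgt[p] * exp(-(wn - ctr[p])^2 / (2 * wid[p]^2))
    sp
  }
  spectral_angle <- function(a, b)
    acos(min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
  with_seed(stage_seed(spec$seed, "spectral_library"), {
    for (attempt in 1:50) {
      lib <- t(vapply(seq_len(spec$n_classes), function(i) draw_one(), numeric(length(wn))))
      angles <- utils::combn(spec$n_classes, 2, function(ij)
        spectral_angle(lib[ij[1], ], lib[ij[2], ]))
      if (all(angles >= 5)) return(lib)
    }
    stopf("could not draw a spectral library with pairwise angles >= 5 degrees")
  })
}

#' Render a phantom into clean and noisy hypercubes
#'
#' The clean cube's band `b` is the Gaussian-blurred plane of per-pixel
#' library lookups `library[label[r, c], b]`; the noisy cube adds seeded
#' i.i.d. Gaussian noise of sd `spec$noise_sd`.
#'
#' @param label_map integer class map from [generate_class_map()].
#' @param library spectral library from [generate_spectral_library()].
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth`: list with `label_map`,
#'   `clean_cube` and `noisy_cube`.
#' @export
render_hypercube <- function(label_map, library, spec) {
  if (max(label_map) + 1L > nrow(library))
    stopf("label map uses class %d but library has %d classes", max(label_map), nrow(library))
  nb <- length(spec$wavenumbers)
  clean <- array(0, c(nb, nrow(label_map), ncol(label_map)))
  for (b in seq_len(nb)) {
    plane <- matrix(library[label_map + 1L, b], nrow(label_map), ncol(label_map))
    clean[b, , ] <- blur_gaussian(plane, spec$spatial_blur_sigma)
  }
  noisy <- clean
  if (spec$noise_sd > 0)
    noisy <- clean + with_seed(stage_seed(spec$seed, "noise"),
                               array(stats::rnorm(length(clean), sd = spec$noise_sd), dim(clean)))
  structure(list(label_map = label_map,
                 clean_cube = hyper_cube(clean, spec$wavenumbers, spec$dx, spec$dy),
                 noisy_cube = hyper_cube(noisy, spec$wavenumbers, spec$dx, spec$dy)),
            class = "phantom_truth")
}

#' Generate a complete phantom (class map, spectra, cubes)
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth` (see [render_hypercube()]) with the spectral
#'   library attached as attribute `"library"`.
#' @export
generate_phantom <- function(spec) {
  lab <- generate_class_map(spec)
  lib <- generate_spectral_library(spec)
  out <- render_hypercube(lab, lib, spec)
  attr(out, "library") <- lib
  out
}

#' Decimate a cube along y, keeping one full-resolution reference band
#'
#' Simulates the sparse interleaved acquisition: every band except the
#' reference keeps only rows `0, s, 2s, ...` (0-based; row 0 retained, last
#' partial stride kept).
#'
#' @param cube a dense [hyper_cube()].
#' @param scheme a [sampling_scheme()]; `scheme$reference_wavenumber` must
#'   be a band of `cube`.
#' @return a [sparse_cube()].
#' @export
subsample_y <- function(cube, scheme) {
  ref <- extract_band(cube, scheme$reference_wavenumber)  # errors if absent
  d <- cube_dims(cube)
  keep_rows <- seq.int(1L, d[2], by = scheme$s)
  others <- setdiff(seq_len(n_bands(cube)), match(scheme$reference_wavenumber, cube$wavenumbers))
  sb <- array(0, c(length(others), length(keep_rows), d[3]))
  for (i in seq_along(others)) sb[i, , ] <- cube$data[others[i], keep_rows, ]
  sparse_cube(ref, sb, cube$wavenumbers[others], scheme)
}

#' Percentage of data acquired under a sparse scheme
#'
#' Relative to full-resolution acquisition of the same field of view
#' (x sampling unchanged): `100 * dy_hi / dy_lo`. At the recommended
#' 0.5 x 5 um spacing this is 10%.
#'
#' @param scheme a [sampling_scheme()].
#' @return percent of pixels collected per non-reference band.
#' @export
sampling_fraction <- function(scheme) 100 * scheme$dy_hi / scheme$dy_lo

#' Linear acquisition-time model for a sparse scan
#'
#' Raster-scan imaging time is proportional to the number of acquired
#' rows: one band (the reference) at full resolution plus `n_bands - 1`
#' bands at `ceil(rows_hi / s)` rows each. A pure linear model with a
#' per-row calibration constant; instrument overheads are outside it.
#'
#' @param scheme a [sampling_scheme()].
#' @param n_bands total number of bands including the reference.
#' @param rows_hi full-resolution row count.
#' @param row_time minutes per full-resolution row (calibration input).
#' @return estimated minutes.
#' @export
acquisition_time_estimate <- function(scheme, n_bands, rows_hi, row_time) {
  if (!isTRUE(row_time > 0)) stopf("row_time must be > 0")
  row_time * (rows_hi + (n_bands - 1) * ceiling(rows_hi / scheme$s))
}
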