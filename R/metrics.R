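#' SSIM parameters
#'
#' Standard structural-similarity constants: 11 x 11 Gaussian window with
#' sigma 1.5 (normalized to sum 1), stabilizers `c1 = (k1 * L)^2`,
#' `c2 = (k2 * L)^2` with `k1 = 0.01`, `k2 = 0.03`. The dynamic range `L`
#' defaults to the pooled range of the two images being compared (which
#' keeps the score symmetric); [evaluate_reconstruction()] passes the
#' ground-truth band's range explicitly so the score cannot be gamed by
#' range inflation.
#'
#' @param window_size odd window side in pixels.
#' @param window_sigma Gaussian sigma of the window, pixels.
#' @param k1,k2 stabilizer constants, > 0.
#' @param dynamic_range `L`, or `NULL` to use the pooled range.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(window_size = 11, window_sigma = 1.5,
                        k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  if (!isTRUE(k1 > 0) || !isTRUE(k2 > 0)) stopf("k1 and k2 must be > 0")
  if (window_size %% 2 != 1) stopf("window_size must be odd")
  structure(list(window_size = as.integer(window_size),
                 window_sigma = window_sigma, k1 = k1, k2 = k2,
                 dynamic_range = dynamic_range),
            class = "ssim_params")
}

#' Mean squared error between two images
#'
#' @param a,b matrices (or arrays) of identical shape.
#' @return mean over pixels of `(a - b)^2`.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stopf("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
          paste(dim(b), collapse = "x"))
  mean((a - b)^2)
}

#' Structural similarity index (mean local SSIM)
#'
#' Windowed luminance/contrast/structure similarity in [-1, 1], 1 iff the
#' images are identical. Local statistics use the Gaussian window of
#' `params`, computed in valid mode (borders where the window does not
#' fully fit are excluded).
#'
#' @param a,b matrices of identical shape, at least as large as the window.
#' @param params an [ssim_params()].
#' @return scalar mean SSIM.
#' @export
ssim <- function(a, b, params = ssim_params()) {
  if (!identical(dim(a), dim(b)))
    stopf("shape mismatch: %s vs %s", paste(dim(a), collapse = "x"),
          paste(dim(b), collapse = "x"))
  if (min(dim(a)) < params$window_size)
    stopf("image %s smaller than the %d x %d SSIM window",
          paste(dim(a), collapse = "x"), params$window_size, params$window_size)
  r <- (params$window_size - 1L) %/% 2L
  k <- gaussian_kernel1d(params$window_sigma, r)
  L <- params$dynamic_range %||% diff(range(c(a, b)))
  if (L <= 0) L <- 1  # identical constant images: stabilizers carry the score
  c1 <- (params$k1 * L)^2
  c2 <- (params$k2 * L)^2
  f <- function(m) conv_sep(m, k, mode = "valid")
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Per-band MSE/SSIM report for a reconstruction
#'
#' Scores every band of `candidate` against the matching band of `truth`
#' (wavenumbers must agree exactly) and aggregates with unweighted band
#' means. The SSIM dynamic range is taken from the truth band.
#'
#' @param truth ground-truth [hyper_cube()] (typically the clean phantom).
#' @param candidate reconstructed or interpolated [hyper_cube()].
#' @param method label stored in the report rows (e.g. `"interpolated"`,
#'   `"fused"`).
#' @param params an [ssim_params()].
#' @param joint if `TRUE`, additionally score the full cubes jointly as a
#'   single image stack (one extra attribute `"joint"`).
#' @return list with `per_band` (data frame `wavenumber`, `method`, `mse`,
#'   `ssim`), `mean_mse`, `mean_ssim`.
#' @export
evaluate_reconstruction <- function(truth, candidate, method = "fused",
                                    params = ssim_params(), joint = FALSE) {
  if (!isTRUE(all.equal(truth$wavenumbers, candidate$wavenumbers)))
    stopf("wavenumber mismatch between truth and candidate")
  d <- cube_dims(truth)
  if (!identical(cube_dims(candidate), d)) stopf("cube shape mismatch")
  rows <- lapply(seq_len(d[1]), function(b) {
    tb <- matrix(truth$data[b, , ], d[2], d[3])
    cb <- matrix(candidate$data[b, , ], d[2], d[3])
    p <- params; p$dynamic_range <- max(diff(range(tb)), .Machine$double.eps)
    data.frame(wavenumber = truth$wavenumbers[b], method = method,
               mse = mse(tb, cb), ssim = ssim(tb, cb, p))
  })
  per_band <- do.call(rbind, rows)
  out <- list(per_band = per_band,
              mean_mse = mean(per_band$mse), mean_ssim = mean(per_band$ssim))
  if (joint) {
    flat_t <- matrix(aperm(truth$data, c(2, 1, 3)), d[2] * d[1], d[3])
    flat_c <- matrix(aperm(candidate$data, c(2, 1, 3)), d[2] * d[1], d[3])
    p <- params; p$dynamic_range <- max(diff(range(flat_t)), .Machine$double.eps)
    out$joint <- data.frame(mse = mse(flat_t, flat_c), ssim = ssim(flat_t, flat_c, p))
  }
  out
}

#' Pixel-spacing sweep: reconstruction quality vs y spacing
#'
#' For each replicate phantom (seeds `base_seed + 0 .. n_replicates - 1`)
#' and each y pixel spacing: generate the phantom, decimate the noisy cube,
#' interpolate, fuse, and score both candidates against the clean truth.
#' Mirrors the MSE/SSIM-versus-spacing experiment used to pick the
#' operating point (0.5 x 5 um).
#'
#' @param spec a [phantom_spec()] (its `seed` is overridden per replicate).
#' @param spacings y spacings in micrometres; each must be an integer
#'   multiple of `spec$dy`.
#' @param n_replicates number of replicate phantoms (default 4).
#' @param base_seed first replicate seed (default `spec$seed`).
#' @param interp an [interp_params()].
#' @param fusion a [fusion_params()].
#' @param reference_wavenumber full-resolution band (default 1660).
#' @return object of class `sweep_result`: list with `values` (long data
#'   frame: `replicate`, `spacing`, `wavenumber`, `method`, `mse`, `ssim`)
#'   and `summary` (mean and sd over replicates of the per-replicate band
#'   means, by spacing and method; sd uses denominator n - 1).
#' @export
spacing_sweep <- function(spec, spacings, n_replicates = 4,
                          base_seed = spec$seed,
                          interp = interp_params(), fusion = fusion_params(),
                          reference_wavenumber = 1660) {
  for (sp in spacings)
    if (abs(sp / spec$dy - round(sp / spec$dy)) > 1e-9)
      stopf("spacing %g um is not an integer multiple of dy = %g um", sp, spec$dy)
  vals <- list()
  for (i in seq_len(n_replicates)) {
    rspec <- spec; rspec$seed <- as.integer(base_seed + i - 1)
    ph <- generate_phantom(rspec)
    for (sp in spacings) {
      scheme <- sampling_scheme(dy_lo = sp, dx_hi = spec$dx, dy_hi = spec$dy,
                                reference_wavenumber = reference_wavenumber)
      sparse <- subsample_y(ph$noisy_cube, scheme)
      ic <- interpolate_cube(sparse, interp)
      fc <- reconstruct_cube(sparse, fusion, interp)
      for (cand in list(list(cube = ic, method = "interpolated"),
                        list(cube = fc, method = "fused"))) {
        ev <- evaluate_reconstruction(ph$clean_cube, cand$cube, cand$method)
        pb <- ev$per_band
        pb$replicate <- i
        pb$spacing <- sp
        vals[[length(vals) + 1L]] <- pb
      }
    }
  }
  values <- do.call(rbind, vals)[, c("replicate", "spacing", "wavenumber",
                                     "method", "mse", "ssim")]
  rep_means <- stats::aggregate(cbind(mse, ssim) ~ replicate + spacing + method,
                                values, mean)
  summary <- do.call(rbind, lapply(split(rep_means,
                                         rep_means[c("spacing", "method")]),
    function(g) data.frame(spacing = g$spacing[1], method = g$method[1],
                           mse_mean = mean(g$mse), mse_sd = stats::sd(g$mse),
                           ssim_mean = mean(g$ssim), ssim_sd = stats::sd(g$ssim))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$method, summary$spacing), ]
  structure(list(values = values, summary = summary,
                 n_replicates = n_replicates, base_seed = base_seed),
            class = "sweep_result")
}
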