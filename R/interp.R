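#' Fourier interpolation parameters
#'
#' Controls the Gaussian frequency window applied after zero-padding a
#' y-decimated band image in the Fourier domain. The window is anchored to
#' the low-resolution sampling rate: it falls to gain 0.5 at
#' `window_half_gain_fraction * (rows_lo / 2)` (i.e. a fraction of the
#' low-resolution Nyquist index). `Inf` disables the window. Amplitude
#' normalization is fixed to `rows_hi / rows_lo` so the mean absorbance
#' (DC) is preserved and spectra stay quantitative.
#'
#' @param window_half_gain_fraction positive number (default 1); `Inf`
#'   disables windowing.
#' @return an object of class `interp_params`.
#' @export
interp_params <- function(window_half_gain_fraction = 1) {
  if (!isTRUE(window_half_gain_fraction > 0))
    stopf("window_half_gain_fraction must be > 0")
  structure(list(window_half_gain_fraction = window_half_gain_fraction),
            class = "interp_params")
}

#' Gaussian window over centered y-frequencies
#'
#' `w(k) = exp(-k^2 / (2 sigma^2))` over the centered frequency index
#' `k = -floor(rows_hi/2) .. ceil(rows_hi/2) - 1`, with `sigma` chosen so
#' that the gain is exactly 0.5 at the half-gain frequency
#' `f_c = window_half_gain_fraction * rows_lo / 2`. `w(0) = 1` (DC
#' untouched) and the window is even.
#'
#' @param rows_hi padded (output) row count.
#' @param rows_lo low-resolution (input) row count, `2 <= rows_lo <= rows_hi`.
#' @param params an [interp_params()].
#' @return numeric vector of length `rows_hi`, indexed by centered frequency.
#' @export
gaussian_freq_window <- function(rows_hi, rows_lo, params = interp_params()) {
  if (rows_lo < 2 || rows_hi < rows_lo)
    stopf("need rows_hi >= rows_lo >= 2 (got %d, %d)", rows_hi, rows_lo)
  k <- centered_freqs(rows_hi)
  if (!is.finite(params$window_half_gain_fraction)) return(rep(1, rows_hi))
  f_c <- params$window_half_gain_fraction * rows_lo / 2
  sigma <- f_c / sqrt(2 * log(2))
  exp(-k^2 / (2 * sigma^2))
}

#' Upsample a band image along y by Fourier zero-padding
#'
#' Per column: forward FFT along y, center the spectrum, zero-pad
#' symmetrically to `rows_hi`, multiply by the Gaussian frequency window,
#' inverse FFT, rescale by `rows_hi / rows_lo`, take the real part. For an
#' even `rows_lo` the Nyquist bin is split half/half into the +/- Nyquist
#' positions of the padded spectrum so real inputs map to real outputs.
#'
#' @param band_lo low-resolution matrix (`rows_lo x cols`).
#' @param rows_hi target row count (`>= rows_lo`).
#' @param params an [interp_params()].
#' @return matrix `rows_hi x cols`.
#' @export
fft_upsample_y <- function(band_lo, rows_hi, params = interp_params()) {
  n_lo <- nrow(band_lo)
  if (rows_hi < n_lo) stopf("rows_hi (%d) < rows_lo (%d)", rows_hi, n_lo)
  if (n_lo < 2) stopf("need at least 2 low-resolution rows")
  X <- stats::mvfft(band_lo)                       # freq order 0, 1, ..., n_lo-1
  k_lo <- centered_freqs(n_lo)                     # centered order
  Xc <- X[fftshift_vec_idx(n_lo), , drop = FALSE]  # rows now follow k_lo
  k_hi <- centered_freqs(rows_hi)
  Y <- matrix(0i, rows_hi, ncol(band_lo))
  idx <- match(k_lo, k_hi)
  Y[idx, ] <- Xc
  if (rows_hi > n_lo && n_lo %% 2 == 0) {
    # split the Nyquist bin (k = -n_lo/2) between -n_lo/2 and +n_lo/2
    nyq_src <- match(-n_lo / 2, k_hi)
    nyq_dst <- match(+n_lo / 2, k_hi)
    Y[nyq_dst, ] <- Y[nyq_src, ] / 2
    Y[nyq_src, ] <- Y[nyq_src, ] / 2
  }
  w <- gaussian_freq_window(rows_hi, n_lo, params)
  Y <- Y * w
  y <- stats::mvfft(Y[ifftshift_vec_idx(rows_hi), , drop = FALSE], inverse = TRUE) / n_lo
  resid <- max(abs(Im(y))) / max(max(abs(y)), .Machine$double.eps)
  if (is.complex(band_lo) == FALSE && resid > 1e-8)
    stopf("interpolation residual imaginary part %.2e exceeds 1e-8 of signal", resid)
  matrix(Re(y), rows_hi, ncol(band_lo))
}

#' Interpolate every sparse band to the reference grid
#'
#' Upsamples each y-decimated band to the reference band's row count by
#' [fft_upsample_y()] and reassembles a dense cube; the full-resolution
#' reference band is copied through unchanged.
#'
#' @param sparse a [sparse_cube()].
#' @param params an [interp_params()].
#' @return a dense [hyper_cube()] (bands ascending, reference included).
#' @export
interpolate_cube <- function(sparse, params = interp_params()) {
  rows_hi <- nrow(sparse$reference_band)
  cols <- ncol(sparse$reference_band)
  wn_all <- sort(c(sparse$wavenumbers, sparse$scheme$reference_wavenumber))
  out <- array(0, c(length(wn_all), rows_hi, cols))
  for (i in seq_along(sparse$wavenumbers)) {
    up <- fft_upsample_y(matrix(sparse$sparse_bands[i, , ],
                                dim(sparse$sparse_bands)[2], cols),
                         rows_hi, params)
    out[match(sparse$wavenumbers[i], wn_all), , ] <- up
  }
  out[match(sparse$scheme$reference_wavenumber, wn_all), , ] <- sparse$reference_band
  hyper_cube(out, wn_all, sparse$scheme$dx_hi, sparse$scheme$dy_hi)
}
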