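# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
fftshift_vec_idx <- function(n) {
  # index order that moves the zero-frequency bin to position floor(n/2)+1
  s <- ceiling(n / 2)
  c((s + 1L):n, 1L:s)
}

ifftshift_vec_idx <- function(n) {
  s <- floor(n / 2)
  c((s + 1L):n, 1L:s)
}

fftshift2 <- function(m) m[fftshift_vec_idx(nrow(m)), fftshift_vec_idx(ncol(m)), drop = FALSE]

ifftshift2 <- function(m) m[ifftshift_vec_idx(nrow(m)), ifftshift_vec_idx(ncol(m)), drop = FALSE]

# centered frequency indices -floor(n/2) .. ceil(n/2)-1, in fftshifted order
centered_freqs <- function(n) seq.int(-floor(n / 2), ceiling(n / 2) - 1L)

# unitary 2-D FFT pair (Parseval holds without extra factors)
ufft2 <- function(m) stats::fft(m) / sqrt(length(m))

uifft2 <- function(m) stats::fft(m, inverse = TRUE) / sqrt(length(m))

#' Evaluate an expression with a local, restored RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic small-integer seed derived from a base seed and a stage name
stage_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 1009 + h) %% .Machine$integer.max)
}

gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect ("symmetric") padding along both axes
pad_reflect <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  ri <- c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, m), 1:m, pmax(m - seq_len(r) + 1L, 1L))
  img[ri, ci, drop = FALSE]
}

# separable convolution with a symmetric 1-D kernel; "same" output with
# reflect padding, or "valid" output (borders cropped)
conv_sep <- function(img, kernel, mode = c("same", "valid")) {
  mode <- match.arg(mode)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(img)
  work <- if (mode == "same") pad_reflect(img, r) else img
  cols <- apply(work, 2L, function(v) stats::convolve(v, kernel, type = "filter"))
  if (!is.matrix(cols)) cols <- matrix(cols, nrow = 1L)
  rows <- t(apply(cols, 1L, function(v) stats::convolve(v, kernel, type = "filter")))
  if (nrow(cols) == 1L) rows <- matrix(rows, nrow = 1L)
  rows
}

# Gaussian blur, sigma in pixels; sigma <= 0 is the identity
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel1d(sigma), mode = "same")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
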