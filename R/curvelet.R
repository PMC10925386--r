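#' Curvelet transform parameters
#'
#' Configuration for the tight-frame discrete curvelet transform used by
#' the fusion step: number of dyadic scales, the orientation count at the
#' second-coarsest scale (doubling every second scale toward finer
#' scales), and whether the finest scale is an isotropic wavelet ring
#' (default, avoids directional boundary artifacts at the highest
#' frequencies) or a full curvelet scale.
#'
#' @param n_scales integer >= 2, or `NULL` to use
#'   `max(2, ceil(log2(min(rows, cols))) - 3)` for the image at hand.
#' @param n_angles_coarse orientations at the second-coarsest scale;
#'   multiple of 4 (default 16). Orientations come in antipodal wedge
#'   pairs; a pair represents one spatial orientation.
#' @param finest_scale_type `"wavelet"` (default) or `"curvelet"`.
#' @return an object of class `curvelet_params`.
#' @export
curvelet_params <- function(n_scales = NULL, n_angles_coarse = 16,
                            finest_scale_type = c("wavelet", "curvelet")) {
  finest_scale_type <- match.arg(finest_scale_type)
  if (!is.null(n_scales) && (!is_count(n_scales) || n_scales < 2))
    stopf("n_scales must be an integer >= 2")
  if (!is_count(n_angles_coarse) || n_angles_coarse %% 4 != 0 || n_angles_coarse < 4)
    stopf("n_angles_coarse must be a positive multiple of 4")
  structure(list(n_scales = n_scales, n_angles_coarse = as.integer(n_angles_coarse),
                 finest_scale_type = finest_scale_type),
            class = "curvelet_params")
}

# Meyer auxiliary polynomial: C^3 step from 0 at t<=0 to 1 at t>=1
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# complementary radial transition pair at boundary B (transition on [B/2, B]);
# low^2 + high^2 == 1 exactly
radial_low <- function(rho, B) cos(pi / 2 * meyer_nu((rho - B / 2) / (B / 2)))
radial_high <- function(rho, B) sin(pi / 2 * meyer_nu((rho - B / 2) / (B / 2)))

# squared angular partition: sqrt of telescoping Meyer steps; wedge l of n
# is centered at -pi + (l-1) * 2*pi/n with support width 2 * (2*pi/n)
angular_window <- function(theta, l, n) {
  delta <- 2 * pi / n
  ctr <- -pi + (l - 1) * delta
  d <- (theta - ctr + pi) %% (2 * pi) - pi
  p <- numeric(length(theta))
  up <- d >= -delta & d < 0
  dn <- d >= 0 & d <= delta
  p[up] <- meyer_nu((d[up] + delta) / delta)
  p[dn] <- 1 - meyer_nu(d[dn] / delta)
  sqrt(pmax(p, 0))
}

orientations_at_scale <- function(j, J, params) {
  # scale 1 is the isotropic low-pass; finest scale isotropic iff wavelet type
  if (j == 1) return(1L)
  if (j == J && params$finest_scale_type == "wavelet") return(1L)
  as.integer(params$n_angles_coarse * 2^((j - 2) %/% 2))
}

resolve_curvelet_params <- function(shape, params) {
  J <- params$n_scales %||% max(2L, as.integer(ceiling(log2(min(shape))) - 3L))
  if (min(shape) < 2^(J + 1))
    stopf("image %d x %d too small for %d curvelet scales (minimum size %d)",
          shape[1], shape[2], J, 2^(J + 1))
  list(n_scales = as.integer(J), n_angles_coarse = params$n_angles_coarse,
       finest_scale_type = params$finest_scale_type)
}

.fdct_cache <- new.env(parent = emptyenv())

# Frequency tiling plan: per wedge, the window values restricted to the
# wedge's bounding box in the centered frequency grid. The windows form an
# exact squared partition of unity, so analysis followed by synthesis is
# the identity and coefficient energy equals image energy (tight frame).
fdct_plan <- function(shape, rp) {
  key <- paste(shape[1], shape[2], rp$n_scales, rp$n_angles_coarse,
               rp$finest_scale_type, sep = "|")
  if (!is.null(.fdct_cache[[key]])) return(.fdct_cache[[key]])
  n1 <- shape[1]; n2 <- shape[2]; J <- rp$n_scales
  w1 <- centered_freqs(n1) / (n1 / 2)   # row (y) frequency in [-1, 1)
  w2 <- centered_freqs(n2) / (n2 / 2)   # col (x) frequency in [-1, 1)
  rho <- outer(abs(w1), abs(w2), pmax)  # concentric-square radius
  theta <- atan2(outer(w1, rep(1, n2)), outer(rep(1, n1), w2))
  B <- 2^(-(J - seq_len(J - 1)))        # dyadic boundaries, B[J-1] = 1/2
  scales <- vector("list", J)
  for (j in seq_len(J)) {
    Wj <- if (j == 1) radial_low(rho, B[1])
          else if (j < J) radial_high(rho, B[j - 1]) * radial_low(rho, B[j])
          else radial_high(rho, B[J - 1])
    n_or <- orientations_at_scale(j, J, rp)
    wedges <- vector("list", n_or)
    for (l in seq_len(n_or)) {
      U <- if (n_or == 1L) Wj else Wj * angular_window(theta, l, n_or)
      nz <- which(U > 1e-12, arr.ind = TRUE)
      if (nrow(nz) == 0)
        stopf("empty curvelet wedge (scale %d, orientation %d): too many angles for a %d x %d image",
              j, l, n1, n2)
      bbox <- c(min(nz[, 1]), max(nz[, 1]), min(nz[, 2]), max(nz[, 2]))
      wedges[[l]] <- list(U = U[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE],
                          bbox = bbox)
    }
    scales[[j]] <- wedges
  }
  plan <- list(shape = shape, rp = rp, scales = scales)
  .fdct_cache[[key]] <- plan
  plan
}

#' Forward fast discrete curvelet transform
#'
#' Frequency-domain implementation: the image's 2-D spectrum is multiplied
#' by smooth Meyer-style polar wedge windows whose squares form an exact
#' partition of unity (tight frame), each windowed wedge is cropped to its
#' rectangular frequency support and inverse-transformed to give complex
#' coefficients. Deterministic; non-square and non-power-of-two sizes are
#' handled directly.
#'
#' @param image real matrix, at least 32 x 32, finite values.
#' @param params a [curvelet_params()].
#' @return an object of class `curvelet_coeffs`: `pyramid[[j]][[l]]` holds
#'   the complex coefficient matrix of scale `j` (1 = coarsest) and
#'   orientation `l`, plus `shape` and resolved `params`.
#' @export
fdct_forward <- function(image, params = curvelet_params()) {
  if (!is.matrix(image) || min(dim(image)) < 32)
    stopf("image must be a matrix of at least 32 x 32 pixels")
  if (any(!is.finite(image))) stopf("image contains non-finite values")
  rp <- resolve_curvelet_params(dim(image), params)
  plan <- fdct_plan(dim(image), rp)
  Fq <- fftshift2(ufft2(image))
  pyramid <- lapply(plan$scales, function(wedges) {
    lapply(wedges, function(w) {
      b <- w$bbox
      uifft2(w$U * Fq[b[1]:b[2], b[3]:b[4], drop = FALSE])
    })
  })
  structure(list(pyramid = pyramid, shape = dim(image), params = rp),
            class = "curvelet_coeffs")
}

#' @export
print.curvelet_coeffs <- function(x, ...) {
  no <- vapply(x$pyramid, length, 1L)
  cat(sprintf("<curvelet_coeffs> %d x %d image, %d scales (orientations: %s), finest = %s\n",
              x$shape[1], x$shape[2], length(no), paste(no, collapse = ", "),
              x$params$finest_scale_type))
  invisible(x)
}

#' Inverse fast discrete curvelet transform
#'
#' Exact inverse of [fdct_forward()] under the tight-frame normalization:
#' each coefficient block is transformed back to its frequency support,
#' re-windowed, accumulated, and inverse-transformed to the recorded image
#' shape.
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @return real matrix of the recorded shape.
#' @export
fdct_inverse <- function(coeffs) {
  if (!inherits(coeffs, "curvelet_coeffs")) stopf("not a curvelet_coeffs object")
  plan <- fdct_plan(coeffs$shape, coeffs$params)
  if (length(coeffs$pyramid) != length(plan$scales))
    stopf("coefficient pyramid has %d scales; plan expects %d",
          length(coeffs$pyramid), length(plan$scales))
  acc <- matrix(0i, coeffs$shape[1], coeffs$shape[2])
  for (j in seq_along(plan$scales)) {
    if (length(coeffs$pyramid[[j]]) != length(plan$scales[[j]]))
      stopf("scale %d has %d orientations; plan expects %d",
            j, length(coeffs$pyramid[[j]]), length(plan$scales[[j]]))
    for (l in seq_along(plan$scales[[j]])) {
      w <- plan$scales[[j]][[l]]
      b <- w$bbox
      cf <- coeffs$pyramid[[j]][[l]]
      if (!identical(dim(cf), dim(w$U)))
        stopf("coefficient block (scale %d, orientation %d) is %s; plan expects %s",
              j, l, paste(dim(cf), collapse = "x"), paste(dim(w$U), collapse = "x"))
      acc[b[1]:b[2], b[3]:b[4]] <- acc[b[1]:b[2], b[3]:b[4]] + w$U * ufft2(cf)
    }
  }
  Re(uifft2(ifftshift2(acc)))
}

#' Split curvelet coefficients into low- and high-frequency parts
#'
#' The `depth` finest scales go to the high part, everything else to the
#' low part; both parts stay structurally complete with zero-filled
#' placeholders, and `low + high` reassembles the input exactly.
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @param depth integer in `0 .. n_scales`.
#' @return list with elements `low` and `high` (both `curvelet_coeffs`).
#' @export
split_by_scale <- function(coeffs, depth) {
  J <- length(coeffs$pyramid)
  if (!is_count(depth) || depth < 0 || depth > J)
    stopf("depth must be an integer in 0 .. %d (got %s)", J, format(depth))
  zero_like <- function(scale) lapply(scale, function(m) matrix(0i, nrow(m), ncol(m)))
  low <- coeffs; high <- coeffs
  for (j in seq_len(J)) {
    if (j > J - depth) low$pyramid[[j]] <- zero_like(coeffs$pyramid[[j]])
    else high$pyramid[[j]] <- zero_like(coeffs$pyramid[[j]])
  }
  list(low = low, high = high)
}

#' Total squared magnitude of curvelet coefficients
#'
#' Under the tight-frame normalization this equals the image energy
#' (Parseval identity).
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @param scale optional scale index (1 = coarsest) to restrict to.
#' @return scalar sum of `|coefficient|^2`.
#' @export
coeff_energy <- function(coeffs, scale = NULL) {
  scales <- if (is.null(scale)) seq_along(coeffs$pyramid) else scale
  sum(vapply(scales, function(j)
    sum(vapply(coeffs$pyramid[[j]], function(m) sum(Mod(m)^2), 0)), 0))
}
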