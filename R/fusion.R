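#' Curvelet fusion parameters
#'
#' Controls how interpolated bands are sharpened against the
#' full-resolution reference band: the number of finest curvelet scales
#' substituted from the (equalized) reference, and the equalization mode.
#' `fusion_depth = NULL` resolves to `ceil(log2(s))` for decimation factor
#' `s` (at least 1, and at most `n_scales - 1` so the coarsest scale — and
#' with it the band's mean absorbance — always comes from the interpolated
#' band).
#'
#' @param fusion_depth integer >= 0, or `NULL` for the default above.
#' @param equalization `"affine_lsq"` (least-squares affine match of the
#'   reference to each band, the default) or `"off"`.
#' @param curvelet a [curvelet_params()].
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(fusion_depth = NULL,
                          equalization = c("affine_lsq", "off"),
                          curvelet = curvelet_params()) {
  equalization <- match.arg(equalization)
  if (!is.null(fusion_depth) && (!is_count(fusion_depth) || fusion_depth < 0))
    stopf("fusion_depth must be an integer >= 0")
  structure(list(fusion_depth = fusion_depth, equalization = equalization,
                 curvelet = curvelet),
            class = "fusion_params")
}

default_fusion_depth <- function(s, n_scales) {
  min(max(1L, as.integer(ceiling(log2(max(s, 2))))), n_scales - 1L)
}

#' Least-squares affine equalization of the reference band
#'
#' Finds gain `a` and offset `b` minimizing `sum((a * ref + b - target)^2)`
#' over all pixels, so the reference band is brought onto the target
#' band's intensity scale before its high-frequency content is borrowed.
#' A constant reference gives `a = 0`, `b = mean(target)`.
#'
#' @param reference_band,target_band matrices of identical shape.
#' @return list with `equalized` (matrix `a * ref + b`), `a`, `b`.
#' @export
affine_equalize <- function(reference_band, target_band) {
  if (!identical(dim(reference_band), dim(target_band)))
    stopf("shape mismatch: reference %s vs target %s",
          paste(dim(reference_band), collapse = "x"),
          paste(dim(target_band), collapse = "x"))
  mr <- mean(reference_band); mt <- mean(target_band)
  vr <- mean((reference_band - mr)^2)
  if (vr == 0) {
    a <- 0; b <- mt
  } else {
    a <- mean((reference_band - mr) * (target_band - mt)) / vr
    b <- mt - a * mr
  }
  list(equalized = a * reference_band + b, a = a, b = b)
}

#' Sharpen one interpolated band with the reference band's high frequencies
#'
#' Pipeline: equalize the reference to the interpolated band, take the
#' curvelet transform of both, keep the low scales of the interpolated
#' band and the `fusion_depth` finest scales of the equalized reference,
#' and invert. With `fusion_depth = 0` this reduces to the transform
#' round trip of the interpolated band.
#'
#' @param interp_band interpolated band matrix (full-resolution grid).
#' @param reference_band full-resolution reference matrix, same shape.
#' @param params a [fusion_params()]; a `NULL` `fusion_depth` defaults to 1
#'   here (use [reconstruct_cube()] to derive it from the decimation factor).
#' @return fused band matrix, same shape; equalization coefficients are
#'   attached as attributes `"a"` and `"b"`.
#' @export
sharpen_band <- function(interp_band, reference_band, params = fusion_params()) {
  if (!identical(dim(interp_band), dim(reference_band)))
    stopf("shape mismatch: interpolated %s vs reference %s",
          paste(dim(interp_band), collapse = "x"),
          paste(dim(reference_band), collapse = "x"))
  eq <- if (params$equalization == "affine_lsq")
    affine_equalize(reference_band, interp_band)
  else list(equalized = reference_band, a = 1, b = 0)
  ci <- fdct_forward(interp_band, params$curvelet)
  depth <- params$fusion_depth %||% 1L
  depth <- min(depth, length(ci$pyramid))
  if (depth == 0) {
    out <- fdct_inverse(ci)
  } else {
    cr <- fdct_forward(eq$equalized, params$curvelet)
    parts_i <- split_by_scale(ci, depth)
    parts_r <- split_by_scale(cr, depth)
    fused <- parts_i$low
    for (j in seq_along(fused$pyramid))
      for (l in seq_along(fused$pyramid[[j]]))
        fused$pyramid[[j]][[l]] <- fused$pyramid[[j]][[l]] + parts_r$high$pyramid[[j]][[l]]
    out <- fdct_inverse(fused)
  }
  attr(out, "a") <- eq$a
  attr(out, "b") <- eq$b
  out
}

#' Reconstruct a full-resolution cube from a sparse acquisition
#'
#' Runs [interpolate_cube()] and then sharpens every non-reference band
#' against the full-resolution reference via [sharpen_band()]. The
#' reference band passes through bit-identical. Per-band equalization
#' coefficients are attached as attribute `"equalization"` (data frame
#' with `wavenumber`, `a`, `b`).
#'
#' @param sparse a [sparse_cube()].
#' @param params a [fusion_params()]; `fusion_depth = NULL` resolves to
#'   `ceil(log2(s))` clamped to `n_scales - 1`.
#' @param interp an [interp_params()].
#' @return a dense [hyper_cube()].
#' @export
reconstruct_cube <- function(sparse, params = fusion_params(),
                             interp = interp_params()) {
  interp_cube <- interpolate_cube(sparse, interp)
  ref <- sparse$reference_band
  rp <- resolve_curvelet_params(dim(ref), params$curvelet)
  depth <- params$fusion_depth %||% default_fusion_depth(sparse$scheme$s, rp$n_scales)
  band_params <- fusion_params(fusion_depth = depth,
                               equalization = params$equalization,
                               curvelet = params$curvelet)
  out <- interp_cube
  eqlog <- data.frame(wavenumber = numeric(0), a = numeric(0), b = numeric(0))
  for (i in seq_len(n_bands(interp_cube))) {
    wn <- interp_cube$wavenumbers[i]
    if (wn == sparse$scheme$reference_wavenumber) next
    fused <- sharpen_band(matrix(interp_cube$data[i, , ], nrow(ref), ncol(ref)),
                          ref, band_params)
    out$data[i, , ] <- fused
    eqlog <- rbind(eqlog, data.frame(wavenumber = wn,
                                     a = attr(fused, "a"), b = attr(fused, "b")))
  }
  attr(out, "equalization") <- eqlog
  out
}
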