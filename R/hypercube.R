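#' Hyperspectral absorbance cube
#'
#' A `hyper_cube` is the dense band stack of a mid-IR spectroscopic image:
#' absorbance planes indexed `[band, row, col]` together with the band
#' wavenumbers and the pixel pitch in x and y. Images follow a top-left
#' origin, row-major convention: row indices increase downward and sparse
#' row `i` (0-based) corresponds to full-resolution row `i * s`.
#'
#' @param data numeric array `[band, row, col]`, or a list of band matrices
#'   (one per wavenumber). A list with inconsistent plane shapes is stored
#'   as-is so that [validate_cube()] can report the violation.
#' @param wavenumbers numeric vector of band centers in cm^-1, expected
#'   strictly ascending (checked by [validate_cube()], not here).
#' @param dx,dy pixel pitch in micrometres along x (columns) and y (rows).
#' @return an object of class `hyper_cube`.
#' @seealso [validate_cube()], [extract_band()], [subsample_y()]
#' @export
hyper_cube <- function(data, wavenumbers, dx = 0.5, dy = 0.5) {
  if (is.list(data)) {
    shapes <- unique(lapply(data, dim))
    if (length(shapes) == 1L && length(data) == length(wavenumbers)) {
      arr <- array(0, c(length(data), shapes[[1]][1], shapes[[1]][2]))
      for (b in seq_along(data)) arr[b, , ] <- data[[b]]
      data <- arr
    }
  }
  structure(
    list(data = data, wavenumbers = as.numeric(wavenumbers),
         dx = as.numeric(dx), dy = as.numeric(dy)),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- cube_dims(x)
  cat(sprintf("<hyper_cube> %d bands, %d x %d px, dx = %g um, dy = %g um\n",
              d[1], d[2], d[3], x$dx, x$dy))
  cat(sprintf("  wavenumbers: %g .. %g cm^-1\n",
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Cube dimensions and band count
#'
#' @param cube a [hyper_cube()].
#' @return `cube_dims()`: integer vector `(bands, rows, cols)`;
#'   `n_bands()`: number of bands.
#' @export
cube_dims <- function(cube) {
  if (is.array(cube$data)) dim(cube$data)
  else c(length(cube$data), dim(cube$data[[1]]))
}

#' @rdname cube_dims
#' @export
n_bands <- function(cube) length(cube$wavenumbers)

#' Validate a hyperspectral cube
#'
#' Checks every `hyper_cube` invariant and reports violations as
#' human-readable strings; validation never raises.
#'
#' @param cube a [hyper_cube()].
#' @return character vector of violations; `character(0)` iff the cube is
#'   well formed. Absorbance values of magnitude above 5 are reported as
#'   suspicious (noise can dip slightly negative; |A| > 5 is not plausible
#'   tissue absorbance).
#' @export
validate_cube <- function(cube) {
  v <- character(0)
  planes <- if (is.array(cube$data)) dim(cube$data)[1] else length(cube$data)
  if (length(cube$wavenumbers) != planes)
    v <- c(v, sprintf("number of wavenumbers (%d) != number of band planes (%d)",
                      length(cube$wavenumbers), planes))
  if (!is.array(cube$data)) {
    shapes <- vapply(cube$data, function(p) paste(dim(p), collapse = "x"), "")
    bad <- which(shapes != shapes[1])
    if (length(bad))
      v <- c(v, sprintf("band plane(s) %s have shape %s, expected %s",
                        paste(bad, collapse = ", "),
                        paste(unique(shapes[bad]), collapse = ", "), shapes[1]))
  }
  if (length(cube$wavenumbers) > 1 && any(diff(cube$wavenumbers) <= 0))
    v <- c(v, sprintf("wavenumbers not strictly ascending (first offender at index %d)",
                      which(diff(cube$wavenumbers) <= 0)[1] + 1L))
  if (!isTRUE(cube$dx > 0)) v <- c(v, sprintf("dx must be > 0 (got %g)", cube$dx))
  if (!isTRUE(cube$dy > 0)) v <- c(v, sprintf("dy must be > 0 (got %g)", cube$dy))
  vals <- if (is.array(cube$data)) cube$data else unlist(cube$data)
  if (any(!is.finite(vals)))
    v <- c(v, "non-finite absorbance values present")
  else if (any(abs(vals) > 5))
    v <- c(v, sprintf("suspicious absorbance magnitude: max |A| = %.3g exceeds 5", max(abs(vals))))
  v
}

#' Extract one band plane by wavenumber
#'
#' @param cube a [hyper_cube()].
#' @param wavenumber band center in cm^-1; must match a cube band exactly.
#' @return the 2-D absorbance matrix `[row, col]` for that band.
#' @export
extract_band <- function(cube, wavenumber) {
  i <- match(wavenumber, cube$wavenumbers)
  if (is.na(i))
    stopf("wavenumber %g cm^-1 not present in cube (available: %g .. %g over %d bands; exact match required)",
          wavenumber, min(cube$wavenumbers), max(cube$wavenumbers), n_bands(cube))
  if (is.array(cube$data)) cube$data[i, , ] else cube$data[[i]]
}

#' Sparse y-interleaved sampling scheme
#'
#' Describes the acquisition geometry: full-resolution pitch (`dx_hi`,
#' `dy_hi`), the sparse y pitch `dy_lo` used for all bands except the
#' reference, and the full-resolution reference band (Amide I, 1660 cm^-1,
#' by default). The decimation factor `s = dy_lo / dy_hi` must be a whole
#' number.
#'
#' @param dy_lo sparse y pitch in micrometres for non-reference bands.
#' @param dx_hi,dy_hi full-resolution pixel pitch in micrometres.
#' @param reference_wavenumber wavenumber (cm^-1) of the band acquired at
#'   full resolution.
#' @return an object of class `sampling_scheme` with the integer decimation
#'   factor in `$s`.
#' @export
sampling_scheme <- function(dy_lo, dx_hi = 0.5, dy_hi = 0.5,
                            reference_wavenumber = 1660) {
  if (!isTRUE(dy_hi > 0) || !isTRUE(dx_hi > 0)) stopf("pixel pitches must be > 0")
  if (!isTRUE(dy_lo >= dy_hi)) stopf("dy_lo (%g) must be >= dy_hi (%g)", dy_lo, dy_hi)
  s <- dy_lo / dy_hi
  if (abs(s - round(s)) > 1e-9)
    stopf("dy_lo / dy_hi = %g is not an integer decimation factor", s)
  structure(list(dx_hi = dx_hi, dy_hi = dy_hi, dy_lo = dy_lo,
                 reference_wavenumber = reference_wavenumber,
                 s = as.integer(round(s))),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme> %g x %g um target, dy_lo = %g um (s = %d), reference %g cm^-1\n",
              x$dx_hi, x$dy_hi, x$dy_lo, x$s, x$reference_wavenumber))
  invisible(x)
}

#' Sparse cube: full-resolution reference band + y-decimated bands
#'
#' @param reference_band full-resolution reference matrix (`rows_hi x cols`).
#' @param sparse_bands array `[band, rows_lo, cols]` of decimated planes.
#' @param wavenumbers wavenumbers of the sparse bands (cm^-1, ascending).
#' @param scheme a [sampling_scheme()].
#' @return an object of class `sparse_cube`. Sparse row `i` (0-based)
#'   corresponds to full-resolution row `i * s`; `rows_lo = ceil(rows_hi/s)`
#'   so the final partial stride is retained.
#' @export
sparse_cube <- function(reference_band, sparse_bands, wavenumbers, scheme) {
  rows_hi <- nrow(reference_band)
  rows_lo <- dim(sparse_bands)[2]
  expect_lo <- ceiling(rows_hi / scheme$s)
  if (rows_lo != expect_lo)
    stopf("sparse bands have %d rows; expected ceil(%d / %d) = %d",
          rows_lo, rows_hi, scheme$s, expect_lo)
  if (dim(sparse_bands)[3] != ncol(reference_band))
    stopf("sparse bands have %d columns; reference has %d",
          dim(sparse_bands)[3], ncol(reference_band))
  if (dim(sparse_bands)[1] != length(wavenumbers))
    stopf("%d sparse planes for %d wavenumbers", dim(sparse_bands)[1], length(wavenumbers))
  structure(list(reference_band = reference_band, sparse_bands = sparse_bands,
                 wavenumbers = as.numeric(wavenumbers), scheme = scheme),
            class = "sparse_cube")
}

#' @export
print.sparse_cube <- function(x, ...) {
  cat(sprintf("<sparse_cube> reference %d x %d px at %g cm^-1; %d sparse bands %d x %d px (s = %d)\n",
              nrow(x$reference_band), ncol(x$reference_band),
              x$scheme$reference_wavenumber, dim(x$sparse_bands)[1],
              dim(x$sparse_bands)[2], dim(x$sparse_bands)[3], x$scheme$s))
  invisible(x)
}
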