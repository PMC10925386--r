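# Hyperspectral cube, label-map and report I/O.
#
# ENVI: .hdr text header + .dat binary, BSQ interleave, 32-bit little-endian
# float (exact float32 round trip). TIFF: one page per band; because baseline
# TIFF writers in R quantize samples to [0,1] integers, each band is stored
# as 32-bit unsigned ints with an affine scale/offset recorded in the JSON
# sidecar (round-trip accuracy ~2e-10 of the band range, i.e. better than
# single precision). Wavenumbers and pixel pitch travel in the .hdr (ENVI)
# or the sidecar (TIFF).

envi_paths <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

tiff_paths <- function(path) {
  base <- sub("\\.(tif|tiff)$", "", path)
  list(tif = paste0(base, ".tif"), json = paste0(base, ".json"))
}

#' Write a hyperspectral cube to ENVI or TIFF
#'
#' ENVI writes a `.hdr`/`.dat` pair (BSQ, 32-bit little-endian float);
#' TIFF writes a multi-page `.tif` (one page per band) plus a `.json`
#' sidecar carrying wavenumbers, pixel pitch and per-band scaling. Both
#' are read back by [read_cube()] with value round trip at (better than)
#' 32-bit float precision.
#'
#' @param cube a valid [hyper_cube()].
#' @param path output path; the extension may be omitted.
#' @param format `"envi"` or `"tiff"`.
#' @return the primary file path, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  v <- validate_cube(cube)
  v <- v[!grepl("suspicious", v)]
  if (length(v)) stopf("refusing to write invalid cube: %s", v[1])
  d <- cube_dims(cube)
  if (format == "envi") {
    p <- envi_paths(path)
    hdr <- c("ENVI",
             "description = {sparseptir hyperspectral cube}",
             sprintf("samples = %d", d[3]),
             sprintf("lines = %d", d[2]),
             sprintf("bands = %d", d[1]),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 4",
             "interleave = bsq",
             "byte order = 0",
             "wavelength units = Wavenumber (cm-1)",
             sprintf("pixel size x um = %.10g", cube$dx),
             sprintf("pixel size y um = %.10g", cube$dy),
             sprintf("wavelength = {%s}",
                     paste(sprintf("%.10g", cube$wavenumbers), collapse = ", ")))
    writeLines(hdr, p$hdr)
    con <- file(p$dat, "wb")
    on.exit(close(con))
    for (b in seq_len(d[1]))                    # BSQ: band-major, line-major
      writeBin(as.vector(t(cube$data[b, , ])), con, size = 4L, endian = "little")
    return(invisible(p$dat))
  }
  p <- tiff_paths(path)
  pages <- vector("list", d[1])
  offset <- scale <- numeric(d[1])
  for (b in seq_len(d[1])) {
    plane <- matrix(cube$data[b, , ], d[2], d[3])
    offset[b] <- min(plane)
    rng <- max(plane) - min(plane)
    scale[b] <- if (rng > 0) rng else 1
    pages[[b]] <- (plane - offset[b]) / scale[b]
  }
  tiff::writeTIFF(pages, p$tif, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(wavenumbers = cube$wavenumbers, dx = cube$dx, dy = cube$dy,
         band_offset = offset, band_scale = scale, encoding = "uint32-affine"),
    p$json, auto_unbox = TRUE, digits = NA)
  invisible(p$tif)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # collapse brace-delimited values to single lines, then split key = value
  txt <- gsub("\\{([^}]*)\\}", "{\\1}", txt)
  for (m in regmatches(txt, gregexpr("[a-zA-Z][a-zA-Z0-9 ()_-]*=\\s*(\\{[^}]*\\}|[^\n]*)", txt))[[1]]) {
    kv <- regmatches(m, regexec("^([^=]+)=\\s*(.*)$", m))[[1]]
    key <- trimws(kv[2]); val <- trimws(kv[3])
    fields[[tolower(key)]] <- val
  }
  fields
}

envi_numlist <- function(s) as.numeric(strsplit(gsub("[{}]", "", s), ",")[[1]])

#' Read a hyperspectral cube from ENVI or TIFF
#'
#' Bands are reordered to ascending wavenumber on load if needed; the
#' returned cube passes [validate_cube()].
#'
#' @param path path written by [write_cube()] (extension optional).
#' @param format `"envi"` or `"tiff"`.
#' @return a [hyper_cube()].
#' @export
read_cube <- function(path, format = c("envi", "tiff")) {
  format <- match.arg(format)
  if (format == "envi") {
    p <- envi_paths(path)
    if (!file.exists(p$hdr)) stopf("missing ENVI header %s", p$hdr)
    h <- parse_envi_header(p$hdr)
    for (need in c("samples", "lines", "bands", "data type", "interleave"))
      if (is.null(h[[need]])) stopf("ENVI header lacks '%s'", need)
    if (as.integer(h[["data type"]]) != 4L) stopf("only float32 ENVI (data type 4) supported")
    if (tolower(h[["interleave"]]) != "bsq") stopf("only BSQ interleave supported")
    if (is.null(h[["wavelength"]])) stopf("ENVI header lacks wavelength metadata")
    ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
    nb <- as.integer(h[["bands"]])
    wn <- envi_numlist(h[["wavelength"]])
    if (length(wn) != nb) stopf("header lists %d wavelengths for %d bands", length(wn), nb)
    raw <- readBin(p$dat, numeric(), n = ns * nl * nb, size = 4L, endian = "little")
    if (length(raw) != ns * nl * nb)
      stopf("ENVI data file has %d values; header promises %d", length(raw), ns * nl * nb)
    arr <- array(0, c(nb, nl, ns))
    for (b in seq_len(nb))
      arr[b, , ] <- matrix(raw[((b - 1) * ns * nl + 1):(b * ns * nl)], nl, ns, byrow = TRUE)
    dx <- as.numeric(h[["pixel size x um"]] %||% "1")
    dy <- as.numeric(h[["pixel size y um"]] %||% "1")
  } else {
    p <- tiff_paths(path)
    if (!file.exists(p$json)) stopf("missing TIFF sidecar %s", p$json)
    meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
    pages <- tiff::readTIFF(p$tif, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    wn <- as.numeric(meta$wavenumbers)
    if (length(pages) != length(wn))
      stopf("TIFF has %d pages but sidecar lists %d wavenumbers", length(pages), length(wn))
    shapes <- unique(lapply(pages, dim))
    if (length(shapes) != 1) stopf("TIFF pages have mismatched shapes")
    arr <- array(0, c(length(pages), shapes[[1]][1], shapes[[1]][2]))
    for (b in seq_along(pages))
      arr[b, , ] <- pages[[b]] * meta$band_scale[b] + meta$band_offset[b]
    dx <- meta$dx; dy <- meta$dy
  }
  ord <- order(wn)
  cube <- hyper_cube(arr[ord, , , drop = FALSE], wn[ord], dx, dy)
  v <- validate_cube(cube)
  v <- v[!grepl("suspicious", v)]
  if (length(v)) stopf("file yielded an invalid cube: %s", v[1])
  cube
}

#' Write a label map as integer TIFF + JSON sidecar
#'
#' Single-page 8-bit TIFF; the sidecar maps class index to name and RGB
#' channel (red = epithelium, green = stroma, blue = necrosis by default).
#'
#' @param label_map integer matrix, labels `0 .. 255`.
#' @param path output path (`.tif` extension optional).
#' @param class_names optional character vector of class names.
#' @return the TIFF path, invisibly.
#' @export
write_label_map <- function(label_map, path, class_names = NULL) {
  p <- tiff_paths(path)
  if (max(label_map) > 255 || min(label_map) < 0) stopf("labels must be in 0 .. 255")
  n <- max(label_map) + 1L
  class_names <- class_names %||%
    c("epithelium", "stroma", "necrosis", paste0("class", seq_len(max(0, n - 3)) + 2L))[seq_len(n)]
  tiff::writeTIFF(label_map / 255, p$tif, bits.per.sample = 8L, compression = "none")
  pal <- class_palette(n)
  jsonlite::write_json(
    list(classes = data.frame(index = seq_len(n) - 1L, name = class_names,
                              r = pal[, 1], g = pal[, 2], b = pal[, 3])),
    p$json, digits = NA)
  invisible(p$tif)
}

#' Read a label map written by [write_label_map()]
#' @param path path to the TIFF (extension optional).
#' @return integer label matrix with the class table as attribute `"classes"`.
#' @export
read_label_map <- function(path) {
  p <- tiff_paths(path)
  lab <- tiff::readTIFF(p$tif, as.is = TRUE)
  if (file.exists(p$json))
    attr(lab, "classes") <- jsonlite::read_json(p$json, simplifyVector = TRUE)$classes
  lab
}

#' Write a per-band quality report as CSV
#'
#' Columns `wavenumber,method,mse,ssim`; floats keep full precision.
#'
#' @param rows data frame with those columns (zero rows allowed).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  cols <- c("wavenumber", "method", "mse", "ssim")
  if (nrow(rows) && !all(cols %in% names(rows)))
    stopf("report must have columns %s", paste(cols, collapse = ", "))
  if (nrow(rows) == 0) rows <- data.frame(wavenumber = numeric(0), method = character(0),
                                          mse = numeric(0), ssim = numeric(0))
  out <- rows[, cols, drop = FALSE]
  for (nm in c("wavenumber", "mse", "ssim")) out[[nm]] <- sprintf("%.10g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a report CSV written by [write_report()]
#' @param path CSV path.
#' @return data frame `wavenumber`, `method`, `mse`, `ssim`.
#' @export
read_report <- function(path) {
  utils::read.csv(path, colClasses = c(wavenumber = "numeric", method = "character",
                                       mse = "numeric", ssim = "numeric"))
}

#' Write a sparse cube as a directory
#'
#' Layout: `reference.(hdr|dat|tif)` (single-band cube), `bands.*` (the
#' decimated planes) and `scheme.json`.
#'
#' @param sparse a [sparse_cube()].
#' @param dir output directory (created if needed).
#' @param format `"envi"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_sparse_cube <- function(sparse, dir, format = c("envi", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- sparse$scheme
  ref_arr <- array(sparse$reference_band,
                   c(1, nrow(sparse$reference_band), ncol(sparse$reference_band)))
  write_cube(hyper_cube(ref_arr, sc$reference_wavenumber, sc$dx_hi, sc$dy_hi),
             file.path(dir, "reference"), format)
  write_cube(hyper_cube(sparse$sparse_bands, sparse$wavenumbers, sc$dx_hi, sc$dy_lo),
             file.path(dir, "bands"), format)
  jsonlite::write_json(list(dx_hi = sc$dx_hi, dy_hi = sc$dy_hi, dy_lo = sc$dy_lo,
                            reference_wavenumber = sc$reference_wavenumber,
                            rows_hi = nrow(sparse$reference_band)),
                       file.path(dir, "scheme.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a sparse cube directory written by [write_sparse_cube()]
#' @param dir directory path.
#' @param format `"envi"` or `"tiff"`.
#' @return a [sparse_cube()].
#' @export
read_sparse_cube <- function(dir, format = c("envi", "tiff")) {
  format <- match.arg(format)
  meta <- jsonlite::read_json(file.path(dir, "scheme.json"), simplifyVector = TRUE)
  scheme <- sampling_scheme(dy_lo = meta$dy_lo, dx_hi = meta$dx_hi, dy_hi = meta$dy_hi,
                            reference_wavenumber = meta$reference_wavenumber)
  ref <- read_cube(file.path(dir, "reference"), format)
  bands <- read_cube(file.path(dir, "bands"), format)
  sparse_cube(matrix(ref$data[1, , ], cube_dims(ref)[2], cube_dims(ref)[3]),
              bands$data, bands$wavenumbers, scheme)
}
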