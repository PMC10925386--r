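#' Pipeline run configuration
#'
#' A single JSON-serializable document wiring phantom generation, sparse
#' acquisition, interpolation, fusion, quality metrics and segmentation.
#' Unknown keys are rejected so typos cannot silently change a run.
#'
#' @param phantom a [phantom_spec()] or a named list of overrides.
#' @param dy_lo sparse y pitch in micrometres.
#' @param reference_wavenumber full-resolution band (cm^-1).
#' @param window_half_gain_fraction see [interp_params()].
#' @param fusion_depth see [fusion_params()] (`NULL` = derived).
#' @param n_angles_coarse,finest_scale_type see [curvelet_params()].
#' @param sweep_spacings y spacings (um) for the quality sweep, or `NULL`
#'   to skip the sweep stage.
#' @param sweep_replicates replicate phantoms in the sweep.
#' @param per_class balanced training pixels per class.
#' @param n_trees random-forest tree count.
#' @param format `"envi"` or `"tiff"` for cube artifacts.
#' @param outdir output directory.
#' @param seed global seed; expanded deterministically into per-stage seeds.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), dy_lo = 5,
                       reference_wavenumber = 1660,
                       window_half_gain_fraction = 1, fusion_depth = NULL,
                       n_angles_coarse = 16,
                       finest_scale_type = "wavelet",
                       sweep_spacings = NULL, sweep_replicates = 4,
                       per_class = 500, n_trees = 100,
                       format = "envi", outdir = "sparseptir-run", seed = 1) {
  if (is.list(phantom) && !inherits(phantom, "phantom_spec"))
    phantom <- do.call(phantom_spec, phantom)
  structure(list(phantom = phantom, dy_lo = as.numeric(dy_lo),
                 reference_wavenumber = reference_wavenumber,
                 window_half_gain_fraction = window_half_gain_fraction,
                 fusion_depth = fusion_depth,
                 n_angles_coarse = n_angles_coarse,
                 finest_scale_type = finest_scale_type,
                 sweep_spacings = sweep_spacings,
                 sweep_replicates = sweep_replicates,
                 per_class = per_class, n_trees = n_trees,
                 format = format, outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file; top-level keys must be [run_config()] arguments
#'   (unknown keys are an error), `phantom` a nested object of
#'   [phantom_spec()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$phantom)) {
    badp <- setdiff(names(raw$phantom), names(formals(phantom_spec)))
    if (length(badp)) stopf("unknown phantom key(s): %s", paste(badp, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a run configuration as JSON
#'
#' The output directory is not serialized: it is a property of the run
#' location, not of the experiment, and leaving it out keeps manifests of
#' identical experiments byte-identical wherever they are materialized.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$outdir <- NULL
  x$phantom <- unclass(x$phantom)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full sparse-reconstruction pipeline
#'
#' phantom -> subsample -> interpolate -> reconstruct -> evaluate ->
#' (optional sweep) -> segment, writing every artifact under
#' `config$outdir` and a `manifest.json` mapping each file to its MD5
#' checksum. Identical configs produce identical checksums. Each stage
#' derives its seed deterministically from the global seed and the stage
#' name, so stages can be rerun in isolation.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage log lines.
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    if (!quiet)
      message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                      paste(sprintf(...), collapse = "")))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- config$format
  spec <- config$phantom
  spec$seed <- stage_seed(config$seed, "phantom")

  log_stage("phantom", "rows=%d cols=%d classes=%d seed=%d",
            spec$rows, spec$cols, spec$n_classes, spec$seed)
  ph <- generate_phantom(spec)
  write_label_map(ph$label_map, file.path(outdir, "labels"))
  write_cube(ph$clean_cube, file.path(outdir, "truth_clean"), fmt)
  write_cube(ph$noisy_cube, file.path(outdir, "truth_noisy"), fmt)

  scheme <- sampling_scheme(dy_lo = config$dy_lo, dx_hi = spec$dx, dy_hi = spec$dy,
                            reference_wavenumber = config$reference_wavenumber)
  log_stage("subsample", "dy_lo=%g um (s=%d, %.3g%% of data)",
            scheme$dy_lo, scheme$s, sampling_fraction(scheme))
  sparse <- subsample_y(ph$noisy_cube, scheme)
  write_sparse_cube(sparse, file.path(outdir, "sparse"), fmt)

  ip <- interp_params(config$window_half_gain_fraction)
  log_stage("interpolate", "half-gain fraction %g", ip$window_half_gain_fraction)
  interp_cube_out <- interpolate_cube(sparse, ip)
  write_cube(interp_cube_out, file.path(outdir, "interpolated"), fmt)

  fp <- fusion_params(fusion_depth = config$fusion_depth,
                      curvelet = curvelet_params(
                        n_angles_coarse = config$n_angles_coarse,
                        finest_scale_type = config$finest_scale_type))
  log_stage("reconstruct", "fusion depth %s",
            config$fusion_depth %||% "auto")
  recon <- reconstruct_cube(sparse, fp, ip)
  write_cube(recon, file.path(outdir, "reconstructed"), fmt)
  eq <- attr(recon, "equalization")
  utils::write.csv(eq, file.path(outdir, "equalization.csv"), row.names = FALSE)

  log_stage("evaluate", "MSE/SSIM against clean truth")
  ev_i <- evaluate_reconstruction(ph$clean_cube, interp_cube_out, "interpolated")
  ev_f <- evaluate_reconstruction(ph$clean_cube, recon, "fused")
  write_report(rbind(ev_i$per_band, ev_f$per_band),
               file.path(outdir, "quality_report.csv"))

  if (!is.null(config$sweep_spacings)) {
    log_stage("sweep", "spacings {%s} um, %d replicates",
              paste(config$sweep_spacings, collapse = ", "), config$sweep_replicates)
    sw <- spacing_sweep(spec, config$sweep_spacings, config$sweep_replicates,
                        base_seed = stage_seed(config$seed, "sweep"),
                        interp = ip, fusion = fp,
                        reference_wavenumber = config$reference_wavenumber)
    utils::write.csv(sw$values, file.path(outdir, "sweep_values.csv"), row.names = FALSE)
    utils::write.csv(sw$summary, file.path(outdir, "sweep_summary.csv"), row.names = FALSE)
  }

  log_stage("segment", "train right half, test left half, %d px/class",
            config$per_class)
  mid <- floor(ncol(ph$label_map) / 2)
  train_mask <- col(ph$label_map) > mid            # right half trains
  test_cols <- seq_len(mid)                        # left half tests
  avail <- min(tabulate(ph$label_map[train_mask] + 1L, nbins = spec$n_classes))
  per_class <- min(config$per_class, avail)
  train <- sample_training_pixels(recon, ph$label_map, per_class,
                                  seed = stage_seed(config$seed, "segment"),
                                  reference_wavenumber = config$reference_wavenumber,
                                  mask = train_mask)
  model <- train_pixel_classifier(train, n_trees = config$n_trees,
                                  seed = stage_seed(config$seed, "forest"))
  pm <- predict_map(model, recon, config$reference_wavenumber)
  seg <- evaluate_segmentation(pm$labels[, test_cols],
                               ph$label_map[, test_cols],
                               pm$probabilities[, , test_cols, drop = FALSE],
                               classes = model$classes)
  jsonlite::write_json(
    list(per_class = seg$per_class,
         overall_accuracy = seg$overall_accuracy,
         pixel_match_accuracy = seg$pixel_match_accuracy,
         confusion = as.data.frame.matrix(unclass(seg$confusion)),
         per_class_training_pixels = per_class),
    file.path(outdir, "segmentation_report.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(seg$per_class, file.path(outdir, "segmentation_per_class.csv"),
                   row.names = FALSE)
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(render_rgb(ph$label_map), file.path(outdir, "labels_truth.png"))
    png::writePNG(render_rgb(pm$labels), file.path(outdir, "labels_predicted.png"))
  }

  write_run_config(config, file.path(outdir, "config.json"))
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.json"))
  md5 <- as.vector(tools::md5sum(file.path(outdir, files)))
  manifest <- data.frame(file = files, md5 = md5)
  jsonlite::write_json(list(config = "config.json", files = manifest),
                       file.path(outdir, "manifest.json"), digits = NA)
  log_stage("done", "%d artifacts in %.1f s", nrow(manifest),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}
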