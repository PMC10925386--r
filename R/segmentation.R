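#' Class-balanced pixel sampling for classifier training
#'
#' Draws exactly `per_class` pixels per class without replacement (seeded),
#' taking as features the spectra over all bands except the reference
#' (the 27-band feature vector); equal class counts prevent class bias in
#' training.
#'
#' @param cube a dense [hyper_cube()] (reconstructed or ground truth).
#' @param label_map integer class map (`0 ..`), same image shape.
#' @param per_class pixels per class; must not exceed the smallest class
#'   support within `mask`.
#' @param seed RNG seed.
#' @param reference_wavenumber band excluded from the features (default
#'   1660); `NULL` keeps all bands.
#' @param mask optional logical matrix restricting eligible pixels (e.g.
#'   one TMA-style half for training).
#' @return object of class `pixel_dataset`: `spectra` `[n_pixels, n_bands]`,
#'   `labels` (integer), `provenance` (data frame `row`, `col`, 1-based),
#'   `feature_wavenumbers`.
#' @export
sample_training_pixels <- function(cube, label_map, per_class, seed = 1,
                                   reference_wavenumber = 1660, mask = NULL) {
  d <- cube_dims(cube)
  if (!identical(dim(label_map), d[2:3]))
    stopf("label map is %s; cube planes are %s",
          paste(dim(label_map), collapse = "x"), paste(d[2:3], collapse = "x"))
  keep_bands <- seq_len(d[1])
  if (!is.null(reference_wavenumber)) {
    ri <- match(reference_wavenumber, cube$wavenumbers)
    if (!is.na(ri)) keep_bands <- keep_bands[-ri]
  }
  eligible <- if (is.null(mask)) rep(TRUE, length(label_map)) else as.vector(mask)
  classes <- sort(unique(as.vector(label_map)))
  picks <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(as.vector(label_map) == cl & eligible)
      if (length(idx) < per_class)
        stopf("class %d has only %d eligible pixels; %d per class requested",
              cl, length(idx), per_class)
      picks <- c(picks, sample(idx, per_class))
    }
  })
  rc <- arrayInd(picks, d[2:3])
  flat <- matrix(cube$data[keep_bands, , , drop = FALSE], length(keep_bands), d[2] * d[3])
  structure(list(spectra = t(flat[, picks, drop = FALSE]),
                 labels = as.vector(label_map)[picks],
                 provenance = data.frame(row = rc[, 1], col = rc[, 2]),
                 feature_wavenumbers = cube$wavenumbers[keep_bands]),
            class = "pixel_dataset")
}

#' Train a pixel-wise random-forest spectral classifier
#'
#' An ensemble of decision trees over per-pixel band spectra: 100 trees,
#' unlimited depth, square-root feature subsampling, seeded (conventional
#' random-forest defaults, exposed here as arguments).
#'
#' @param train a `pixel_dataset` with at least 2 classes present.
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param seed RNG seed for training.
#' @return object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(train, n_trees = 100, mtry = NULL, seed = 1) {
  classes <- sort(unique(train$labels))
  if (length(classes) < 2) stopf("training data contains a single class")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(train$spectra))))
  fit <- with_seed(seed,
    randomForest::randomForest(x = train$spectra,
                               y = factor(train$labels, levels = classes),
                               ntree = n_trees, mtry = mtry))
  structure(list(fit = fit, classes = classes,
                 feature_wavenumbers = train$feature_wavenumbers),
            class = "pixel_classifier")
}

#' Predict a label map (and class-probability planes) for a cube
#'
#' Applies the classifier to every pixel spectrum. The predicted class is
#' the probability argmax with ties broken toward the lower class index.
#'
#' @param model a `pixel_classifier`.
#' @param cube a dense [hyper_cube()]; its non-reference band count must
#'   match the training feature count.
#' @param reference_wavenumber band excluded from features (must match
#'   training; default 1660).
#' @return list with `labels` (integer matrix) and `probabilities` (array
#'   `[class, row, col]`, planes summing to 1 per pixel).
#' @export
predict_map <- function(model, cube, reference_wavenumber = 1660) {
  d <- cube_dims(cube)
  keep_bands <- seq_len(d[1])
  if (!is.null(reference_wavenumber)) {
    ri <- match(reference_wavenumber, cube$wavenumbers)
    if (!is.na(ri)) keep_bands <- keep_bands[-ri]
  }
  if (length(keep_bands) != length(model$feature_wavenumbers))
    stopf("cube provides %d feature bands; classifier was trained on %d",
          length(keep_bands), length(model$feature_wavenumbers))
  flat <- t(matrix(cube$data[keep_bands, , , drop = FALSE],
                   length(keep_bands), d[2] * d[3]))
  prob <- stats::predict(model$fit, flat, type = "prob")
  pick <- max.col(prob, ties.method = "first")
  labels <- matrix(model$classes[pick], d[2], d[3])
  probs <- array(0, c(length(model$classes), d[2], d[3]))
  for (k in seq_along(model$classes)) probs[k, , ] <- matrix(prob[, k], d[2], d[3])
  list(labels = labels, probabilities = probs, classes = model$classes)
}

# trapezoidal one-vs-rest ROC area; ties handled by grouping identical scores
roc_auc_trapezoid <- function(scores, positive) {
  pos <- sum(positive); neg <- sum(!positive)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)   # per-threshold operating points
  tpr <- c(0, tp[last] / pos)
  fpr <- c(0, fp[last] / neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per-class accuracy is the class recall; overall accuracy is the
#' support-weighted mean of class recalls, which is identical to the raw
#' pixel-match fraction (both are reported). One-vs-rest AUC per class is
#' computed by trapezoidal integration of the ROC built from that class's
#' probability plane; a class absent from the truth gets `NA` (undefined),
#' never 0.
#'
#' @param pred predicted integer label matrix.
#' @param truth ground-truth integer label matrix, same shape.
#' @param probabilities array `[class, row, col]` of class probabilities
#'   (classes in ascending label order), or `NULL` to skip AUC.
#' @param classes class labels corresponding to the probability planes;
#'   default `sort(unique(c(truth, pred)))`.
#' @return object of class `segmentation_report`: `per_class` data frame
#'   (`class`, `support`, `accuracy` in percent, `auc`), `overall_accuracy`
#'   (percent, support-weighted), `pixel_match_accuracy` (percent),
#'   `confusion` matrix (rows = truth, summing to class support).
#' @export
evaluate_segmentation <- function(pred, truth, probabilities = NULL,
                                  classes = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stopf("prediction and truth shapes differ")
  classes <- classes %||% sort(unique(c(as.vector(truth), as.vector(pred))))
  k <- length(classes)
  tv <- factor(as.vector(truth), levels = classes)
  pv <- factor(as.vector(pred), levels = classes)
  confusion <- table(truth = tv, predicted = pv)
  support <- as.vector(table(tv))
  acc <- ifelse(support > 0, 100 * diag(confusion) / support, NA_real_)
  auc <- rep(NA_real_, k)
  if (!is.null(probabilities)) {
    for (i in seq_len(k)) {
      if (support[i] == 0 || support[i] == length(tv)) next
      auc[i] <- roc_auc_trapezoid(as.vector(probabilities[i, , ]),
                                  as.vector(truth) == classes[i])
    }
  }
  present <- support > 0
  overall <- sum(acc[present] * support[present]) / sum(support[present])
  structure(list(
    per_class = data.frame(class = classes, support = support,
                           accuracy = acc, auc = auc),
    overall_accuracy = overall,
    pixel_match_accuracy = 100 * mean(as.vector(pred) == as.vector(truth)),
    confusion = confusion),
    class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("<segmentation_report> OA = %.2f%% (pixel match %.2f%%)\n",
              x$overall_accuracy, x$pixel_match_accuracy))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Default class palette: red = epithelium, green = stroma, blue = necrosis
#' @param n number of classes.
#' @return matrix `[n, 3]` of RGB values in [0, 1].
#' @export
class_palette <- function(n = 3) {
  base <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  if (n > nrow(base)) stopf("palette supports at most %d classes", nrow(base))
  base[seq_len(n), , drop = FALSE]
}

#' Render a label map as an RGB image
#'
#' Class 0 maps to the red channel, class 1 to green, class 2 to blue
#' (the epithelium/stroma/necrosis channel convention); additional classes
#' take the extended palette.
#'
#' @param label_map integer matrix with labels `0 ..`.
#' @param palette matrix `[n_classes, 3]`; default [class_palette()].
#' @return array `rows x cols x 3` of RGB values in [0, 1].
#' @export
render_rgb <- function(label_map, palette = NULL) {
  n <- max(label_map) + 1L
  palette <- palette %||% class_palette(n)
  out <- array(0, c(dim(label_map), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(palette[label_map + 1L, ch], dim(label_map)[1])
  out
}

#' Recover a label map from an RGB class rendering
#'
#' Inverse of [render_rgb()] for exact palette colors.
#'
#' @param rgb array `rows x cols x 3`.
#' @param palette matrix `[n_classes, 3]`; default [class_palette()] sized
#'   by the distinct colors present.
#' @return integer label matrix.
#' @export
labels_from_rgb <- function(rgb, palette = NULL) {
  flat <- matrix(rgb, prod(dim(rgb)[1:2]), 3L)
  palette <- palette %||% class_palette(7)
  key <- apply(palette, 1, paste, collapse = ",")
  got <- apply(round(flat, 9), 1, paste, collapse = ",")
  idx <- match(got, key)
  if (any(is.na(idx))) stopf("RGB image contains colors outside the palette")
  matrix(idx - 1L, dim(rgb)[1], dim(rgb)[2])
}
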