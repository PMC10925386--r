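# synthetic, clearly separable two-cluster spectra for classifier unit tests
make_separable <- function(n_per_class = 60, p = 8, gap = 3, seed = 40) {
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * p, 0, 1), n_per_class, p)
  x1 <- matrix(rnorm(n_per_class * p, gap, 1), n_per_class, p)
  list(spectra = rbind(x0, x1), labels = rep(0:1, each = n_per_class))
}

as_dataset <- function(d, wn = seq_len(ncol(d$spectra))) {
  structure(list(spectra = d$spectra, labels = d$labels,
                 provenance = data.frame(row = seq_along(d$labels), col = 1L),
                 feature_wavenumbers = wn),
            class = "pixel_dataset")
}

test_that("balanced pixel sampling is exact, seeded, and support-checked", {
  spec <- tiny_spec(seed = 41)
  ph <- generate_phantom(spec)
  ds <- sample_training_pixels(ph$noisy_cube, ph$label_map, 10, seed = 5)
  expect_identical(nrow(ds$spectra), 30L)
  expect_identical(as.vector(table(ds$labels)), rep(10L, 3))
  expect_identical(ncol(ds$spectra), length(spec$wavenumbers) - 1L)  # reference excluded
  ds2 <- sample_training_pixels(ph$noisy_cube, ph$label_map, 10, seed = 5)
  expect_identical(ds$provenance, ds2$provenance)
  # spectra come from the stated pixels
  i <- 7L
  b <- match(ds$feature_wavenumbers[1], ph$noisy_cube$wavenumbers)
  expect_equal(ds$spectra[i, 1],
               ph$noisy_cube$data[b, ds$provenance$row[i], ds$provenance$col[i]])
  expect_error(sample_training_pixels(ph$noisy_cube, ph$label_map, 1e6, seed = 1),
               "class")
})

test_that("the forest separates separable classes and is deterministic", {
  d <- make_separable()
  train <- as_dataset(d)
  model <- train_pixel_classifier(train, seed = 1)
  pred <- stats::predict(model$fit, train$spectra)
  expect_equal(mean(pred == factor(train$labels)), 1)     # training accuracy 100%
  model2 <- train_pixel_classifier(train, seed = 1)
  expect_identical(stats::predict(model2$fit, train$spectra), pred)
  bad <- train; bad$labels <- rep(0L, length(bad$labels))
  expect_error(train_pixel_classifier(bad), "single class")
})

test_that("permuted labels give chance-level held-out accuracy", {
  d <- make_separable(n_per_class = 150, seed = 42)
  set.seed(43)
  d$labels <- sample(d$labels)                           # break the signal
  idx <- sample(length(d$labels), 200)
  train <- as_dataset(list(spectra = d$spectra[idx, ], labels = d$labels[idx]))
  test_x <- d$spectra[-idx, ]; test_y <- d$labels[-idx]
  model <- train_pixel_classifier(train, seed = 2)
  acc <- mean(stats::predict(model$fit, test_x) == factor(test_y))
  expect_gt(acc, 0.5 - 0.10); expect_lt(acc, 0.5 + 0.10)
})

test_that("predict_map yields normalized probabilities and exact recall of training spectra", {
  d <- make_separable(n_per_class = 50, gap = 4, seed = 44)
  train <- as_dataset(d, wn = seq(1000, by = 10, length.out = ncol(d$spectra)))
  model <- train_pixel_classifier(train, seed = 3)
  # cube whose pixels all equal one class-1 training spectrum
  rows <- 6; cols <- 5
  arr <- array(0, c(ncol(d$spectra), rows, cols))
  proto <- d$spectra[51, ]                                # a class-1 pixel
  for (b in seq_along(proto)) arr[b, , ] <- proto[b]
  cube <- hyper_cube(arr, train$feature_wavenumbers)
  pm <- predict_map(model, cube, reference_wavenumber = NULL)
  expect_true(all(pm$labels == 1L))
  sums <- apply(pm$probabilities, c(2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  pm2 <- predict_map(model, cube, reference_wavenumber = NULL)
  expect_identical(pm$probabilities, pm2$probabilities)
  small <- hyper_cube(arr[1:3, , , drop = FALSE], train$feature_wavenumbers[1:3])
  expect_error(predict_map(model, small, reference_wavenumber = NULL), "trained on")
})

test_that("segmentation evaluation reproduces hand-computed accuracies", {
  truth <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4)
  pred <- truth; pred[2, 2] <- 1                          # one class-0 pixel -> 1
  # confusion: TP0 = 3, FN0 = 1, TP1 = 4, FP1 = 1
  rep <- evaluate_segmentation(pred, truth)
  expect_equal(rep$per_class$accuracy, c(75, 100))
  expect_equal(rep$overall_accuracy, (4 * 75 + 4 * 100) / 8)
  expect_equal(rep$overall_accuracy, rep$pixel_match_accuracy)
  expect_identical(as.vector(rep$confusion), c(3L, 0L, 1L, 4L))

  perfect <- evaluate_segmentation(truth, truth,
                                   probabilities = {
                                     p <- array(0, c(2, 2, 4))
                                     p[1, , ] <- (truth == 0); p[2, , ] <- (truth == 1); p
                                   })
  expect_equal(perfect$per_class$accuracy, c(100, 100))
  expect_equal(perfect$per_class$auc, c(1, 1))
})

test_that("AUC is chance-level for uniform probabilities and NA for absent classes", {
  set.seed(45)
  n <- 50; m <- 40                                        # 2000 pixels
  truth <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  p1 <- matrix(runif(n * m), n, m)
  probs <- array(0, c(2, n, m)); probs[1, , ] <- 1 - p1; probs[2, , ] <- p1
  rep <- evaluate_segmentation(truth, truth, probs)
  expect_lt(abs(rep$per_class$auc[1] - 0.5), 0.05)
  expect_lt(abs(rep$per_class$auc[2] - 0.5), 0.05)

  truth0 <- matrix(0L, 4, 4); pred0 <- truth0; pred0[1, 1] <- 1L
  rep0 <- evaluate_segmentation(pred0, truth0, classes = 0:1,
                                probabilities = array(0.5, c(2, 4, 4)))
  expect_true(is.na(rep0$per_class$auc[2]))               # class 1 absent from truth
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  set.seed(46)
  labels <- sample(0:1, 300, replace = TRUE)
  scores <- runif(300) + 0.4 * labels                     # informative but noisy
  probs <- array(0, c(2, 1, 300))
  probs[2, 1, ] <- scores; probs[1, 1, ] <- 1 - scores
  rep <- evaluate_segmentation(matrix(labels, 1), matrix(labels, 1), probs)
  oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(rep$per_class$auc[2], oracle, tolerance = 1e-12)
  expect_equal(rep$per_class$auc[1], oracle, tolerance = 1e-12)  # complement symmetry
})

test_that("RGB renderings follow the channel convention and invert exactly", {
  all0 <- matrix(0L, 4, 4)
  rgb0 <- render_rgb(all0)
  expect_true(all(rgb0[, , 1] == 1) && all(rgb0[, , 2:3] == 0))

  board <- matrix(as.integer((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 3), 6, 6)
  rgb <- render_rgb(board)
  for (cl in 0:2)
    expect_true(all(rgb[, , cl + 1][board == cl] == 1))
  expect_identical(labels_from_rgb(rgb), board)
})
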