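#' Classifier configuration
#'
#' A small residual convolutional network (same residual-block backbone as
#' the discriminators) trained with the binary cross-entropy objective to
#' recognise ground-glass nodules (positive class) among nodule slices.
#'
#' @param image_size input side in pixels.
#' @param base_channels first-stage feature channels.
#' @param steps optimisation steps.
#' @param batch_size samples per step.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(image_size = 64, base_channels = 8,
                              steps = 150, batch_size = 8,
                              learning_rate = 2e-3, seed = 1L) {
  structure(
    list(image_size = as.integer(image_size),
         base_channels = as.integer(base_channels),
         steps = as.integer(steps), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Train and evaluate the GGN classifier
#'
#' `train_classifier()` fits the residual network with cross-entropy on
#' labelled slices; `evaluate_classifier()` scores a held-out set and
#' returns per-class precision (`TP / (TP + FP)`) and recall
#' (`TP / (TP + FN)`) from the test confusion matrix at threshold 0.5
#' (a class never predicted has precision 0 by convention).
#'
#' @param images list of numeric matrices (or [ct_slice()]s), all one size,
#'   values in \[0, 1\].
#' @param labels logical vector; `TRUE` = GGN.
#' @param config a [classifier_config()].
#' @return `train_classifier()` an object of class `ggn_classifier`;
#'   `evaluate_classifier()` a tibble with one row per class.
#' @export
train_classifier <- function(images, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  labels <- as.logical(labels)
  if (length(images) == 0L || length(images) != length(labels)) {
    stop("`images` and `labels` must be non-empty and of equal length", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  S <- config$image_size
  X <- vapply(images, as_image_matrix, matrix(0, S, S))
  gcfg <- gan_config(image_size = S, roi_size = max(2L, S %/% 16L),
                     base_channels = config$base_channels, seed = config$seed)
  net <- build_discriminator(gcfg, "whole")
  net$role <- "classifier"
  n <- length(labels)
  nb <- min(config$batch_size, n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  for (step in seq_len(config$steps)) {
    set.seed((config$seed + 104729L * step) %% 2147483647L)
    idx <- sample.int(n, nb, replace = nb > n)
    x <- array(X[, , idx], dim = c(S, S, nb, 1))
    y <- as.numeric(labels[idx])
    net_zero_grads(net)
    s <- net$forward(x, train = TRUE)
    loss <- -mean(y * log(s) + (1 - y) * log(1 - s))
    if (!is.finite(loss)) stop(sprintf("classifier diverged at step %d", step), call. = FALSE)
    net$backward(-(y / s - (1 - y) / (1 - s)) / nb)
    net_step(net, config$learning_rate)
  }
  structure(list(net = net, config = config), class = "ggn_classifier")
}

#' @rdname train_classifier
#' @param classifier a trained `ggn_classifier`.
#' @export
evaluate_classifier <- function(classifier, images, labels) {
  stopifnot(inherits(classifier, "ggn_classifier"))
  labels <- as.logical(labels)
  if (length(images) == 0L) stop("empty test set", call. = FALSE)
  S <- classifier$config$image_size
  X <- vapply(images, as_image_matrix, matrix(0, S, S))
  x <- array(X, dim = c(S, S, length(labels), 1))
  s <- classifier$net$forward(x, train = FALSE)
  precision_recall(s >= 0.5, labels)
}

# per-class precision/recall from predictions; a never-predicted class has
# precision 0 by convention
precision_recall <- function(pred, labels) {
  metrics_for <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    tibble::tibble(
      class = if (cls) "ggn" else "non_ggn",
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0
    )
  }
  dplyr::bind_rows(metrics_for(TRUE), metrics_for(FALSE))
}

#' Stratified nested training subsets and held-out test set
#'
#' Splits a dataset into a stratified held-out test set and `n_subsets`
#' stratified, disjoint training subsets. Fraction `f` of the training data
#' means the union of the first `f * n_subsets / 100` subsets, so larger
#' fractions are supersets of smaller ones.
#'
#' @param dataset tibble with an `is_ggn` column (e.g.
#'   [make_phantom_dataset()] output).
#' @param n_subsets number of training subsets (default 10).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return A list with `subsets` (list of row-index vectors into `dataset`,
#'   in order), `test` (row indices), and `dataset`.
#' @export
split_subsets <- function(dataset, n_subsets = 10L, test_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(dataset), "is_ggn" %in% names(dataset))
  y <- dataset$is_ggn
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test <- integer(0)
  pool_by_class <- list()
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    n_test <- round(length(idx) * test_fraction)
    test <- c(test, idx[seq_len(n_test)])
    pool_by_class[[as.character(cls)]] <- idx[-seq_len(n_test)]
  }
  subsets <- rep(list(integer(0)), n_subsets)
  for (pool in pool_by_class) {
    assign_to <- rep_len(seq_len(n_subsets), length(pool))
    for (s in seq_len(n_subsets)) {
      subsets[[s]] <- c(subsets[[s]], pool[assign_to == s])
    }
  }
  if (any(lengths(subsets) == 0L) || length(test) == 0L) {
    stop("dataset too small for the requested split", call. = FALSE)
  }
  both <- function(ix) length(unique(y[ix])) == 2L
  if (!both(test) || !all(vapply(subsets, both, logical(1)))) {
    stop("class-starved split: a subset or the test set is single-class", call. = FALSE)
  }
  list(subsets = subsets, test = sort(test), dataset = dataset)
}

#' The data-augmentation sweep
#'
#' For each training fraction `f` (percent): arm `real_only` trains the
#' classifier on the first `f%` of the stratified training subsets; arm
#' `real_plus_synthetic` first trains the inpainting GAN on the GGN slices
#' of the same subset, synthesises one new GGN slice per real GGN (the GAN
#' inpaints a blanked region at a fresh lung location of a subset slice,
#' doubling the minority class), adds them to the training data, and trains
#' the classifier. Both arms are evaluated on the same held-out test set;
#' no test case ever enters classifier or GAN training.
#'
#' @param real_dataset tibble from [make_phantom_dataset()].
#' @param fractions percents in 10..100 (multiples of 10).
#' @param gan_recipe a [gan_config()] used to train the GAN in arm B.
#' @param clf_config a [classifier_config()].
#' @param seed master seed.
#' @param hu_window normalisation window applied to all slices.
#' @param verbose print progress.
#' @return An `augmentation_result` tibble: one row per (fraction, arm,
#'   class) with `precision`, `recall`, `n_train_real`, `n_train_synth`,
#'   `seed`; attribute `test_ids` records the held-out case ids.
#' @export
augmentation_experiment <- function(real_dataset, fractions, gan_recipe,
                                    clf_config = classifier_config(),
                                    seed = 1L, hu_window = c(-1000, 400),
                                    verbose = FALSE) {
  stopifnot(all(fractions %in% seq(10, 100, 10)))
  split <- split_subsets(real_dataset, 10L, 0.2, seed)
  ds <- split$dataset
  norm_slices <- purrr::map(ds$slice, normalize_intensity, hu_window = hu_window)
  test_idx <- split$test
  test_imgs <- norm_slices[test_idx]
  test_lab <- ds$is_ggn[test_idx]

  rows <- list()
  train_ids <- list()
  for (f in fractions) {
    take <- unlist(split$subsets[seq_len(f %/% 10L)])
    train_ids[[as.character(f)]] <- ds$id[take]
    train_imgs <- norm_slices[take]
    train_lab <- ds$is_ggn[take]
    n_real <- length(take)

    for (arm in c("real_only", "real_plus_synthetic")) {
      imgs <- train_imgs; labs <- train_lab; n_synth <- 0L
      if (arm == "real_plus_synthetic") {
        synth <- synthesise_ggns(ds, take, norm_slices, gan_recipe, seed + f,
                                 verbose = verbose)
        imgs <- c(imgs, synth)
        labs <- c(labs, rep(TRUE, length(synth)))
        n_synth <- length(synth)
      }
      cfg <- clf_config
      cfg$seed <- as.integer((seed + f) %% 2147483647L)
      clf <- tryCatch(
        train_classifier(imgs, labs, cfg),
        error = function(e) stop(sprintf("fraction %d, arm %s: %s", f, arm,
                                         conditionMessage(e)), call. = FALSE)
      )
      met <- evaluate_classifier(clf, test_imgs, test_lab)
      met$fraction <- f; met$arm <- arm
      met$n_train_real <- n_real; met$n_train_synth <- n_synth
      met$seed <- seed
      rows[[length(rows) + 1L]] <- met
      if (verbose) message(sprintf("fraction %3d%%, %s: GGN recall %.2f",
                                   f, arm, met$recall[met$class == "ggn"]))
    }
  }
  out <- dplyr::bind_rows(rows)[, c("fraction", "arm", "class", "precision",
                                    "recall", "n_train_real", "n_train_synth",
                                    "seed")]
  attr(out, "test_ids") <- ds$id[test_idx]
  attr(out, "train_ids") <- train_ids
  class(out) <- c("augmentation_result", class(out))
  out
}

# train the GAN on the subset's GGN slices and inpaint fresh GGNs at new
# lung locations of the same slices; one synthetic slice per real GGN
synthesise_ggns <- function(ds, take, norm_slices, gan_recipe, seed,
                            verbose = FALSE) {
  ggn_idx <- take[ds$is_ggn[take]]
  if (length(ggn_idx) == 0L) return(list())
  R <- gan_recipe$roi_size
  pairs <- purrr::map(ggn_idx, function(i) {
    blank_roi(norm_slices[[i]], ds$annotation[[i]], R)
  })
  recipe <- gan_recipe
  recipe$seed <- as.integer(seed %% 2147483647L)
  fit <- train_gan(pairs, recipe, verbose = FALSE)
  S <- recipe$image_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(recipe$seed + 13L)
  purrr::map(seq_along(ggn_idx), function(k) {
    i <- ggn_idx[k]
    interior <- which(lung_interior(ds$lung_mask[[i]], margin = R %/% 2 + 1L),
                      arr.ind = TRUE)
    ctr <- interior[sample.int(nrow(interior), 1L), ]
    r1 <- min(max(ctr[1] - 1L - R %/% 2L, 0L), S - R)
    c1 <- min(max(ctr[2] - 1L - R %/% 2L, 0L), S - R)
    box <- c(r1, c1, r1 + R, c1 + R)
    px <- norm_slices[[i]]$pixels
    px[(r1 + 1):(r1 + R), (c1 + 1):(c1 + R)] <- 0
    blank <- ct_slice(px, spacing = norm_slices[[i]]$spacing, normalized = TRUE,
                      id = sprintf("%s-synth%d", ds$id[i], k))
    generate_synthetic(fit$checkpoint, blank, box)
  })
}

#' Plot an augmentation sweep
#'
#' Precision and recall of the GGN class against the real-data fraction,
#' one line per arm.
#'
#' @param object an `augmentation_result`.
#' @param which class to plot (default `"ggn"`).
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.augmentation_result <- function(object, which = "ggn", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$class == which)
  long <- tidyr::pivot_longer(df, c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value,
                                     colour = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "% of real training data", y = NULL, colour = NULL,
                  title = "Classifier performance with and without synthetic GGNs") +
    ggplot2::theme_minimal()
}
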