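#' Train the dual-discriminator inpainting GAN
#'
#' Alternating adversarial optimisation. Per step: (1) both discriminators
#' are updated on (target = real, generated = fake) batches — the whole-image
#' discriminator on full slices, the ROI discriminator on the per-sample ROI
#' crops of the same images — via the binary cross-entropy
#' [discriminator_loss()]; (2) the generator is updated on the composite
#' objective [total_generator_loss()] (whole-image + ROI, SSIM +
#' adversarial), where each adversarial term backpropagates through the
#' corresponding (frozen) discriminator into the generated image. All three
#' networks use Adam at `config$learning_rate`. The run is a pure function
#' of `(pairs, config, seed)`: the per-step seed chain is derived from
#' `config$seed`, so two runs with identical arguments give bit-identical
#' loss histories.
#'
#' @param pairs list of `training_pair` objects (see [blank_roi()]), all of
#'   one image size, or a tibble with a `pair` list-column.
#' @param config a [gan_config()]; `config$image_size` must match the pairs.
#' @param checkpoint_dir optional directory; checkpoints are written every
#'   `config$checkpoint_interval` steps and at the end.
#' @param verbose print progress every 50 steps.
#' @return An object of class `ggn_gan`: list with `history` (tibble with
#'   one row per step: the four generator loss terms, their total, and both
#'   discriminator losses), `checkpoint`, `config`, and the live networks.
#' @export
train_gan <- function(pairs, config, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "gan_config"))
  if (is.data.frame(pairs)) pairs <- pairs$pair
  if (length(pairs) == 0L) stop("`pairs` must contain at least one training pair", call. = FALSE)
  sizes <- vapply(pairs, function(p) nrow(p$target_image$pixels), integer(1))
  if (length(unique(sizes)) != 1L) stop("all pairs must share one image size", call. = FALSE)
  if (sizes[1] != config$image_size) {
    stop(sprintf("pairs are %dx%d but config$image_size is %d",
                 sizes[1], sizes[1], config$image_size), call. = FALSE)
  }
  n <- length(pairs)
  S <- config$image_size; R <- config$roi_size
  inputs <- vapply(pairs, function(p) p$input_image$pixels, matrix(0, S, S))
  targets <- vapply(pairs, function(p) p$target_image$pixels, matrix(0, S, S))
  boxes <- lapply(pairs, function(p) roi_center_box(p$roi_box, R, S))

  G <- build_generator(config)
  Dw <- build_discriminator(config, "whole")
  Dr <- build_discriminator(config, "roi")
  lr <- config$learning_rate; b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  p_real <- if (config$label_smoothing) 0.9 else 1
  p_fake <- if (config$label_smoothing) 0.1 else 0

  nb <- min(config$batch_size, n)
  hist <- vector("list", config$steps)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  for (step in seq_len(config$steps)) {
    set.seed((config$seed + 7919L * step) %% 2147483647L)
    idx <- sample.int(n, nb, replace = nb > n)
    x <- array(inputs[, , idx], dim = c(S, S, nb, 1))
    y <- array(targets[, , idx], dim = c(S, S, nb, 1))
    bxs <- boxes[idx]

    gen <- G$forward(x, train = TRUE)

    # --- discriminator updates (generator untouched) ---
    y_roi <- stack_crops(y, bxs, R)
    g_roi <- stack_crops(gen, bxs, R)

    d_w <- update_discriminator(Dw, y, gen, p_real, p_fake, lr, b1, b2)
    d_r <- update_discriminator(Dr, y_roi, g_roi, p_real, p_fake, lr, b1, b2)

    # --- generator update ---
    net_zero_grads(G)
    # adversarial terms: -log D(G(x)), gradients through frozen discriminators
    net_zero_grads(Dw)
    s_w <- Dw$forward(gen, train = TRUE)
    d_gen <- Dw$backward(adv_score_grad(s_w, config$adv_reduction))
    net_zero_grads(Dr)
    s_r <- Dr$forward(g_roi, train = TRUE)
    d_crop_adv <- Dr$backward(adv_score_grad(s_r, config$adv_reduction))
    # SSIM terms, averaged over the batch
    l_ssim_w <- 0; l_ssim_r <- 0
    for (i in seq_len(nb)) {
      sg <- ssim_global(gen[, , i, 1], y[, , i, 1], 0.01^2, 0.03^2)
      l_ssim_w <- l_ssim_w + (1 - sg$value) / nb
      d_gen[, , i, 1] <- d_gen[, , i, 1] - sg$dx / nb
      sr <- ssim_global(g_roi[, , i, 1], y_roi[, , i, 1], 0.01^2, 0.03^2)
      l_ssim_r <- l_ssim_r + (1 - sr$value) / nb
      d_crop_adv[, , i, 1] <- d_crop_adv[, , i, 1] - sr$dx / nb
    }
    d_gen <- scatter_crops(d_gen, d_crop_adv, bxs)
    G$backward(d_gen)
    net_step(G, lr, b1, b2)

    l_adv_w <- adversarial_loss(s_w, reduction = config$adv_reduction)
    l_adv_r <- adversarial_loss(s_r, reduction = config$adv_reduction)
    lb <- loss_breakdown(l_ssim_w, l_adv_w, l_ssim_r, l_adv_r)
    if (!is.finite(lb$total) || !is.finite(d_w) || !is.finite(d_r)) {
      stop(sprintf("training diverged at step %d (non-finite loss)", step), call. = FALSE)
    }
    hist[[step]] <- c(step = step, l_ssim_whole = lb$l_ssim_whole,
                      l_adv_whole = lb$l_adv_whole, l_ssim_roi = lb$l_ssim_roi,
                      l_adv_roi = lb$l_adv_roi, total = lb$total,
                      d_whole = d_w, d_roi = d_r)
    if (verbose && step %% 50L == 0L) {
      message(sprintf("step %4d: G total %.4f (ssim_w %.4f), D %.4f/%.4f",
                      step, lb$total, lb$l_ssim_whole, d_w, d_r))
    }
    if (!is.null(checkpoint_dir) && config$checkpoint_interval > 0L &&
        step %% config$checkpoint_interval == 0L) {
      save_checkpoint(make_checkpoint(G, Dw, Dr, config, step),
                      file.path(checkpoint_dir, sprintf("ckpt-%05d.rds", step)))
    }
  }

  history <- tibble::as_tibble(do.call(rbind, hist))
  ckpt <- make_checkpoint(G, Dw, Dr, config, config$steps)
  if (!is.null(checkpoint_dir)) {
    save_checkpoint(ckpt, file.path(checkpoint_dir, "ckpt-final.rds"))
  }
  structure(
    list(history = history, checkpoint = ckpt, config = config,
         generator = G, d_whole = Dw, d_roi = Dr),
    class = "ggn_gan"
  )
}

# gradient of the adversarial loss wrt the scores: d/ds [-log s] = -1/s
adv_score_grad <- function(s, reduction) {
  g <- -1 / s
  if (reduction == "mean") g <- g / length(s)
  g
}

# one discriminator update on a real and a fake batch; returns the loss
update_discriminator <- function(D, real, fake, p_real, p_fake, lr, b1, b2) {
  net_zero_grads(D)
  sr <- D$forward(real, train = TRUE)
  # d/ds of -(p log s + (1-p) log(1-s))
  D$backward(-(p_real / sr - (1 - p_real) / (1 - sr)))
  sf <- D$forward(fake, train = TRUE)
  D$backward(-(p_fake / sf - (1 - p_fake) / (1 - sf)))
  net_step(D, lr, b1, b2)
  -sum(p_real * log(sr) + (1 - p_real) * log(1 - sr)) -
    sum(p_fake * log(sf) + (1 - p_fake) * log(1 - sf))
}

# the training ROI crop: config$roi_size square centred on the pair's
# (possibly larger) blanked box, clipped to bounds
roi_center_box <- function(roi_box, R, S) {
  cr <- floor((roi_box[1] + roi_box[3]) / 2)
  cc <- floor((roi_box[2] + roi_box[4]) / 2)
  r1 <- min(max(cr - floor(R / 2), 0L), S - R)
  c1 <- min(max(cc - floor(R / 2), 0L), S - R)
  as.integer(c(r1, c1, r1 + R, c1 + R))
}

stack_crops <- function(arr, boxes, R) {
  nb <- dim(arr)[3]
  out <- array(0, dim = c(R, R, nb, 1))
  for (i in seq_len(nb)) {
    b <- boxes[[i]]
    out[, , i, 1] <- arr[(b[1] + 1):b[3], (b[2] + 1):b[4], i, 1]
  }
  out
}

scatter_crops <- function(d_full, d_crop, boxes) {
  nb <- dim(d_full)[3]
  for (i in seq_len(nb)) {
    b <- boxes[[i]]
    d_full[(b[1] + 1):b[3], (b[2] + 1):b[4], i, 1] <-
      d_full[(b[1] + 1):b[3], (b[2] + 1):b[4], i, 1] + d_crop[, , i, 1]
  }
  d_full
}

make_checkpoint <- function(G, Dw, Dr, config, step) {
  structure(
    list(generator = layers_get_params(G$layers),
         d_whole = layers_get_params(Dw$layers),
         d_roi = layers_get_params(Dr$layers),
         config = config, step = step),
    class = "ggn_checkpoint"
  )
}

#' Save or load a training checkpoint
#'
#' A checkpoint is a single archive holding all three networks' parameters,
#' the [gan_config()] (including the seed) and the step count; it is
#' sufficient for inference-only generation with [generate_synthetic()].
#'
#' @param checkpoint a `ggn_checkpoint`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "ggn_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "ggn_checkpoint"))
  ckpt
}

#' Synthesise a nodule into a blanked slice
#'
#' Inference-mode forward pass of a trained generator. With
#' `composite_output` set in the checkpoint's config (the default), the
#' generated content is pasted only inside `roi_box`, so every pixel outside
#' the box is bit-identical to the input.
#'
#' @param checkpoint a `ggn_checkpoint` (or a `ggn_gan` fit, whose final
#'   checkpoint is used).
#' @param input_image a normalised, ROI-blanked [ct_slice()] (or matrix)
#'   whose side matches the checkpoint's `image_size`.
#' @param roi_box half-open 0-based box of the blanked region.
#' @return A normalised [ct_slice()].
#' @export
generate_synthetic <- function(checkpoint, input_image, roi_box) {
  if (inherits(checkpoint, "ggn_gan")) checkpoint <- checkpoint$checkpoint
  stopifnot(inherits(checkpoint, "ggn_checkpoint"))
  cfg <- checkpoint$config
  px <- as_image_matrix(input_image)
  if (nrow(px) != cfg$image_size || ncol(px) != cfg$image_size) {
    stop(sprintf("input is %dx%d but checkpoint expects %dx%d",
                 nrow(px), ncol(px), cfg$image_size, cfg$image_size),
         call. = FALSE)
  }
  G <- build_generator(cfg)
  layers_set_params(G$layers, checkpoint$generator)
  x <- array(px, dim = c(cfg$image_size, cfg$image_size, 1, 1))
  gen <- G$forward(x, train = FALSE)[, , 1, 1]
  out <- if (cfg$composite_output) {
    mask <- matrix(FALSE, nrow(px), ncol(px))
    b <- as.integer(roi_box)
    mask[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- TRUE
    composite(gen, px, mask)
  } else gen
  id0 <- if (inherits(input_image, "ct_slice")) input_image$id else "input"
  sp <- if (inherits(input_image, "ct_slice")) input_image$spacing else 1
  ct_slice(out, spacing = sp, normalized = TRUE, id = paste0(id0, "-synth"))
}

#' @export
print.ggn_gan <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<ggn_gan: %d steps at %dx%d; final total loss %.4f (ssim_whole %.4f)>\n",
              nrow(x$history), x$config$image_size, x$config$image_size,
              last$total, last$l_ssim_whole))
  invisible(x)
}

#' Tidy methods for GAN fits
#'
#' `tidy()` returns the per-step loss history (one row per optimisation
#' step, the four generator loss terms, their total, and both discriminator
#' losses); `glance()` returns a one-row summary with the final and the
#' first/last-decile mean losses.
#'
#' @param x a `ggn_gan` fit.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ggn_gan <- function(x, ...) x$history

#' @rdname tidy.ggn_gan
#' @exportS3Method generics::glance
glance.ggn_gan <- function(x, ...) {
  h <- x$history
  k <- max(1L, floor(nrow(h) / 10))
  tibble::tibble(
    steps = nrow(h),
    image_size = x$config$image_size,
    final_total = h$total[nrow(h)],
    ssim_whole_first_decile = mean(head(h$l_ssim_whole, k)),
    ssim_whole_last_decile = mean(tail(h$l_ssim_whole, k)),
    d_whole_final = h$d_whole[nrow(h)],
    d_roi_final = h$d_roi[nrow(h)]
  )
}

#' Plot the training loss history
#'
#' @param object a `ggn_gan` fit.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ggn_gan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"step",
                              names_to = "term", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "step", y = "loss", colour = NULL,
                  title = "GAN training loss history") +
    ggplot2::theme_minimal()
}
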