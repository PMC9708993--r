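#' GAN configuration
#'
#' Hyperparameters for the dual-discriminator inpainting GAN. The generator
#' is an SRGAN-style residual image-to-image network (no upsampling stage:
#' input and output sizes are equal); both discriminators are residual-block
#' classifiers, one judging the whole image and one the nodule region of
#' interest (ROI). Full-resolution CT work uses `image_size = 512`,
#' `roi_size = 32`; desk-scale runs use 64 and 4 (the same 1/16 ratio).
#'
#' @param image_size side of the (square) whole image in pixels.
#' @param roi_size side of the square ROI crop; `<= image_size`.
#' @param n_res_blocks residual blocks in the generator.
#' @param base_channels feature channels of the first stage.
#' @param learning_rate Adam learning rate for all three networks
#'   (0.0001 at full scale).
#' @param adam_betas length-2 Adam moment decay rates.
#' @param batch_size training pairs per step.
#' @param steps optimisation steps.
#' @param seed master seed; a run is a pure function of (data, config, seed).
#' @param ssim_mode `"global"` (whole-grid statistics, the default) or
#'   `"windowed"` (11x11 Gaussian sliding window; measurement only — the
#'   training path uses global statistics).
#' @param composite_output at inference, paste the generated ROI into the
#'   known input background so pixels outside the ROI are bit-identical to
#'   the input.
#' @param adv_reduction `"sum"` (as the adversarial loss is written) or
#'   `"mean"` over the batch.
#' @param label_smoothing if `TRUE`, discriminator targets are 0.9/0.1
#'   instead of 1/0 (off by default).
#' @param checkpoint_interval steps between checkpoints (0 = only at end).
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(image_size = 64, roi_size = image_size / 16,
                       n_res_blocks = 8, base_channels = 32,
                       learning_rate = 1e-4, adam_betas = c(0.9, 0.999),
                       batch_size = 4, steps = 200, seed = 1L,
                       ssim_mode = c("global", "windowed"),
                       composite_output = TRUE,
                       adv_reduction = c("sum", "mean"),
                       label_smoothing = FALSE,
                       checkpoint_interval = 0L) {
  ssim_mode <- match.arg(ssim_mode)
  adv_reduction <- match.arg(adv_reduction)
  image_size <- as.integer(image_size); roi_size <- as.integer(roi_size)
  if (image_size < 8L) stop("`image_size` too small", call. = FALSE)
  if (roi_size < 2L || roi_size > image_size) {
    stop("`roi_size` must lie in [2, image_size]", call. = FALSE)
  }
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  structure(
    list(image_size = image_size, roi_size = roi_size,
         n_res_blocks = as.integer(n_res_blocks),
         base_channels = as.integer(base_channels),
         learning_rate = learning_rate, adam_betas = adam_betas,
         batch_size = as.integer(batch_size), steps = as.integer(steps),
         seed = as.integer(seed), ssim_mode = ssim_mode,
         composite_output = isTRUE(composite_output),
         adv_reduction = adv_reduction,
         label_smoothing = isTRUE(label_smoothing),
         checkpoint_interval = as.integer(checkpoint_interval)),
    class = "gan_config"
  )
}

# ---- structural similarity --------------------------------------------------

#' Structural similarity index (SSIM) and SSIM loss
#'
#' `ssim()` computes the structural similarity index between two equal-shape
#' images with values in \[0, 1\]:
#' \deqn{S = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' with the universal constants \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}
#' at dynamic range \eqn{L = 1}. `mode = "global"` uses whole-image
#' statistics (a single value of each moment); `mode = "windowed"` averages
#' the index over an 11x11 Gaussian-weighted sliding window
#' (\eqn{\sigma = 1.5}). `ssim_loss()` is \eqn{1 - S}, zero iff the images
#' are identical, and is symmetric in its arguments.
#'
#' `formula = "as_printed"` evaluates a literal transcription of a corrupted
#' published variant of the loss (asymmetric and not unital at `x == y`),
#' kept only for side-by-side comparison; the standard form is always the
#' default and the one used in training.
#'
#' @param x,y numeric matrices of identical shape, values in \[0, 1\].
#' @param C1,C2 stabilising constants, both > 0.
#' @param mode `"global"` or `"windowed"`.
#' @param formula `"standard"` or `"as_printed"`.
#' @return `ssim()` a scalar in \[-1, 1\]; `ssim_loss()` a nonnegative scalar.
#' @export
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' ssim(x, x)           # 1
#' ssim_loss(x, x)      # 0
ssim <- function(x, y, C1 = 0.01^2, C2 = 0.03^2,
                 mode = c("global", "windowed"),
                 formula = c("standard", "as_printed")) {
  mode <- match.arg(mode); formula <- match.arg(formula)
  x <- as_image_matrix(x); y <- as_image_matrix(y)
  if (!identical(dim(x), dim(y))) stop("`x` and `y` must have the same shape", call. = FALSE)
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be > 0", call. = FALSE)
  if (formula == "as_printed") {
    if (mode != "global") stop("the printed variant is global-only", call. = FALSE)
    return(ssim_printed(x, y, C1, C2))
  }
  if (mode == "global") {
    ssim_global(x, y, C1, C2)$value
  } else {
    ssim_windowed(x, y, C1, C2)
  }
}

#' @rdname ssim
#' @export
ssim_loss <- function(x, y, C1 = 0.01^2, C2 = 0.03^2,
                      mode = c("global", "windowed"),
                      formula = c("standard", "as_printed")) {
  1 - ssim(x, y, C1, C2, mode = mode, formula = formula)
}

as_image_matrix <- function(x) {
  if (inherits(x, "ct_slice")) x <- x$pixels
  if (is.array(x) && length(dim(x)) > 2L) x <- array(x, dim = dim(x)[1:2])
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

# global-statistics SSIM with analytic gradient wrt x (population moments)
ssim_global <- function(x, y, C1, C2) {
  n <- length(x)
  mux <- mean(x); muy <- mean(y)
  vx <- mean((x - mux)^2); vy <- mean((y - muy)^2)
  sxy <- mean((x - mux) * (y - muy))
  A1 <- 2 * mux * muy + C1; A2 <- 2 * sxy + C2
  B1 <- mux^2 + muy^2 + C1; B2 <- vx + vy + C2
  S <- (A1 * A2) / (B1 * B2)
  dA1 <- 2 * muy / n
  dA2 <- 2 * (y - muy) / n
  dB1 <- 2 * mux / n
  dB2 <- 2 * (x - mux) / n
  dS <- ((dA1 * A2 + A1 * dA2) * B1 * B2 - A1 * A2 * (dB1 * B2 + B1 * dB2)) /
    (B1 * B2)^2
  list(value = S, dx = dS)
}

# literal transcription of the corrupted printed loss; returns the "index"
# such that loss = 1 - index
ssim_printed <- function(x, y, C1, C2) {
  mux <- mean(x); muy <- mean(y)
  sx <- sqrt(mean((x - mux)^2)); sy <- sqrt(mean((y - muy)^2))
  sxy <- mean((x - mux) * (y - muy))
  ((2 * mux * muy + C1) + (sxy + C2)) /
    ((mux^2 * muy^2 + C1) * (sx^2 * sy^2 + C2))
}

# 11x11 Gaussian-window SSIM via separable banded smoothing matrices
ssim_windowed <- function(x, y, C1, C2, sigma = 1.5, half = 5L) {
  G_r <- gauss_band_trunc(nrow(x), sigma, half)
  G_c <- gauss_band_trunc(ncol(x), sigma, half)
  smooth <- function(z) G_r %*% z %*% t(G_c)
  mux <- smooth(x); muy <- smooth(y)
  vx <- smooth(x * x) - mux^2
  vy <- smooth(y * y) - muy^2
  sxy <- smooth(x * y) - mux * muy
  S <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (vx + vy + C2))
  mean(S)
}

gauss_band_trunc <- function(n, sigma, half) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  k <- exp(-0.5 * ((i - j) / sigma)^2)
  k[abs(i - j) > half] <- 0
  k / rowSums(k)
}

# ---- adversarial losses -----------------------------------------------------

#' Adversarial and discriminator losses
#'
#' `adversarial_loss()` is the generator-side term
#' \eqn{\sum_n -\log D(G(x_n))} over a batch of discriminator scores
#' (natural logarithm; `reduction = "mean"` divides by the batch size).
#' `discriminator_loss()` is the binary cross-entropy
#' \eqn{-\sum \log D(\mathrm{real}) - \sum \log(1 - D(\mathrm{fake}))}.
#' All scores must lie strictly inside (0, 1).
#'
#' @param d_scores,real_scores,fake_scores numeric vectors of scores in (0, 1).
#' @param reduction `"sum"` or `"mean"`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' adversarial_loss(0.5)          # log(2)
#' discriminator_loss(0.5, 0.5)   # 2 log(2)
adversarial_loss <- function(d_scores, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  check_scores(d_scores)
  out <- -sum(log(d_scores))
  if (reduction == "mean") out <- out / length(d_scores)
  out
}

#' @rdname adversarial_loss
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  check_scores(real_scores); check_scores(fake_scores)
  -sum(log(real_scores)) - sum(log(1 - fake_scores))
}

check_scores <- function(s) {
  if (length(s) == 0L || any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    stop("scores must be non-empty and strictly inside (0, 1)", call. = FALSE)
  }
  invisible(s)
}

# ---- ROI geometry -----------------------------------------------------------

#' Crop and composite with a region-of-interest box
#'
#' `crop_roi()` extracts the half-open 0-based box
#' `(row_min, col_min, row_max, col_max)` from an image; cropping then
#' pasting back at the same box is the identity. `composite()` selects the
#' generated image inside `roi_mask` and the input elsewhere, so the known
#' background is preserved exactly.
#'
#' @param image numeric matrix (or [ct_slice()]).
#' @param roi_box length-4 half-open 0-based box.
#' @return `crop_roi()` the sub-matrix; `composite()` a matrix of the input
#'   shape.
#' @export
crop_roi <- function(image, roi_box) {
  image <- as_image_matrix(image)
  b <- as.integer(roi_box)
  if (length(b) != 4L || b[1] < 0L || b[2] < 0L ||
      b[3] > nrow(image) || b[4] > ncol(image) || b[1] >= b[3] || b[2] >= b[4]) {
    stop("`roi_box` out of bounds or degenerate", call. = FALSE)
  }
  image[(b[1] + 1L):b[3], (b[2] + 1L):b[4], drop = FALSE]
}

#' @rdname crop_roi
#' @param generated,target_input numeric matrices of identical shape.
#' @param roi_mask logical matrix of the same shape.
#' @export
composite <- function(generated, target_input, roi_mask) {
  generated <- as_image_matrix(generated)
  target_input <- as_image_matrix(target_input)
  if (!identical(dim(generated), dim(target_input)) ||
      !identical(dim(generated), dim(roi_mask))) {
    stop("`generated`, `target_input` and `roi_mask` must share one shape", call. = FALSE)
  }
  out <- target_input
  out[roi_mask] <- generated[roi_mask]
  out
}

# ---- composite generator loss -----------------------------------------------

#' Total generator loss (whole-image + ROI, SSIM + adversarial)
#'
#' The training objective splits the image into two parts and sums an SSIM
#' and an adversarial term for each:
#' \deqn{L = (L_{ssim} + L_{adv})_{whole} + (L_{ssim} + L_{adv})_{ROI}}
#' where the SSIM terms compare the generated image (and its ROI crop) with
#' the target, and the adversarial terms are \eqn{-\log D(\cdot)} of the
#' respective discriminator scores of the generated inputs.
#'
#' @param generated,target numeric matrices of identical shape, values in
#'   \[0, 1\].
#' @param roi_box half-open 0-based ROI box.
#' @param d_whole_score,d_roi_score discriminator scores in (0, 1); may be
#'   vectors for a batch.
#' @param C1,C2 SSIM constants.
#' @param adv_reduction `"sum"` or `"mean"`.
#' @return A `loss_breakdown`: list with `l_ssim_whole`, `l_adv_whole`,
#'   `l_ssim_roi`, `l_adv_roi` and `total` (their exact sum).
#' @export
total_generator_loss <- function(generated, target, roi_box,
                                 d_whole_score, d_roi_score,
                                 C1 = 0.01^2, C2 = 0.03^2,
                                 adv_reduction = "sum") {
  generated <- as_image_matrix(generated); target <- as_image_matrix(target)
  l_ssim_whole <- ssim_loss(generated, target, C1, C2)
  l_ssim_roi <- ssim_loss(crop_roi(generated, roi_box), crop_roi(target, roi_box),
                          C1, C2)
  l_adv_whole <- adversarial_loss(d_whole_score, reduction = adv_reduction)
  l_adv_roi <- adversarial_loss(d_roi_score, reduction = adv_reduction)
  loss_breakdown(l_ssim_whole, l_adv_whole, l_ssim_roi, l_adv_roi)
}

loss_breakdown <- function(l_ssim_whole, l_adv_whole, l_ssim_roi, l_adv_roi) {
  structure(
    list(l_ssim_whole = l_ssim_whole, l_adv_whole = l_adv_whole,
         l_ssim_roi = l_ssim_roi, l_adv_roi = l_adv_roi,
         total = l_ssim_whole + l_adv_whole + l_ssim_roi + l_adv_roi),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss: total %.4f = ssim_w %.4f + adv_w %.4f + ssim_roi %.4f + adv_roi %.4f>\n",
    x$total, x$l_ssim_whole, x$l_adv_whole, x$l_ssim_roi, x$l_adv_roi))
  invisible(x)
}

# ---- networks ---------------------------------------------------------------

#' Build the generator network
#'
#' SRGAN-style residual image-to-image network without the super-resolution
#' upsampling stage: a 3x3 convolution + PReLU head, `n_res_blocks` residual
#' blocks of (3x3 conv, batch norm, PReLU, 3x3 conv, batch norm) with a skip
#' connection each, a trunk convolution with a long skip back to the head
#' features, and a sigmoid-activated 3x3 output convolution enforcing
#' values in \[0, 1\]. Input and output shapes are equal.
#'
#' @param config a [gan_config()].
#' @return An object of class `ggn_network` (role `"generator"`).
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  C <- config$base_channels; B <- config$n_res_blocks
  net <- new.env(parent = emptyenv())
  net$role <- "generator"; net$input_size <- config$image_size
  L <- list(conv_in = layer_conv(1, C), act_in = layer_prelu(C))
  for (b in seq_len(B)) {
    L[[paste0("rb", b, "_conv1")]] <- layer_conv(C, C)
    L[[paste0("rb", b, "_bn1")]] <- layer_batchnorm(C)
    L[[paste0("rb", b, "_act")]] <- layer_prelu(C)
    L[[paste0("rb", b, "_conv2")]] <- layer_conv(C, C)
    L[[paste0("rb", b, "_bn2")]] <- layer_batchnorm(C)
  }
  L$conv_mid <- layer_conv(C, C)
  L$bn_mid <- layer_batchnorm(C)
  L$conv_out <- layer_conv(C, 1, gain = 1)
  L$act_out <- layer_sigmoid()
  net$layers <- L
  net$n_blocks <- B

  net$forward <- function(x, train = TRUE) {
    L <- net$layers
    f0 <- L$act_in$forward(L$conv_in$forward(x, train), train)
    h <- f0
    for (b in seq_len(net$n_blocks)) {
      t <- L[[paste0("rb", b, "_conv1")]]$forward(h, train)
      t <- L[[paste0("rb", b, "_bn1")]]$forward(t, train)
      t <- L[[paste0("rb", b, "_act")]]$forward(t, train)
      t <- L[[paste0("rb", b, "_conv2")]]$forward(t, train)
      t <- L[[paste0("rb", b, "_bn2")]]$forward(t, train)
      h <- h + t
    }
    m <- L$bn_mid$forward(L$conv_mid$forward(h, train), train)
    h2 <- m + f0
    L$act_out$forward(L$conv_out$forward(h2, train), train)
  }

  net$backward <- function(dy) {
    L <- net$layers
    dh2 <- L$conv_out$backward(L$act_out$backward(dy))
    df0 <- dh2                                  # long skip
    dh <- L$conv_mid$backward(L$bn_mid$backward(dh2))
    for (b in rev(seq_len(net$n_blocks))) {
      dt <- L[[paste0("rb", b, "_bn2")]]$backward(dh)
      dt <- L[[paste0("rb", b, "_conv2")]]$backward(dt)
      dt <- L[[paste0("rb", b, "_act")]]$backward(dt)
      dt <- L[[paste0("rb", b, "_bn1")]]$backward(dt)
      dt <- L[[paste0("rb", b, "_conv1")]]$backward(dt)
      dh <- dh + dt
    }
    df0 <- df0 + dh
    L$conv_in$backward(L$act_in$backward(df0))
  }
  class(net) <- "ggn_network"
  net
}

#' Build a discriminator network
#'
#' Residual-block classifier: a 3x3 convolution + leaky-ReLU head, then
#' stages of a strided 3x3 convolution (halving the spatial extent and
#' widening the channels) followed by a residual block, down to a 4x4 map;
#' global average pooling and a dense layer with sigmoid yield one score
#' strictly inside (0, 1). `which = "whole"` consumes `image_size` inputs,
#' `which = "roi"` consumes `roi_size` inputs.
#'
#' @param config a [gan_config()].
#' @param which `"whole"` or `"roi"`.
#' @return An object of class `ggn_network`.
#' @export
build_discriminator <- function(config, which = c("whole", "roi")) {
  stopifnot(inherits(config, "gan_config"))
  which <- match.arg(which)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + if (which == "whole") 101L else 202L)
  S <- if (which == "whole") config$image_size else config$roi_size
  C <- config$base_channels
  n_stages <- max(0L, floor(log2(S / 4)))
  net <- new.env(parent = emptyenv())
  net$role <- paste0(which, "_discriminator"); net$input_size <- S
  L <- list(conv0 = layer_conv(1, C), act0 = layer_leaky())
  w <- C
  widths <- integer(0)
  for (k in seq_len(n_stages)) {
    w2 <- min(w * 2L, 4L * C)
    L[[paste0("st", k, "_down")]] <- layer_conv(w, w2, stride = 2L)
    L[[paste0("st", k, "_bn")]] <- layer_batchnorm(w2)
    L[[paste0("st", k, "_act")]] <- layer_leaky()
    L[[paste0("st", k, "_rconv1")]] <- layer_conv(w2, w2)
    L[[paste0("st", k, "_rbn1")]] <- layer_batchnorm(w2)
    L[[paste0("st", k, "_ract")]] <- layer_leaky()
    L[[paste0("st", k, "_rconv2")]] <- layer_conv(w2, w2)
    L[[paste0("st", k, "_rbn2")]] <- layer_batchnorm(w2)
    L[[paste0("st", k, "_act2")]] <- layer_leaky()
    w <- w2
    widths <- c(widths, w2)
  }
  L$pool <- layer_global_pool()
  L$dense <- layer_dense(w, 1L)
  L$score <- layer_sigmoid()
  net$layers <- L
  net$n_stages <- n_stages

  net$forward <- function(x, train = TRUE) {
    if (dim(x)[1] != net$input_size || dim(x)[2] != net$input_size) {
      stop(sprintf("%s expects %dx%d input, got %dx%d", net$role,
                   net$input_size, net$input_size, dim(x)[1], dim(x)[2]),
           call. = FALSE)
    }
    L <- net$layers
    h <- L$act0$forward(L$conv0$forward(x, train), train)
    for (k in seq_len(net$n_stages)) {
      h <- L[[paste0("st", k, "_act")]]$forward(
        L[[paste0("st", k, "_bn")]]$forward(
          L[[paste0("st", k, "_down")]]$forward(h, train), train), train)
      t <- L[[paste0("st", k, "_rconv1")]]$forward(h, train)
      t <- L[[paste0("st", k, "_rbn1")]]$forward(t, train)
      t <- L[[paste0("st", k, "_ract")]]$forward(t, train)
      t <- L[[paste0("st", k, "_rconv2")]]$forward(t, train)
      t <- L[[paste0("st", k, "_rbn2")]]$forward(t, train)
      h <- L[[paste0("st", k, "_act2")]]$forward(h + t, train)
    }
    p <- L$pool$forward(h, train)
    s <- L$score$forward(L$dense$forward(p, train), train)
    # clamp away from exact 0/1 so log terms stay finite at double precision
    as.vector(pmin(pmax(s, 1e-12), 1 - 1e-12))
  }

  net$backward <- function(dscore) {
    L <- net$layers
    dp <- L$dense$backward(L$score$backward(matrix(dscore, 1L)))
    dh <- L$pool$backward(dp)
    for (k in rev(seq_len(net$n_stages))) {
      dsum <- L[[paste0("st", k, "_act2")]]$backward(dh)
      dt <- L[[paste0("st", k, "_rbn2")]]$backward(dsum)
      dt <- L[[paste0("st", k, "_rconv2")]]$backward(dt)
      dt <- L[[paste0("st", k, "_ract")]]$backward(dt)
      dt <- L[[paste0("st", k, "_rbn1")]]$backward(dt)
      dt <- L[[paste0("st", k, "_rconv1")]]$backward(dt)
      dh <- dsum + dt
      dh <- L[[paste0("st", k, "_down")]]$backward(
        L[[paste0("st", k, "_bn")]]$backward(
          L[[paste0("st", k, "_act")]]$backward(dh)))
    }
    L$conv0$backward(L$act0$backward(dh))
  }
  class(net) <- "ggn_network"
  net
}

#' @export
print.ggn_network <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) sum(lengths(l$params)), numeric(1)))
  cat(sprintf("<ggn_network %s: input %dx%d, %d layers, %d parameters>\n",
              x$role, x$input_size, x$input_size, length(x$layers), np))
  invisible(x)
}
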