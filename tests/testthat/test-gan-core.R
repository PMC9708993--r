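test_that("ssim is unital, symmetric and bounded on random images", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- matrix(runif(256), 16, 16)
    y <- matrix(runif(256), 16, 16)
    expect_equal(ssim(x, x), 1)
    expect_equal(ssim(x, y), ssim(y, x))
    expect_true(abs(ssim(x, y)) <= 1)
    expect_equal(ssim_loss(x, y), ssim_loss(y, x))
  }
  # constant equal images: zero variances, equal means
  expect_equal(ssim(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), 1)
  expect_equal(ssim(matrix(0.3, 4, 4), matrix(0.3, 4, 4), mode = "windowed"), 1)
  expect_error(ssim(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("ssim matches direct arithmetic on the anti-correlated 2x2 example", {
  x <- matrix(c(0, 0, 1, 1), 2, 2)   # [[0,1],[0,1]]
  y <- matrix(c(1, 1, 0, 0), 2, 2)   # [[1,0],[1,0]]
  C1 <- 1e-4; C2 <- 9e-4
  # oracle: closed form evaluated term by term
  mux <- 0.5; muy <- 0.5; vx <- 0.25; vy <- 0.25; sxy <- -0.25
  oracle <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (vx + vy + C2))
  expect_equal(ssim(x, y, C1 = C1, C2 = C2), oracle)
  expect_equal(ssim_loss(x, y, C1 = C1, C2 = C2), 1 - oracle)
})

test_that("ssim degrades monotonically with noise amplitude on average", {
  set.seed(7)
  x <- matrix(runif(1024), 32, 32)
  amps <- c(0.01, 0.05, 0.15, 0.4)
  mean_ssim <- vapply(amps, function(a) {
    mean(vapply(1:10, function(i) {
      set.seed(100 * i)
      y <- pmin(pmax(x + a * matrix(rnorm(1024), 32, 32), 0), 1)
      ssim(x, y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ssim) < 0))
})

test_that("the literal printed loss variant is exposed but not unital", {
  x <- matrix(runif(64), 8, 8)
  printed <- ssim(x, x, formula = "as_printed")
  expect_false(isTRUE(all.equal(printed, 1)))
  expect_equal(ssim_loss(x, x, formula = "as_printed"), 1 - printed)
})

test_that("adversarial and discriminator losses match their closed forms", {
  expect_equal(adversarial_loss(0.5), log(2))
  expect_equal(adversarial_loss(c(0.5, 0.25)), log(2) + log(4))
  expect_equal(adversarial_loss(1 - 1e-12), 0, tolerance = 1e-9)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2))
  expect_equal(discriminator_loss(1 - 1e-12, 1e-12), 0, tolerance = 1e-9)
  expect_error(adversarial_loss(c(0.5, 1)), "scores")
  expect_error(adversarial_loss(0), "scores")
  expect_error(discriminator_loss(numeric(0), 0.5), "scores")

  # brute-force elementwise oracles on random score lists
  set.seed(3)
  for (rep in 1:20) {
    s <- runif(sample(1:6, 1), 0.01, 0.99)
    f <- runif(sample(1:6, 1), 0.01, 0.99)
    adv_oracle <- 0; for (v in s) adv_oracle <- adv_oracle - log(v)
    expect_equal(adversarial_loss(s), adv_oracle)
    expect_equal(adversarial_loss(s, reduction = "mean"), adv_oracle / length(s))
    d_oracle <- 0
    for (v in s) d_oracle <- d_oracle - log(v)
    for (v in f) d_oracle <- d_oracle - log(1 - v)
    expect_equal(discriminator_loss(s, f), d_oracle)
  }
})

test_that("total generator loss composes its four terms exactly", {
  set.seed(5)
  gen <- matrix(runif(64), 8, 8)
  tgt <- matrix(runif(64), 8, 8)
  box <- c(2, 2, 6, 6)
  lb <- total_generator_loss(gen, tgt, box, 0.5, 0.5)
  expect_equal(lb$total,
               lb$l_ssim_whole + lb$l_adv_whole + lb$l_ssim_roi + lb$l_adv_roi,
               tolerance = 1e-12)
  expect_true(lb$total >= max(lb$l_ssim_whole, lb$l_adv_whole,
                              lb$l_ssim_roi, lb$l_adv_roi))
  # oracle: compose the two closed forms independently
  expect_equal(lb$l_adv_whole, log(2))
  expect_equal(lb$l_adv_roi, log(2))
  expect_equal(lb$l_ssim_whole, 1 - ssim(gen, tgt))
  expect_equal(lb$l_ssim_roi, 1 - ssim(gen[3:6, 3:6], tgt[3:6, 3:6]))
  # perfect-generator limit
  lb0 <- total_generator_loss(tgt, tgt, box, 1 - 1e-12, 1 - 1e-12)
  expect_equal(lb0$total, 0, tolerance = 1e-9)
})

test_that("crop_roi and composite follow half-open box semantics", {
  img <- matrix(1:16, 4, 4)
  expect_identical(crop_roi(img[1:2, 1:2], c(0, 0, 2, 2)), img[1:2, 1:2])
  expect_identical(crop_roi(img, c(1, 1, 3, 3)), img[2:3, 2:3])
  expect_error(crop_roi(img, c(0, 0, 5, 2)), "roi_box")

  # crop then paste back reproduces the image
  patch <- crop_roi(img, c(1, 1, 3, 3))
  img2 <- img; img2[2:3, 2:3] <- patch
  expect_identical(img2, img)

  gen <- matrix(runif(16), 4, 4); inp <- matrix(runif(16), 4, 4)
  expect_identical(composite(gen, inp, matrix(FALSE, 4, 4)), inp)
  expect_identical(composite(gen, inp, matrix(TRUE, 4, 4)), gen)
  m <- matrix(c(TRUE, FALSE), 4, 4)
  out <- composite(gen, inp, m)
  for (i in 1:4) for (j in 1:4) {
    expect_identical(out[i, j], if (m[i, j]) gen[i, j] else inp[i, j])
  }
  expect_error(composite(gen, matrix(0, 3, 3), m), "shape")
})

test_that("generator output shape and range contracts hold across sizes", {
  for (S in c(32, 64, 128)) {
    cfg <- gan_config(image_size = S, roi_size = max(4, S / 16),
                      n_res_blocks = 1, base_channels = 4, seed = 2)
    G <- build_generator(cfg)
    x <- array(0, dim = c(S, S, 1, 1))
    out <- G$forward(x, train = FALSE)
    expect_equal(dim(out), c(S, S, 1, 1))
    expect_true(all(out >= 0 & out <= 1))
  }
  # inference determinism
  cfg <- tiny_gan_config()
  G <- build_generator(cfg)
  set.seed(1)
  x <- array(runif(32 * 32), dim = c(32, 32, 1, 1))
  expect_identical(G$forward(x, train = FALSE), G$forward(x, train = FALSE))
})

test_that("discriminators score in (0,1) and reject mismatched inputs", {
  cfg <- gan_config(image_size = 64, roi_size = 32, n_res_blocks = 1,
                    base_channels = 4, seed = 3)
  Dr <- build_discriminator(cfg, "roi")
  set.seed(2)
  s <- Dr$forward(array(runif(32 * 32), dim = c(32, 32, 1, 1)), train = FALSE)
  expect_length(s, 1)
  expect_true(is.finite(s) && s > 0 && s < 1)
  Dw <- build_discriminator(cfg, "whole")
  expect_error(Dw$forward(array(0, dim = c(32, 32, 1, 1))), "64x64")
  # scores vary with input but stay strictly interior
  scores <- vapply(1:5, function(i) {
    set.seed(i)
    Dr$forward(array(runif(32 * 32), dim = c(32, 32, 1, 1)), train = FALSE)
  }, numeric(1))
  expect_true(all(scores > 0 & scores < 1))
})
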