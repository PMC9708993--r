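test_that("extraction yields exactly 93 features across the six families", {
  ds <- make_phantom_dataset(1, 1, tiny_phantom_config(64), seed = 9)
  ann <- ds$annotation[[1]]
  mask <- matrix(FALSE, 64, 64)
  mask[(ann$bbox[1] + 1):ann$bbox[3], (ann$bbox[2] + 1):ann$bbox[4]] <- TRUE
  fv <- extract_features(ds$slice[[1]], mask)
  expect_equal(nrow(fv), 93)
  counts <- table(fv$family)
  expect_equal(unname(counts[c("first_order", "glcm", "gldm", "glrlm",
                               "glszm", "ngtdm")]),
               c(18L, 24L, 14L, 16L, 16L, 5L), ignore_attr = TRUE)
  expect_true(all(is.finite(fv$value)))
  expect_silent(validate_feature_vector(fv))
  # the invariant holds on several random inputs
  set.seed(4)
  for (rep in 1:3) {
    img <- matrix(runif(400, 0, 200), 20, 20)
    m <- matrix(runif(400) < 0.7, 20, 20)
    fv2 <- extract_features(img, m, radiomics_config(bin_width = 20))
    expect_equal(nrow(fv2), 93)
  }
  expect_error(extract_features(ds$slice[[1]], matrix(FALSE, 64, 64)), "empty")
})

test_that("a constant masked region degenerates to the documented conventions", {
  img <- matrix(0.5, 10, 10)
  fv <- extract_features(img, matrix(TRUE, 10, 10), radiomics_config(bin_width = 0.05))
  val <- function(fam, feat) fv$value[fv$family == fam & fv$feature == feat]
  expect_equal(val("first_order", "mean"), 0.5)
  expect_equal(val("first_order", "variance"), 0)
  expect_equal(val("first_order", "skewness"), 0)   # undefined -> 0
  expect_equal(val("first_order", "kurtosis"), 0)
  expect_equal(val("first_order", "entropy"), 0)
  expect_equal(val("first_order", "uniformity"), 1)
  expect_equal(val("first_order", "range"), 0)
  # single grey level: correlation convention 1, contrast 0
  expect_equal(val("glcm", "correlation"), 1)
  expect_equal(val("glcm", "contrast"), 0)
  expect_equal(val("ngtdm", "contrast"), 0)
})

test_that("first-order energy and entropy match direct hand evaluation on a 4x4 grid", {
  img <- matrix(c(1, 2, 2, 3,
                  4, 1, 2, 2,
                  3, 3, 1, 4,
                  2, 1, 4, 4), 4, 4, byrow = TRUE)
  fv <- extract_features(img, matrix(TRUE, 4, 4), radiomics_config(bin_width = 1))
  val <- function(feat) fv$value[fv$family == "first_order" & fv$feature == feat]
  # oracle: independent elementwise computation
  x <- as.vector(img)
  expect_equal(val("energy"), sum(x^2))
  expect_equal(val("total_energy"), sum(x^2))       # spacing 1
  counts <- table(x)                                # bin width 1: one level per value
  p <- as.vector(counts) / 16
  expect_equal(val("entropy"), -sum(p * log2(p)))
  expect_equal(val("uniformity"), sum(p^2))
  expect_equal(val("mean"), mean(x))
  expect_equal(val("median"), median(x))
  expect_equal(val("variance"), mean((x - mean(x))^2))
  expect_equal(val("root_mean_squared"), sqrt(mean(x^2)))
  expect_equal(val("mean_absolute_deviation"), mean(abs(x - mean(x))))
  expect_equal(val("interquartile_range"),
               unname(quantile(x, 0.75) - quantile(x, 0.25)))
  expect_equal(val("skewness"), mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(val("kurtosis"), mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
})

test_that("GLCM features match a brute-force pair-enumeration oracle", {
  set.seed(11)
  img <- matrix(sample(1:3, 25, replace = TRUE), 5, 5)
  L <- img                        # bin width 1 on integers 1..3: levels = values
  fv <- extract_features(img, matrix(TRUE, 5, 5), radiomics_config(bin_width = 1))
  val <- function(feat) fv$value[fv$family == "glcm" & fv$feature == feat]

  # oracle: enumerate all neighbouring pixel pairs per direction by loops
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  per_dir <- lapply(dirs, function(d) {
    P <- matrix(0, 3, 3)
    for (i in 1:5) for (j in 1:5) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 >= 1 && i2 <= 5 && j2 >= 1 && j2 <= 5) {
        P[L[i, j], L[i2, j2]] <- P[L[i, j], L[i2, j2]] + 1
        P[L[i2, j2], L[i, j]] <- P[L[i2, j2], L[i, j]] + 1   # symmetric
      }
    }
    P / sum(P)
  })
  contrast_oracle <- mean(vapply(per_dir, function(p) {
    s <- 0
    for (a in 1:3) for (b in 1:3) s <- s + (a - b)^2 * p[a, b]
    s
  }, numeric(1)))
  energy_oracle <- mean(vapply(per_dir, function(p) sum(p^2), numeric(1)))
  maxprob_oracle <- mean(vapply(per_dir, max, numeric(1)))
  expect_equal(val("contrast"), contrast_oracle)
  expect_equal(val("joint_energy"), energy_oracle)
  expect_equal(val("maximum_probability"), maxprob_oracle)
})

test_that("run-length and size-zone matrices are counted correctly on a toy grid", {
  img <- matrix(c(1, 1, 2,
                  1, 2, 2,
                  3, 3, 3), 3, 3, byrow = TRUE)
  # horizontal direction (0,1): runs per row are
  # (1,len2)(2,len1) / (1,len1)(2,len2) / (3,len3)
  P <- ggnforge:::glrlm_matrix(img, 3, 0L, 1L)
  expect_equal(P[1, 2], 1)  # one run of level 1, length 2
  expect_equal(P[1, 1], 1)
  expect_equal(P[2, 1], 1)
  expect_equal(P[2, 2], 1)
  expect_equal(P[3, 3], 1)
  expect_equal(sum(P), 5)

  # 8-connected zones: level 1 (3 px), level 2 (3 px), level 3 (3 px)
  Z <- ggnforge:::glszm_matrix(img, 3)
  expect_equal(dim(Z), c(3, 3))
  expect_equal(Z[1, 3], 1)
  expect_equal(Z[2, 3], 1)
  expect_equal(Z[3, 3], 1)
  expect_equal(sum(Z), 3)
})

test_that("NGTDM components match a direct neighbourhood-loop oracle", {
  set.seed(5)
  img <- matrix(sample(1:3, 16, replace = TRUE), 4, 4)
  fv <- extract_features(img, matrix(TRUE, 4, 4), radiomics_config(bin_width = 1))
  val <- function(feat) fv$value[fv$family == "ngtdm" & fv$feature == feat]

  # oracle: per-pixel mean of 8-neighbours by explicit loops
  s <- numeric(3); ni <- integer(3)
  for (i in 1:4) for (j in 1:4) {
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= 4 && j2 >= 1 && j2 <= 4) nb <- c(nb, img[i2, j2])
    }
    lev <- img[i, j]
    s[lev] <- s[lev] + abs(lev - mean(nb))
    ni[lev] <- ni[lev] + 1
  }
  p <- ni / 16
  coarse_oracle <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  expect_equal(val("coarseness"), coarse_oracle)
  present <- which(p > 0); Ngp <- length(present)
  contrast_oracle <- (sum(outer(p, p) * outer(1:3, 1:3, `-`)^2) / (Ngp * (Ngp - 1))) *
    (sum(s) / 16)
  expect_equal(val("contrast"), contrast_oracle)
})

test_that("GLDM dependence counts respect the 8-neighbourhood definition", {
  img <- matrix(1, 3, 3)
  fv <- extract_features(img, matrix(TRUE, 3, 3), radiomics_config(bin_width = 1))
  val <- function(feat) fv$value[fv$family == "gldm" & fv$feature == feat]
  # uniform 3x3 grid: centre has 8 dependent neighbours (j = 9), edges 5
  # (j = 6), corners 3 (j = 4); large-dependence emphasis is the mean of j^2
  lde_oracle <- (4 * 4^2 + 4 * 6^2 + 1 * 9^2) / 9
  expect_equal(val("large_dependence_emphasis"), lde_oracle)
  expect_equal(val("grey_level_non_uniformity"), 9)   # single level: Nz^2/Nz
})
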