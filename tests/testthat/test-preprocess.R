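test_that("seed filling floods uniform grids completely and stops at rings", {
  s <- ct_slice(matrix(-900, 6, 6))
  expect_true(all(segment_lung_seed_fill(s, c(3, 3), threshold = -400)))

  # 10x10 grid with a high-intensity ring enclosing the seed
  g <- matrix(-900, 10, 10)
  g[3, 3:7] <- 100; g[7, 3:7] <- 100; g[3:7, 3] <- 100; g[3:7, 7] <- 100
  mask <- segment_lung_seed_fill(ct_slice(g), c(5, 5), threshold = -400)
  oracle <- bfs_component(g, c(5, 5), -400)
  expect_identical(mask, oracle)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] %in% 4:6))

  expect_error(segment_lung_seed_fill(ct_slice(g), c(3, 3), threshold = -400),
               "boundary")
  expect_error(segment_lung_seed_fill(ct_slice(g), c(99, 1), threshold = -400),
               "outside")
})

test_that("seed filling equals the 4-connected component oracle on random grids", {
  set.seed(42)
  for (rep in 1:8) {
    g <- matrix(sample(c(-900, 100), 256, replace = TRUE, prob = c(0.6, 0.4)), 16, 16)
    seeds <- which(g < -400, arr.ind = TRUE)
    sp <- seeds[sample.int(nrow(seeds), 1), ]
    expect_identical(
      segment_lung_seed_fill(ct_slice(g), sp, threshold = -400),
      bfs_component(g, sp, -400)
    )
  }
})

test_that("strip_and_pad centres the masked content on a zero canvas", {
  # identity placement: mask covers the whole target-size grid
  s <- ct_slice(matrix(rnorm(32 * 32), 32, 32))
  out <- strip_and_pad(s, matrix(TRUE, 32, 32), 32)
  expect_equal(out$pixels, s$pixels)
  expect_equal(attr(out, "offset"), c(0, 0))

  # 20x20 slice, central 8x8 mask block, target 32: manual index arithmetic
  s2 <- ct_slice(matrix(seq_len(400), 20, 20))
  m2 <- matrix(FALSE, 20, 20); m2[7:14, 7:14] <- TRUE
  out2 <- strip_and_pad(s2, m2, 32)
  nz <- which(out2$pixels != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] %in% 13:20) && all(nz[, 2] %in% 13:20))
  expect_equal(out2$pixels[13:20, 13:20], s2$pixels[7:14, 7:14])
  off <- attr(out2, "offset")
  expect_equal(off, c(12 - 6, 12 - 6))

  expect_error(strip_and_pad(s2, matrix(FALSE, 20, 20), 32), "empty")
  big <- matrix(TRUE, 40, 40)
  expect_error(strip_and_pad(ct_slice(matrix(0, 40, 40)), big, 32), "larger")
})

test_that("window normalisation clips and maps endpoints analytically", {
  s <- ct_slice(matrix(c(-1000, 400, -300, -2000, 1000, 0), 2, 3))
  out <- normalize_intensity(s, c(-1000, 400))
  expect_true(out$normalized)
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[2, 1], 1)
  expect_equal(out$pixels[1, 2], 0.5)     # (-300 + 1000) / 1400
  expect_equal(out$pixels[2, 2], 0)       # clipped below
  expect_equal(out$pixels[1, 3], 1)       # clipped above
  # idempotence with the unit window
  again <- normalize_intensity(out, c(0, 1))
  expect_identical(again$pixels, out$pixels)
  expect_error(normalize_intensity(s, c(5, 5)), "window")
})

test_that("blank_roi honours the training-pair invariants", {
  px <- matrix(runif(64 * 64), 64, 64)
  s <- ct_slice(px, normalized = TRUE)
  ann <- nodule_annotation(centroid = c(40, 30), bbox = c(36, 26, 44, 34), grade = 1)
  pair <- blank_roi(s, ann, roi_size = 16)

  expect_true(all(pair$input_image$pixels[pair$roi_mask] == 0))
  expect_identical(pair$input_image$pixels[!pair$roi_mask],
                   pair$target_image$pixels[!pair$roi_mask])
  b <- pair$roi_box
  expect_equal(sum(pair$roi_mask), 16 * 16)
  expect_true(all(pair$roi_mask[(b[1] + 1):b[3], (b[2] + 1):b[4]]))
  # round trip: pasting the target ROI back reproduces the target exactly
  rebuilt <- pair$input_image$pixels
  rebuilt[pair$roi_mask] <- pair$target_image$pixels[pair$roi_mask]
  expect_identical(rebuilt, pair$target_image$pixels)
})

test_that("blank_roi shifts (never shrinks) the box at image borders", {
  s <- ct_slice(matrix(runif(64 * 64), 64, 64), normalized = TRUE)
  ann <- nodule_annotation(centroid = c(0, 0), bbox = c(0, 0, 2, 2), grade = 1)
  pair <- blank_roi(s, ann, roi_size = 32)
  expect_equal(pair$roi_box, c(0, 0, 32, 32))

  raw <- ct_slice(matrix(0, 64, 64), normalized = FALSE)
  expect_error(blank_roi(raw, ann, 32), "normalised")
  expect_error(blank_roi(s, ann, 64), "roi_size")
})

test_that("the preprocessing chain produces valid pairs from phantoms", {
  ds <- make_phantom_dataset(2, 1, tiny_phantom_config(64), seed = 5)
  out <- preprocess_dataset(ds, preprocess_config(target_size = 96, roi_size = 16))
  for (p in out$pair) {
    expect_s3_class(p$input_image, "ct_slice")
    expect_true(p$input_image$normalized)
    expect_equal(dim(p$input_image$pixels), c(96, 96))
    expect_true(all(p$input_image$pixels[p$roi_mask] == 0))
    # the blanked box should straddle actual lung content, not empty canvas
    expect_gt(sum(p$target_image$pixels[p$roi_mask]), 0)
  }
})

test_that("mask hole filling closes enclosed holes only", {
  m <- matrix(FALSE, 8, 8)
  m[2:7, 2:7] <- TRUE
  m[4:5, 4:5] <- FALSE            # interior hole
  filled <- fill_mask_holes(m)
  expect_true(all(filled[2:7, 2:7]))
  expect_false(any(filled[1, ]))  # border background untouched
})
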