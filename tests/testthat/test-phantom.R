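test_that("phantom slices are deterministic under a fixed seed", {
  cfg <- tiny_phantom_config(64)
  a <- generate_lung_slice(cfg, seed = 7)
  b <- generate_lung_slice(cfg, seed = 7)
  expect_identical(a$slice$pixels, b$slice$pixels)
  expect_identical(a$lung_mask, b$lung_mask)
  expect_false(identical(a$slice$pixels,
                         generate_lung_slice(cfg, seed = 8)$slice$pixels))
})

test_that("noise-free, vessel-free lungs sit exactly at the lung base intensity", {
  cfg <- phantom_config(image_size = 64, vessel_count = 0, noise_sd = 0)
  ph <- generate_lung_slice(cfg, seed = 1)
  expect_true(all(ph$slice$pixels[ph$lung_mask] == cfg$lung_base))
  expect_true(all(ph$slice$pixels[!ph$lung_mask] %in% c(cfg$air, cfg$soft_tissue)))
})

test_that("lung-mask area matches the ellipse-equation oracle and plausible bounds", {
  cfg <- tiny_phantom_config(128)
  ph <- generate_lung_slice(cfg, seed = 3)
  frac <- mean(ph$lung_mask)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.55)
  # oracle: count pixels satisfying either lung-ellipse equation directly,
  # clipped to the body ellipse
  n <- 128
  r <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  in_ell <- function(center, axes) {
    ((r - center[1] * n) / (axes[1] * n))^2 + ((cc - center[2] * n) / (axes[2] * n))^2 <= 1
  }
  body <- ((r - 0.52 * n) / (0.42 * n))^2 + ((cc - 0.5 * n) / (0.45 * n))^2 <= 1
  oracle <- (in_ell(cfg$lung_ellipse_params[[1]]$center, cfg$lung_ellipse_params[[1]]$axes) |
             in_ell(cfg$lung_ellipse_params[[2]]$center, cfg$lung_ellipse_params[[2]]$axes)) & body
  expect_identical(ph$lung_mask, oracle)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(image_size = 16), "image_size")
  expect_error(phantom_config(image_size = 64, lesion_peak_opacity_range = c(0, 1)),
               "opacity")
  expect_error(phantom_config(image_size = 64, lesion_radius_range = c(3, 20)),
               "radius")
})

test_that("lesion implantation honours the disc oracle and rejects degenerate input", {
  cfg <- phantom_config(image_size = 64, vessel_count = 0, noise_sd = 0)
  ph <- generate_lung_slice(cfg, seed = 2)
  ctr <- round(cfg$lung_ellipse_params[[1]]$center * 64)

  expect_error(implant_lesion(ph, ctr, radius = 4, peak_opacity = 0, grade = 5,
                              config = cfg),
               "degenerate")
  expect_error(implant_lesion(ph, c(1, 1), radius = 4, peak_opacity = 0.5,
                              grade = 5, config = cfg),
               "lung mask")

  res <- implant_lesion(ph, ctr, radius = 4, peak_opacity = 0.6, grade = 5,
                        seed = 9, config = cfg)
  changed <- res$slice$pixels != ph$slice$pixels
  # oracle: direct rasterisation of the radius-4 disc, clipped to the mask
  rr <- matrix(seq_len(64), 64, 64); cc <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  disc <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) <= 4 & ph$lung_mask
  expect_identical(changed, disc)
  # annotation bbox is the tight box of the disc (0-based half-open)
  idx <- which(disc, arr.ind = TRUE)
  expect_equal(res$annotation$bbox,
               c(min(idx[, 1]) - 1, min(idx[, 2]) - 1, max(idx[, 1]), max(idx[, 2])))
})

test_that("lesion implantation is deterministic and grade-aware", {
  cfg <- tiny_phantom_config(64)
  ph <- generate_lung_slice(cfg, seed = 4)
  ctr <- round(cfg$lung_ellipse_params[[2]]$center * 64)
  a <- implant_lesion(ph, ctr, 5, 0.5, grade = 1, seed = 11, config = cfg)
  b <- implant_lesion(ph, ctr, 5, 0.5, grade = 1, seed = 11, config = cfg)
  expect_identical(a$annotation$bbox, b$annotation$bbox)
  expect_identical(a$slice$pixels, b$slice$pixels)
  expect_true(a$annotation$is_ggn)
  solid <- implant_lesion(ph, ctr, 5, 0.5, grade = 5, seed = 11, config = cfg)
  expect_false(solid$annotation$is_ggn)
  # subsolid interiors are textured (non-constant), solid discs near-uniform
  ggn_delta <- (a$slice$pixels - ph$slice$pixels)
  expect_gt(sd(ggn_delta[ggn_delta > 0]), 0)
})

test_that("phantom datasets hit the exact GGN count and stay inside the lungs", {
  cfg <- tiny_phantom_config(64)
  ds <- make_phantom_dataset(10, ggn_fraction = 0.5, config = cfg, seed = 3)
  expect_equal(sum(ds$is_ggn), 5)

  ds1 <- make_phantom_dataset(1, ggn_fraction = 0, config = cfg, seed = 3)
  expect_equal(ds1$grade, 5L)

  ds2 <- make_phantom_dataset(40, ggn_fraction = 0.25, config = cfg, seed = 11)
  expect_equal(sum(ds2$is_ggn), 10)
  # oracle: every centroid lies inside its stored lung mask
  inside <- purrr::map2_lgl(ds2$annotation, ds2$lung_mask, function(a, m) {
    m[round(a$centroid[1]) + 1, round(a$centroid[2]) + 1]
  })
  expect_true(all(inside))
  # containment: all pixels changed by the lesion lie inside the lung mask
  seeds <- attr(ds2, "slice_seeds")
  contained <- purrr::map_lgl(seq_len(5), function(i) {
    base <- generate_lung_slice(cfg, seed = seeds[i])
    changed <- ds2$slice[[i]]$pixels != base$slice$pixels
    all(ds2$lung_mask[[i]][changed])
  })
  expect_true(all(contained))
  # reproducibility of the whole dataset
  ds2b <- make_phantom_dataset(40, ggn_fraction = 0.25, config = cfg, seed = 11)
  expect_identical(ds2$slice[[5]]$pixels, ds2b$slice[[5]]$pixels)
})
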