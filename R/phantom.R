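#' Configuration for the synthetic lung-slice phantom generator
#'
#' The phantom generator emulates an axial low-dose chest-CT slice on a
#' Hounsfield-like scale: background air at -1000, a soft-tissue body
#' ellipse at +40, two lung-field ellipses at a lung base intensity of -800
#' with additive Gaussian noise, and a configurable number of bright
#' curvilinear vessel structures inside the lungs. Lesions (subsolid
#' ground-glass or solid) are implanted separately with [implant_lesion()].
#'
#' @param image_size pixels per side (square grid), >= 32.
#' @param lung_ellipse_params list of two lists, each `list(center = c(row,
#'   col), axes = c(a_row, a_col))` in fractions of `image_size`; defaults
#'   place two lungs symmetrically inside the body ellipse.
#' @param vessel_count number of curvilinear vessels per lung field.
#' @param noise_sd standard deviation of additive lung-field noise,
#'   intensity units.
#' @param lesion_radius_range length-2 numeric, lesion radii in pixels.
#' @param lesion_peak_opacity_range length-2 numeric in (0, 1\]; peak lesion
#'   amplitude as a fraction of the lung-to-soft-tissue intensity gap.
#' @param texture_scale smoothing length (pixels) of the multiplicative
#'   lesion texture field.
#' @param air,lung_base,soft_tissue intensities of the three tissue classes.
#' @param seed default seed used when an operation is not given one.
#'
#' @return A list of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 64)
#' ph <- generate_lung_slice(cfg, seed = 7)
#' range(ph$slice$pixels)
phantom_config <- function(image_size = 64,
                           lung_ellipse_params = NULL,
                           vessel_count = 6,
                           noise_sd = 25,
                           lesion_radius_range = c(3, 7),
                           lesion_peak_opacity_range = c(0.35, 0.8),
                           texture_scale = 3,
                           air = -1000, lung_base = -800, soft_tissue = 40,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L) {
    stop("`image_size` must be an integer >= 32", call. = FALSE)
  }
  if (is.null(lung_ellipse_params)) {
    lung_ellipse_params <- list(
      list(center = c(0.52, 0.32), axes = c(0.30, 0.16)),
      list(center = c(0.52, 0.68), axes = c(0.30, 0.16))
    )
  }
  if (length(lung_ellipse_params) != 2L) {
    stop("`lung_ellipse_params` must describe exactly two lung ellipses", call. = FALSE)
  }
  if (any(lesion_peak_opacity_range <= 0) || any(lesion_peak_opacity_range > 1)) {
    stop("`lesion_peak_opacity_range` must lie in (0, 1]", call. = FALSE)
  }
  if (max(lesion_radius_range) > image_size / 8) {
    stop("lesion radius must not exceed image_size / 8", call. = FALSE)
  }
  structure(
    list(image_size = image_size, lung_ellipse_params = lung_ellipse_params,
         vessel_count = as.integer(vessel_count), noise_sd = noise_sd,
         lesion_radius_range = lesion_radius_range,
         lesion_peak_opacity_range = lesion_peak_opacity_range,
         texture_scale = texture_scale, air = air, lung_base = lung_base,
         soft_tissue = soft_tissue, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# ellipse interior mask on an n x n grid; center/axes in pixel units (1-based)
ellipse_mask <- function(n, center, axes) {
  r <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

#' Generate one synthetic lung-slice phantom
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   output.
#' @return A list with elements `slice` (a raw-scale [ct_slice()]) and
#'   `lung_mask` (logical matrix marking lung-field pixels).
#' @export
generate_lung_slice <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  body <- ellipse_mask(n, center = c(0.52, 0.5) * n, axes = c(0.42, 0.45) * n)
  img <- matrix(config$air, n, n)
  img[body] <- config$soft_tissue

  lung_mask <- matrix(FALSE, n, n)
  for (ell in config$lung_ellipse_params) {
    lung_mask <- lung_mask | ellipse_mask(n, ell$center * n, ell$axes * n)
  }
  lung_mask <- lung_mask & body
  img[lung_mask] <- config$lung_base
  if (config$noise_sd > 0) {
    img[lung_mask] <- img[lung_mask] + rnorm(sum(lung_mask), 0, config$noise_sd)
  }

  # bright curvilinear vessels: damped random walks from near each lung centre
  if (config$vessel_count > 0) {
    for (ell in config$lung_ellipse_params) {
      for (v in seq_len(config$vessel_count)) {
        pos <- ell$center * n + rnorm(2, 0, 2)
        heading <- runif(1, 0, 2 * pi)
        len <- round(runif(1, 0.15, 0.45) * n)
        for (s in seq_len(len)) {
          heading <- heading + rnorm(1, 0, 0.35)
          pos <- pos + c(sin(heading), cos(heading))
          r0 <- round(pos[1]); c0 <- round(pos[2])
          if (r0 < 1 || r0 > n || c0 < 1 || c0 > n || !lung_mask[r0, c0]) break
          img[r0, c0] <- config$soft_tissue * 0.5
        }
      }
    }
  }

  slice <- ct_slice(img, spacing = 0.7, normalized = FALSE,
                    id = sprintf("phantom-s%d", seed))
  list(slice = slice, lung_mask = lung_mask)
}

#' Implant a lesion into a lung-slice phantom
#'
#' Adds a radially decaying textured blob clipped to the lung mask. Grades
#' 1-2 produce a subsolid (ground-glass-like) lesion: a smooth raised-cosine
#' radial profile scaled by `peak_opacity` and modulated by multiplicative
#' smoothed-noise texture, so the interior is non-constant. Grade 5 produces
#' a near-uniform solid disc at the soft-tissue intensity. The annotation
#' bounding box is the tight box of pixels changed by more than `epsilon`.
#'
#' @param phantom list `(slice, lung_mask)` as returned by
#'   [generate_lung_slice()], or a [ct_slice()] plus `lung_mask`.
#' @param center length-2 (row, col), 1-based pixel coordinates; must be
#'   inside the lung mask.
#' @param radius lesion radius in pixels, > 0.
#' @param peak_opacity peak amplitude as a fraction of the lung-to-soft-tissue
#'   gap, in (0, 1].
#' @param grade texture grade 1..5; `<= 2` gives a subsolid GGN, `5` a solid
#'   disc.
#' @param seed integer seed for the texture field.
#' @param config the [phantom_config()] supplying intensities and texture
#'   scale.
#' @param epsilon change threshold defining the annotation's bounding box.
#' @return A list `(slice, annotation)` with the modified [ct_slice()] and a
#'   [nodule_annotation()] (0-based coordinates).
#' @export
implant_lesion <- function(phantom, center, radius, peak_opacity, grade,
                           seed = 1L, config = phantom_config(nrow(phantom$slice$pixels)),
                           epsilon = 1e-6) {
  slice <- phantom$slice
  lung_mask <- phantom$lung_mask
  stopifnot(inherits(slice, "ct_slice"), is.logical(lung_mask))
  n <- nrow(slice$pixels)
  r0 <- round(center[1]); c0 <- round(center[2])
  if (r0 < 1 || r0 > n || c0 < 1 || c0 > ncol(slice$pixels) || !lung_mask[r0, c0]) {
    stop("lesion center must lie inside the lung mask", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (peak_opacity <= 0) {
    stop("degenerate lesion: `peak_opacity` must be > 0", call. = FALSE)
  }
  grade <- as.integer(grade)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  inside <- d <= radius

  amp <- peak_opacity * (config$soft_tissue - config$lung_base)
  if (grade <= 2L) {
    profile <- 0.5 * (1 + cos(pi * pmin(d / radius, 1)))   # raised cosine
    texture <- smooth_noise_field(n, config$texture_scale)
    delta <- amp * profile * (0.75 + 0.5 * texture)
  } else {
    # solid: near-uniform disc; the narrow rim roll-off stays strictly
    # positive at d == radius so the changed set is the full rasterised disc
    edge <- pmin((radius + 0.5 - d) / max(1, radius * 0.25), 1)
    profile <- pmax(edge, 0)
    delta <- amp * profile
  }
  delta[!inside] <- 0
  delta[!lung_mask] <- 0

  px <- slice$pixels + delta
  changed <- abs(delta) > epsilon
  if (!any(changed)) {
    stop("degenerate lesion: no pixel changed by more than epsilon", call. = FALSE)
  }
  idx <- which(changed, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]) - 1, min(idx[, 2]) - 1, max(idx[, 1]), max(idx[, 2]))
  ann <- nodule_annotation(
    centroid = c(center[1] - 1, center[2] - 1), bbox = bbox, grade = grade,
    id = sprintf("%s-g%d", slice$id, grade)
  )
  out <- ct_slice(px, spacing = slice$spacing, normalized = FALSE, id = slice$id)
  list(slice = out, annotation = ann)
}

# smoothed uniform noise in [-1, 1], zero-mean-ish, smoothing length `scale`
smooth_noise_field <- function(n, scale) {
  z <- matrix(runif(n * n, -1, 1), n, n)
  if (scale > 1) {
    k <- make_gauss_band(n, sigma = scale / 2)
    z <- k %*% z %*% t(k)
    m <- max(abs(z))
    if (m > 0) z <- z / m
  }
  z
}

# row-normalised banded Gaussian smoothing matrix (n x n)
make_gauss_band <- function(n, sigma) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  k <- exp(-0.5 * ((i - j) / sigma)^2)
  k / rowSums(k)
}

#' Generate a dataset of lesion-bearing phantom slices
#'
#' Each slice carries exactly one lesion; `round(n_slices * ggn_fraction)`
#' lesions are ground-glass (grade drawn from \{1, 2\}), the rest solid
#' (grade 5). Lesion placement is rejected-sampled inside the lung mask with
#' a margin of one radius; after 20 failed attempts per slice the generator
#' raises an error rather than looping forever.
#'
#' @param n_slices number of slices, >= 1.
#' @param ggn_fraction fraction in \[0, 1\] of slices receiving a GGN.
#' @param config a [phantom_config()].
#' @param seed integer master seed; the run is reproducible from
#'   `(n_slices, ggn_fraction, config, seed)`.
#' @return A tibble with one row per slice and list-columns `slice`
#'   (the [ct_slice()]), `lung_mask`, and `annotation`, plus unpacked columns
#'   `id`, `grade`, `is_ggn`.
#' @export
make_phantom_dataset <- function(n_slices, ggn_fraction, config = phantom_config(),
                                 seed = config$seed) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  if (ggn_fraction < 0 || ggn_fraction > 1) {
    stop("`ggn_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n_ggn <- round(n_slices * ggn_fraction)
  is_ggn <- c(rep(TRUE, n_ggn), rep(FALSE, n_slices - n_ggn))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  slice_seeds <- sample.int(.Machine$integer.max, n_slices)
  grades_ggn <- sample(1:2, n_slices, replace = TRUE)

  rows <- purrr::map(seq_len(n_slices), function(i) {
    ph <- generate_lung_slice(config, seed = slice_seeds[i])
    set.seed(slice_seeds[i] %% 1000003L + i)
    radius <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
    opacity <- runif(1, config$lesion_peak_opacity_range[1],
                     config$lesion_peak_opacity_range[2])
    grade <- if (is_ggn[i]) grades_ggn[i] else 5L
    inside <- which(lung_interior(ph$lung_mask, margin = ceiling(radius)),
                    arr.ind = TRUE)
    if (nrow(inside) == 0L) stop("lung field too small for lesion placement", call. = FALSE)
    res <- NULL
    for (attempt in seq_len(20L)) {
      ctr <- inside[sample.int(nrow(inside), 1L), ]
      res <- tryCatch(
        implant_lesion(ph, center = as.numeric(ctr), radius = radius,
                       peak_opacity = opacity, grade = grade,
                       seed = slice_seeds[i] %% 999983L + attempt, config = config),
        error = function(e) NULL
      )
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop("lesion placement failed after 20 attempts", call. = FALSE)
    }
    res$slice$id <- sprintf("phantom-%03d", i)
    res$annotation$id <- sprintf("phantom-%03d-n1", i)
    list(slice = res$slice, lung_mask = ph$lung_mask, annotation = res$annotation)
  })

  out <- tibble::tibble(
    id = purrr::map_chr(rows, ~ .x$slice$id),
    slice = purrr::map(rows, "slice"),
    lung_mask = purrr::map(rows, "lung_mask"),
    annotation = purrr::map(rows, "annotation"),
    grade = purrr::map_int(rows, ~ .x$annotation$grade),
    is_ggn = purrr::map_lgl(rows, ~ .x$annotation$is_ggn)
  )
  attr(out, "slice_seeds") <- slice_seeds
  out
}

# erode the lung mask by `margin` pixels (Chebyshev) so lesions fit inside
lung_interior <- function(mask, margin) {
  if (margin <= 0) return(mask)
  out <- mask
  n <- nrow(mask); m <- ncol(mask)
  for (k in seq_len(margin)) {
    shr <- out
    shr[-1, ] <- shr[-1, ] & out[-n, ]
    shr[-n, ] <- shr[-n, ] & out[-1, ]
    shr[, -1] <- shr[, -1] & out[, -m]
    shr[, -m] <- shr[, -m] & out[, -1]
    shr[1, ] <- FALSE; shr[n, ] <- FALSE; shr[, 1] <- FALSE; shr[, m] <- FALSE
    out <- shr
  }
  out
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
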