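#' Preprocessing configuration
#'
#' Bundles the parameters of the slice-preparation chain: the common canvas
#' size every stripped slice is padded to, the side of the square nodule
#' region of interest (ROI) that is blanked from the generator input, the
#' intensity window mapped onto \[0, 1\], and how lung seed points are chosen
#' for the seed-filling segmentation.
#'
#' @param target_size canvas side in pixels (512 for full-resolution CT;
#'   smaller for desk-scale work).
#' @param roi_size ROI side in pixels (32 at full resolution); must be
#'   smaller than `target_size`.
#' @param hu_window length-2 `(low, high)` intensity window; the default
#'   (-1000, 400) is the standard lung window.
#' @param seed_points `"auto"` or a list of (row, col) seed points (1-based)
#'   for [segment_lung_seed_fill()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 512, roi_size = 32,
                              hu_window = c(-1000, 400), seed_points = "auto") {
  if (roi_size >= target_size) stop("`roi_size` must be < `target_size`", call. = FALSE)
  if (hu_window[1] >= hu_window[2]) stop("`hu_window` must satisfy low < high", call. = FALSE)
  structure(
    list(target_size = as.integer(target_size), roi_size = as.integer(roi_size),
         hu_window = as.numeric(hu_window), seed_points = seed_points),
    class = "preprocess_config"
  )
}

#' Seed-filling lung segmentation
#'
#' 4-connected flood fill: starting from an interior seed point, the fill
#' grows over every pixel whose intensity is strictly below `threshold` and
#' stops where the boundary (at or above threshold) is found. This is the
#' classic seed-filling segmentation used to separate the low-attenuation
#' lung fields from the surrounding soft tissue.
#'
#' @param slice a [ct_slice()].
#' @param seed_point length-2 (row, col), 1-based; must lie on a
#'   below-threshold pixel.
#' @param threshold intensity; pixels `< threshold` are fillable. The default
#'   -400 separates lung parenchyma (about -800) from soft tissue (about +40)
#'   on the raw scale.
#' @return Logical matrix: the filled connected region.
#' @export
#' @examples
#' s <- ct_slice(matrix(c(0, 1, 1, 0), 2, 2))
#' segment_lung_seed_fill(s, c(1, 1), threshold = 0.5)
segment_lung_seed_fill <- function(slice, seed_point, threshold = -400) {
  stopifnot(inherits(slice, "ct_slice"))
  px <- slice$pixels
  n <- nrow(px); m <- ncol(px)
  r0 <- as.integer(seed_point[1]); c0 <- as.integer(seed_point[2])
  if (r0 < 1 || r0 > n || c0 < 1 || c0 > m) {
    stop("seed point outside the grid", call. = FALSE)
  }
  if (px[r0, c0] >= threshold) {
    stop("seed point lies on a boundary (at/above-threshold) pixel", call. = FALSE)
  }
  fillable <- px < threshold
  mask <- matrix(FALSE, n, m)
  # queue-based BFS over 4-neighbours, vectorised frontier expansion
  frontier <- matrix(c(r0, c0), 1, 2)
  mask[r0, c0] <- TRUE
  while (nrow(frontier) > 0L) {
    cand <- rbind(
      cbind(frontier[, 1] - 1L, frontier[, 2]),
      cbind(frontier[, 1] + 1L, frontier[, 2]),
      cbind(frontier[, 1], frontier[, 2] - 1L),
      cbind(frontier[, 1], frontier[, 2] + 1L)
    )
    ok <- cand[, 1] >= 1L & cand[, 1] <= n & cand[, 2] >= 1L & cand[, 2] <= m
    cand <- cand[ok, , drop = FALSE]
    lin <- (cand[, 2] - 1L) * n + cand[, 1]
    keep <- fillable[lin] & !mask[lin]
    lin <- unique(lin[keep])
    if (length(lin) == 0L) break
    mask[lin] <- TRUE
    frontier <- cbind((lin - 1L) %% n + 1L, (lin - 1L) %/% n + 1L)
  }
  mask
}

#' Automatic lung seed points
#'
#' Picks one seed per lung as the intensity minima of the mid-height row,
#' one in the left and one in the right half of the body span.
#'
#' @param slice a [ct_slice()] on the raw intensity scale.
#' @param air_threshold intensities below this are treated as outside-body air.
#' @return List of two (row, col) seed points (1-based).
#' @export
auto_seed_points <- function(slice, air_threshold = -950) {
  px <- slice$pixels
  mid <- round(nrow(px) / 2)
  row <- px[mid, ]
  body <- which(row > air_threshold)
  if (length(body) < 4L) stop("no body span found on the mid-height row", call. = FALSE)
  half <- round(mean(range(body)))
  left <- body[body <= half]; right <- body[body > half]
  c_left <- left[which.min(row[left])]
  c_right <- right[which.min(row[right])]
  list(c(mid, c_left), c(mid, c_right))
}

#' Fill interior holes of a binary mask
#'
#' Dense structures (solid nodules, vessels) stop the seed fill and leave
#' holes inside the lung field; this closes them so stripping retains the
#' nodule. A hole is any `FALSE` component not 4-connected to the border.
#'
#' @param mask logical matrix.
#' @return Logical matrix with interior holes set to `TRUE`.
#' @export
fill_mask_holes <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  outside <- matrix(FALSE, n, m)
  # BFS over !mask starting from all border pixels that are FALSE
  border <- rbind(
    cbind(1L, seq_len(m)), cbind(n, seq_len(m)),
    cbind(seq_len(n), 1L), cbind(seq_len(n), m)
  )
  lin0 <- (border[, 2] - 1L) * n + border[, 1]
  lin0 <- unique(lin0[!mask[lin0]])
  outside[lin0] <- TRUE
  frontier <- lin0
  while (length(frontier) > 0L) {
    r <- (frontier - 1L) %% n + 1L
    cc <- (frontier - 1L) %/% n + 1L
    cand <- c(
      ifelse(r > 1L, frontier - 1L, NA), ifelse(r < n, frontier + 1L, NA),
      ifelse(cc > 1L, frontier - n, NA), ifelse(cc < m, frontier + n, NA)
    )
    cand <- cand[!is.na(cand)]
    cand <- unique(cand[!mask[cand] & !outside[cand]])
    if (length(cand) == 0L) break
    outside[cand] <- TRUE
    frontier <- cand
  }
  mask | (!mask & !outside)
}

#' Strip the background and pad to a common canvas
#'
#' Zeroes every non-lung pixel, crops the retained content to the mask's
#' tight bounding box, and centres it on a `target_size` x `target_size`
#' zero canvas. The crop offset is recorded in the `offset` attribute
#' (length-2, 0-based row/col shift added to original coordinates) so
#' annotation coordinates can be remapped.
#'
#' @param slice a [ct_slice()].
#' @param lung_mask logical matrix, same shape as the slice.
#' @param target_size canvas side in pixels.
#' @return A [ct_slice()] of side `target_size` with attribute `offset`.
#' @export
strip_and_pad <- function(slice, lung_mask, target_size) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!any(lung_mask)) stop("lung mask is empty", call. = FALSE)
  px <- slice$pixels
  px[!lung_mask] <- 0
  idx <- which(lung_mask, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  h <- r2 - r1 + 1L; w <- c2 - c1 + 1L
  if (h > target_size || w > target_size) {
    stop("mask bounding box larger than target_size", call. = FALSE)
  }
  canvas <- matrix(0, target_size, target_size)
  off_r <- floor((target_size - h) / 2)
  off_c <- floor((target_size - w) / 2)
  canvas[off_r + seq_len(h), off_c + seq_len(w)] <- px[r1:r2, c1:c2]
  out <- ct_slice(canvas, spacing = slice$spacing, normalized = slice$normalized,
                  id = slice$id)
  # 0-based shift: new_coord = old_coord + offset
  attr(out, "offset") <- c(off_r - (r1 - 1L), off_c - (c1 - 1L))
  out
}

#' Window-normalise intensities to \[0, 1\]
#'
#' `clip((x - low) / (high - low), 0, 1)`; sets the `normalized` flag.
#' Normalising an already-normalised slice with the window (0, 1) is the
#' identity.
#'
#' @param slice a [ct_slice()].
#' @param hu_window length-2 `(low, high)`, `low < high`.
#' @return A normalised [ct_slice()].
#' @export
normalize_intensity <- function(slice, hu_window = c(-1000, 400)) {
  stopifnot(inherits(slice, "ct_slice"))
  lo <- hu_window[1]; hi <- hu_window[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("invalid window: need low < high", call. = FALSE)
  }
  px <- pmin(pmax((slice$pixels - lo) / (hi - lo), 0), 1)
  ct_slice(px, spacing = slice$spacing, normalized = TRUE, id = slice$id)
}

#' Blank the nodule ROI into a training pair
#'
#' Erases a fixed-size square region of interest centred on the nodule from
#' the slice: the original slice is the target (ground truth), the blanked
#' copy is the generator input. The ROI box is the `roi_size` square centred
#' on the centroid, shifted (never shrunk) to fit the image bounds, so
#' nodules larger than the box are truncated.
#'
#' @param slice a normalised [ct_slice()].
#' @param annotation a [nodule_annotation()] whose centroid lies in the grid.
#' @param roi_size ROI side in pixels, < image side.
#' @return A list of class `training_pair` with fields `input_image`,
#'   `target_image` (both [ct_slice()]), `roi_mask` (logical), `roi_box`
#'   (0-based half-open), `annotation_id`.
#' @export
blank_roi <- function(slice, annotation, roi_size) {
  stopifnot(inherits(slice, "ct_slice"), inherits(annotation, "nodule_annotation"))
  if (!slice$normalized) stop("`slice` must be normalised first", call. = FALSE)
  n <- nrow(slice$pixels); m <- ncol(slice$pixels)
  roi_size <- as.integer(roi_size)
  if (roi_size >= min(n, m)) stop("`roi_size` must be smaller than the image side", call. = FALSE)
  ctr <- annotation$centroid            # 0-based
  if (ctr[1] < 0 || ctr[1] >= n || ctr[2] < 0 || ctr[2] >= m) {
    stop("annotation centroid outside the grid", call. = FALSE)
  }
  r1 <- round(ctr[1]) - floor(roi_size / 2)
  c1 <- round(ctr[2]) - floor(roi_size / 2)
  r1 <- min(max(r1, 0L), n - roi_size)   # shift, never shrink
  c1 <- min(max(c1, 0L), m - roi_size)
  box <- c(r1, c1, r1 + roi_size, c1 + roi_size)

  mask <- matrix(FALSE, n, m)
  mask[(box[1] + 1):box[3], (box[2] + 1):box[4]] <- TRUE
  blanked <- slice$pixels
  blanked[mask] <- 0
  structure(
    list(
      input_image = ct_slice(blanked, spacing = slice$spacing, normalized = TRUE,
                             id = paste0(slice$id, "-input")),
      target_image = slice,
      roi_mask = mask,
      roi_box = box,
      annotation_id = annotation$id
    ),
    class = "training_pair"
  )
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf("<training_pair '%s': %dx%d, roi [%d,%d)x[%d,%d)>\n",
              x$annotation_id, nrow(x$target_image$pixels),
              ncol(x$target_image$pixels),
              x$roi_box[1], x$roi_box[3], x$roi_box[2], x$roi_box[4]))
  invisible(x)
}

#' Phantom training pairs in one call
#'
#' Convenience pipeline for desk-scale experiments: generate `n` GGN-bearing
#' phantom slices, window-normalise them, and blank the ROI around each
#' lesion into a training pair. Phantom slices are already canvas-sized, so
#' the strip-and-pad stage is not needed here.
#'
#' @param n number of pairs.
#' @param config a [phantom_config()].
#' @param roi_size blanked-ROI side in pixels.
#' @param hu_window normalisation window.
#' @param seed integer seed.
#' @return A list of `training_pair` objects.
#' @export
phantom_training_pairs <- function(n, config = phantom_config(), roi_size = 16,
                                   hu_window = c(-1000, 400), seed = 1L) {
  ds <- make_phantom_dataset(n, ggn_fraction = 1, config = config, seed = seed)
  purrr::map2(ds$slice, ds$annotation, function(s, a) {
    blank_roi(normalize_intensity(s, hu_window), a, roi_size)
  })
}

#' Run the full preprocessing chain on a phantom dataset
#'
#' For each row of a [make_phantom_dataset()] tibble: segment the lungs by
#' seed filling (falling back to the stored phantom mask if the automatic
#' seeds fail), strip and pad to `config$target_size`, window-normalise,
#' remap the annotation, and blank the ROI into a training pair.
#'
#' @param dataset tibble from [make_phantom_dataset()].
#' @param config a [preprocess_config()].
#' @return The input tibble with an added list-column `pair` of
#'   `training_pair` objects.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  pairs <- purrr::pmap(
    list(dataset$slice, dataset$lung_mask, dataset$annotation),
    function(slice, lung_mask, ann) {
      mask <- tryCatch({
        seeds <- if (identical(config$seed_points, "auto")) {
          auto_seed_points(slice)
        } else config$seed_points
        m <- Reduce(`|`, lapply(seeds, function(sp) {
          segment_lung_seed_fill(slice, sp, threshold = -400)
        }))
        m <- fill_mask_holes(m)
        if (sum(m) < 0.5 * sum(lung_mask)) lung_mask else m
      }, error = function(e) lung_mask)
      stripped <- strip_and_pad(slice, mask, config$target_size)
      off <- attr(stripped, "offset")
      norm <- normalize_intensity(stripped, config$hu_window)
      ann2 <- nodule_annotation(
        centroid = ann$centroid + off,
        bbox = ann$bbox + c(off, off),
        grade = ann$grade, id = ann$id
      )
      blank_roi(norm, ann2, config$roi_size)
    }
  )
  dataset$pair <- pairs
  dataset
}
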