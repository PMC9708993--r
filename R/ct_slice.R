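#' CT slice container
#'
#' A `ct_slice` holds one 2-D grayscale intensity grid with its pixel spacing
#' and a flag recording whether intensities have been normalised to \[0, 1\].
#' All image-processing functions in the package consume and produce this
#' type. Pixel coordinates are (row, col), 0-based internally only where
#' stated; R-facing accessors are 1-based. Boxes are half-open
#' `(row_min, col_min, row_max, col_max)` in 0-based coordinates so that
#' `row_max - row_min` is the box height.
#'
#' @param pixels numeric matrix of intensities. Raw slices use a
#'   Hounsfield-like scale (air about -1000, lung about -800, soft tissue
#'   about +40); normalised slices lie in \[0, 1\].
#' @param spacing isotropic pixel spacing in mm.
#' @param normalized logical; `TRUE` when intensities are in \[0, 1\].
#' @param id opaque identifier string.
#'
#' @return An object of class `ct_slice`.
#' @export
#' @examples
#' s <- ct_slice(matrix(0, 8, 8))
#' dim(s$pixels)
ct_slice <- function(pixels, spacing = 1, normalized = FALSE, id = "slice") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L)) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a positive scalar (mm per pixel)", call. = FALSE)
  }
  if (isTRUE(normalized)) {
    rng <- range(pixels)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("normalized slice has intensities outside [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, spacing = spacing, normalized = isTRUE(normalized),
         id = as.character(id)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf(
    "<ct_slice '%s': %d x %d px, %.3g mm/px, %s>\n",
    x$id, nrow(x$pixels), ncol(x$pixels), x$spacing,
    if (x$normalized) "normalized [0,1]" else "raw intensity"
  ))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$pixels)

#' Nodule annotation
#'
#' Describes one lesion on a slice: centroid, tight bounding box, the
#' five-level texture grade (1 = pure ground-glass opacity through 5 = solid),
#' and the derived ground-glass flag (`is_ggn` is `TRUE` iff grade <= 2).
#'
#' @param centroid numeric length-2 (row, col), 0-based pixel coordinates.
#' @param bbox numeric length-4 half-open box
#'   `(row_min, col_min, row_max, col_max)`, 0-based.
#' @param grade integer 1..5 texture grade.
#' @param id identifier string.
#'
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(centroid, bbox, grade, id = "nodule") {
  grade <- as.integer(grade)
  if (length(grade) != 1L || is.na(grade) || grade < 1L || grade > 5L) {
    stop("`grade` must be an integer in 1..5", call. = FALSE)
  }
  bbox <- as.numeric(bbox)
  centroid <- as.numeric(centroid)
  if (length(centroid) != 2L || length(bbox) != 4L) {
    stop("`centroid` must have length 2 and `bbox` length 4", call. = FALSE)
  }
  if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4]) {
    stop("`bbox` must be non-degenerate half-open (row_min < row_max)", call. = FALSE)
  }
  if (centroid[1] < bbox[1] || centroid[1] >= bbox[3] ||
      centroid[2] < bbox[2] || centroid[2] >= bbox[4]) {
    stop("`bbox` must contain the centroid", call. = FALSE)
  }
  structure(
    list(centroid = centroid, bbox = bbox, grade = grade,
         is_ggn = grade <= 2L, id = as.character(id)),
    class = "nodule_annotation"
  )
}

#' @export
print.nodule_annotation <- function(x, ...) {
  cat(sprintf(
    "<nodule '%s': grade %d (%s), centroid (%.1f, %.1f), bbox [%g,%g)x[%g,%g)>\n",
    x$id, x$grade, if (x$is_ggn) "GGN" else "solid/part-solid",
    x$centroid[1], x$centroid[2], x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]
  ))
  invisible(x)
}

# ---- IO ---------------------------------------------------------------------

#' Read and write CT slices and annotation sidecars
#'
#' Slices are stored either as 16-bit grayscale PNG (raw intensities are
#' affinely packed into the 16-bit range; the scale and offset are written to
#' a `<file>.json` sidecar so the round trip is lossless to 16-bit
#' quantisation) or as single-slice NIfTI (lossless float, requires the
#' RNifti package). Annotations travel as a JSON sidecar
#' `{id, centroid, bbox, grade}` with 0-based coordinates.
#'
#' @param slice a [ct_slice()].
#' @param path file path; `.png` or `.nii`/`.nii.gz` decides the format.
#' @return `write_slice` returns `path` invisibly; `read_slice` returns a
#'   [ct_slice()].
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    px <- slice$pixels
    lo <- min(px); hi <- max(px)
    scale <- if (hi > lo) hi - lo else 1
    # 16-bit quantisation packed into the red (high byte) and green (low
    # byte) channels, since the PNG writer is 8-bit-per-channel
    q <- round((px - lo) / scale * 65535)
    arr <- array(0, dim = c(nrow(px), ncol(px), 3))
    arr[, , 1] <- (q %/% 256) / 255
    arr[, , 2] <- (q %% 256) / 255
    png::writePNG(arr, target = path, dpi = NULL)
    meta <- list(offset = lo, scale = scale, spacing = slice$spacing,
                 normalized = slice$normalized, id = slice$id)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI IO requires the RNifti package", call. = FALSE)
    }
    img <- RNifti::asNifti(slice$pixels, pixdim = c(slice$spacing, slice$spacing))
    RNifti::writeNifti(img, path)
    jsonlite::write_json(
      list(spacing = slice$spacing, normalized = slice$normalized, id = slice$id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  } else {
    stop("unsupported slice format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (ext == "png") {
    arr <- png::readPNG(path)
    packed <- if (length(dim(arr)) == 3L) {
      (round(arr[, , 1] * 255) * 256 + round(arr[, , 2] * 255)) / 65535
    } else arr
    offset <- meta$offset %||% 0
    scale <- meta$scale %||% 1
    px <- packed * scale + offset
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("NIfTI IO requires the RNifti package", call. = FALSE)
    }
    px <- as.matrix(RNifti::readNifti(path)[, ])
  } else {
    stop("unsupported slice format: ", ext, call. = FALSE)
  }
  ct_slice(px,
           spacing = meta$spacing %||% 1,
           normalized = isTRUE(meta$normalized),
           id = meta$id %||% basename(path))
}

#' @rdname write_slice
#' @param annotation a [nodule_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "nodule_annotation"))
  jsonlite::write_json(
    list(id = annotation$id, centroid = annotation$centroid,
         bbox = annotation$bbox, grade = annotation$grade),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_slice
#' @export
read_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodule_annotation(centroid = x$centroid, bbox = x$bbox,
                    grade = x$grade, id = x$id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
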