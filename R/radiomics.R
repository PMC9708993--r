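#' Radiomics extraction configuration
#'
#' Settings for the 93-feature extractor: the fixed bin width used to
#' discretise grey levels for the texture matrices (and for the first-order
#' entropy/uniformity), and the pixel spacing fallback. Computation is 2-D
#' (single slice). The default bin width of 25 intensity units is the
#' conventional default on a raw CT-like scale; normalised \[0, 1\] images
#' need a correspondingly smaller width (e.g. 0.05).
#'
#' @param bin_width fixed grey-level bin width, > 0.
#' @param spacing pixel spacing (mm) used for total energy when the image is
#'   given as a bare matrix.
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(bin_width = 25, spacing = 1) {
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  structure(list(bin_width = bin_width, spacing = spacing),
            class = "radiomics_config")
}

#' Extract the 93-feature radiomic signature of a masked region
#'
#' Computes the six standard feature families over the masked pixels of a
#' 2-D image: first-order statistics (18 features), grey level co-occurrence
#' matrix (GLCM, 24), grey level dependence matrix (GLDM, 14), grey level
#' run length matrix (GLRLM, 16), grey level size zone matrix (GLSZM, 16)
#' and neighbouring grey tone difference matrix (NGTDM, 5) — 93 features in
#' total, to the standard reference definitions. Texture matrices use grey
#' levels discretised with a fixed bin width; GLCM and GLRLM aggregate the
#' four 2-D directions by averaging; GLSZM zones and GLDM/NGTDM
#' neighbourhoods are 8-connected.
#'
#' @param image a [ct_slice()] or numeric matrix.
#' @param mask logical matrix of the same shape; must contain at least one
#'   `TRUE` pixel.
#' @param config a [radiomics_config()].
#' @return A tibble of class `feature_vector` with columns `family`
#'   (`first_order`, `glcm`, `gldm`, `glrlm`, `glszm`, `ngtdm`), `feature`
#'   and `value`, exactly 93 rows.
#' @export
#' @examples
#' img <- matrix(runif(64, 0, 100), 8, 8)
#' fv <- extract_features(img, matrix(TRUE, 8, 8), radiomics_config(bin_width = 10))
#' dplyr::count(fv, family)
extract_features <- function(image, mask, config = radiomics_config()) {
  spacing <- if (inherits(image, "ct_slice")) image$spacing else config$spacing
  img <- as_image_matrix(image)
  if (!identical(dim(img), dim(mask))) stop("image and mask shapes differ", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  vals <- img[mask]
  # fixed-bin-width discretisation; levels 1..Ng over the masked range
  g <- floor((vals - min(vals)) / config$bin_width) + 1L
  Ng <- max(g)
  L <- matrix(NA_integer_, nrow(img), ncol(img))
  L[mask] <- g

  fo <- features_first_order(vals, g, Ng, spacing)
  glcm <- features_glcm(L, Ng)
  gldm <- features_gldm(L, Ng)
  glrlm <- features_glrlm(L, Ng)
  glszm <- features_glszm(L, Ng)
  ngtdm <- features_ngtdm(L, Ng)

  out <- dplyr::bind_rows(
    tibble::tibble(family = "first_order", feature = names(fo), value = unname(fo)),
    tibble::tibble(family = "glcm", feature = names(glcm), value = unname(glcm)),
    tibble::tibble(family = "gldm", feature = names(gldm), value = unname(gldm)),
    tibble::tibble(family = "glrlm", feature = names(glrlm), value = unname(glrlm)),
    tibble::tibble(family = "glszm", feature = names(glszm), value = unname(glszm)),
    tibble::tibble(family = "ngtdm", feature = names(ngtdm), value = unname(ngtdm))
  )
  validate_feature_vector(out)
  class(out) <- c("feature_vector", class(out))
  out
}

#' Validate the 93-feature cardinality invariant
#'
#' Errors unless the table has exactly 93 rows with family cardinalities
#' first_order 18, glcm 24, gldm 14, glrlm 16, glszm 16, ngtdm 5.
#'
#' @param fv a feature table with `family` and `feature` columns.
#' @return `fv`, invisibly.
#' @export
validate_feature_vector <- function(fv) {
  expected <- c(first_order = 18L, glcm = 24L, gldm = 14L, glrlm = 16L,
                glszm = 16L, ngtdm = 5L)
  counts <- table(fv$family)
  if (nrow(fv) != 93L || !all(names(expected) %in% names(counts)) ||
      !all(counts[names(expected)] == expected)) {
    stop("feature vector must have exactly 93 features with the six standard family counts",
         call. = FALSE)
  }
  if (anyDuplicated(paste(fv$family, fv$feature))) {
    stop("duplicate (family, feature) keys", call. = FALSE)
  }
  invisible(fv)
}

# ---- first order (18) -------------------------------------------------------

features_first_order <- function(x, g, Ng, spacing) {
  n <- length(x)
  p <- tabulate(g, Ng) / n
  p_pos <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  mid <- x[x >= q[1] & x <= q[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(
    energy = sum(x^2),
    total_energy = spacing^2 * sum(x^2),
    entropy = -sum(p_pos * log2(p_pos)),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    mean = mu,
    median = q[3],
    interquartile_range = q[4] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    root_mean_squared = sqrt(mean(x^2)),
    skewness = skew,
    kurtosis = kurt,
    variance = m2,
    uniformity = sum(p_pos^2)
  )
}

# ---- shared helpers ---------------------------------------------------------

# the four 2-D directions (row offset, col offset)
directions_2d <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

# co-occurrence counts of level pairs at a given offset (one direction)
cooccurrence_pairs <- function(L, dr, dc) {
  n <- nrow(L); m <- ncol(L)
  r1 <- max(1L, 1L - dr):min(n, n - dr)
  c1 <- max(1L, 1L - dc):min(m, m - dc)
  a <- L[r1, c1, drop = FALSE]
  b <- L[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(a[ok], b[ok])
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# ---- GLCM (24) --------------------------------------------------------------

glcm_matrix <- function(L, Ng, dr, dc) {
  pr <- cooccurrence_pairs(L, dr, dc)
  P <- matrix(0, Ng, Ng)
  if (nrow(pr) > 0) {
    tab <- table(factor(pr[, 1], levels = 1:Ng), factor(pr[, 2], levels = 1:Ng))
    P <- matrix(as.numeric(tab), Ng, Ng)
  }
  P <- P + t(P)                      # symmetric
  if (sum(P) > 0) P / sum(P) else P
}

glcm_features_one <- function(p) {
  Ng <- nrow(p)
  i <- matrix(1:Ng, Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sx <- sqrt(sum((i - mux)^2 * p)); sy <- sqrt(sum((j - muy)^2 * p))
  # difference and sum distributions
  k_diff <- 0:(Ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * Ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  HXY <- entropy2(p)
  HX <- entropy2(px); HY <- entropy2(py)
  pxy <- outer(px, py)
  pos <- p > 0 & pxy > 0
  HXY1 <- -sum(p[pos] * log2(pxy[pos]))
  HXY2 <- entropy2(pxy)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- if (HXY2 >= HXY) sqrt(1 - exp(-2 * (HXY2 - HXY))) else 0
  corr <- if (sx * sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  mcc <- glcm_mcc(p, px, py)
  c(
    autocorrelation = sum(i * j * p),
    joint_average = mux,
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_tendency = sum((i + j - mux - muy)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = entropy2(p_diff),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(p^2),
    joint_entropy = HXY,
    imc1 = imc1,
    imc2 = imc2,
    idm = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + (i - j)^2 / Ng^2)),
    id = sum(p / (1 + abs(i - j))),
    idn = sum(p / (1 + abs(i - j) / Ng)),
    inverse_variance = sum((p / pmax((i - j)^2, 1))[i != j]),
    maximum_probability = max(p),
    sum_average = sum(k_sum * p_sum),
    sum_entropy = entropy2(p_sum),
    sum_squares = sum((i - mux)^2 * p),
    mcc = mcc
  )
}

glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  if (sum(keep) < 2L) return(1)
  ps <- p[keep, keep, drop = FALSE]
  pxs <- px[keep]; pys <- py[keep]
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  Q <- (ps / pxs) %*% t(sweep(ps, 2L, pys, `/`))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(1, ev[2])))
}

features_glcm <- function(L, Ng) {
  per_dir <- lapply(directions_2d, function(d) {
    glcm_features_one(glcm_matrix(L, Ng, d[1], d[2]))
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

# ---- GLRLM (16) -------------------------------------------------------------

# run-length counts P(level, run length) along one direction
glrlm_matrix <- function(L, Ng, dr, dc) {
  n <- nrow(L); m <- ncol(L)
  lines <- extract_lines(n, m, dr, dc)
  maxlen <- max(vapply(lines, nrow, integer(1)))
  P <- matrix(0, Ng, maxlen)
  for (ln in lines) {
    v <- L[cbind(ln[, 1], ln[, 2])]
    r <- rle(ifelse(is.na(v), -1L, v))
    keep <- r$values > 0
    if (any(keep)) {
      for (q in which(keep)) {
        P[r$values[q], r$lengths[q]] <- P[r$values[q], r$lengths[q]] + 1
      }
    }
  }
  P
}

# pixel index paths covering the grid along direction (dr, dc)
extract_lines <- function(n, m, dr, dc) {
  if (dr == 0L) {                      # horizontal
    lapply(seq_len(n), function(r) cbind(r, seq_len(m)))
  } else if (dc == 0L) {               # vertical
    lapply(seq_len(m), function(cc) cbind(seq_len(n), cc))
  } else if (dc == 1L) {               # diagonal down-right: r - c constant
    lapply(seq(1L - m, n - 1L), function(d) {
      r <- max(1L, 1L + d):min(n, m + d)
      cbind(r, r - d)
    })
  } else {                             # anti-diagonal down-left: r + c constant
    lapply(seq(2L, n + m), function(s) {
      r <- max(1L, s - m):min(n, s - 1L)
      cbind(r, s - r)
    })
  }
}

size_distribution_features <- function(P, Np, prefix_small, prefix_large,
                                       size_name, count_name) {
  Nr <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  s <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / Nr
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  gl_counts <- rowSums(P); sz_counts <- colSums(P)
  out <- c(
    sum(P / s^2) / Nr,                       # small emphasis
    sum(P * s^2) / Nr,                       # large emphasis
    sum(gl_counts^2) / Nr,                   # grey level non-uniformity
    sum(gl_counts^2) / Nr^2,                 # ... normalised
    sum(sz_counts^2) / Nr,                   # size/run non-uniformity
    sum(sz_counts^2) / Nr^2,                 # ... normalised
    Nr / Np,                                 # percentage
    sum((i - mu_i)^2 * p),                   # grey level variance
    sum((s - mu_s)^2 * p),                   # size/run variance
    entropy2(p),                             # entropy
    sum(P / i^2) / Nr,                       # low grey level emphasis
    sum(P * i^2) / Nr,                       # high grey level emphasis
    sum(P / (i^2 * s^2)) / Nr,               # small + low
    sum(P * i^2 / s^2) / Nr,                 # small + high
    sum(P * s^2 / i^2) / Nr,                 # large + low
    sum(P * i^2 * s^2) / Nr                  # large + high
  )
  names(out) <- c(
    paste0(prefix_small, "_emphasis"), paste0(prefix_large, "_emphasis"),
    "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
    paste0(count_name, "_non_uniformity"),
    paste0(count_name, "_non_uniformity_normalised"),
    paste0(size_name, "_percentage"), "grey_level_variance",
    paste0(size_name, "_variance"), paste0(size_name, "_entropy"),
    "low_grey_level_emphasis_base", "high_grey_level_emphasis_base",
    paste0(prefix_small, "_low_grey_level_emphasis"),
    paste0(prefix_small, "_high_grey_level_emphasis"),
    paste0(prefix_large, "_low_grey_level_emphasis"),
    paste0(prefix_large, "_high_grey_level_emphasis")
  )
  out
}

features_glrlm <- function(L, Ng) {
  Np <- sum(!is.na(L))
  per_dir <- lapply(directions_2d, function(d) {
    P <- glrlm_matrix(L, Ng, d[1], d[2])
    f <- size_distribution_features(P, Np, "short_run", "long_run", "run", "run_length")
    names(f)[names(f) == "low_grey_level_emphasis_base"] <- "low_grey_level_run_emphasis"
    names(f)[names(f) == "high_grey_level_emphasis_base"] <- "high_grey_level_run_emphasis"
    f
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

# ---- GLSZM (16) -------------------------------------------------------------

# zone (8-connected equal-level component) size counts P(level, size)
glszm_matrix <- function(L, Ng) {
  n <- nrow(L); m <- ncol(L)
  visited <- matrix(FALSE, n, m)
  zones <- list()
  todo <- which(!is.na(L))
  for (start in todo) {
    if (visited[start]) next
    lev <- L[start]
    comp <- integer(0)
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      r <- (frontier - 1L) %% n + 1L
      cc <- (frontier - 1L) %/% n + 1L
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        ok <- r + dr >= 1L & r + dr <= n & cc + dc >= 1L & cc + dc <= m
        if (!any(ok)) next
        cand <- (cc[ok] + dc - 1L) * n + (r[ok] + dr)
        nbr <- c(nbr, cand)
      }
      nbr <- unique(nbr)
      nbr <- nbr[!visited[nbr] & !is.na(L[nbr]) & L[nbr] == lev]
      visited[nbr] <- TRUE
      frontier <- nbr
    }
    zones[[length(zones) + 1L]] <- c(lev, length(comp))
  }
  zs <- do.call(rbind, zones)
  P <- matrix(0, Ng, max(zs[, 2]))
  for (q in seq_len(nrow(zs))) {
    P[zs[q, 1], zs[q, 2]] <- P[zs[q, 1], zs[q, 2]] + 1
  }
  P
}

features_glszm <- function(L, Ng) {
  Np <- sum(!is.na(L))
  P <- glszm_matrix(L, Ng)
  f <- size_distribution_features(P, Np, "small_area", "large_area", "zone", "size_zone")
  names(f)[names(f) == "low_grey_level_emphasis_base"] <- "low_grey_level_zone_emphasis"
  names(f)[names(f) == "high_grey_level_emphasis_base"] <- "high_grey_level_zone_emphasis"
  f
}

# ---- GLDM (14) --------------------------------------------------------------

features_gldm <- function(L, Ng, alpha = 0) {
  n <- nrow(L); m <- ncol(L)
  dep <- matrix(0L, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1L, 1L - dr):min(n, n - dr)
    c1 <- max(1L, 1L - dc):min(m, m - dc)
    a <- L[r1, c1, drop = FALSE]
    b <- L[r1 + dr, c1 + dc, drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dep[r1, c1] <- dep[r1, c1] + hit
  }
  ok <- !is.na(L)
  j <- dep[ok] + 1L                    # dependence size, centre included
  lev <- L[ok]
  Nd <- max(j)
  P <- matrix(0, Ng, Nd)
  for (q in seq_along(j)) P[lev[q], j[q]] <- P[lev[q], j[q]] + 1
  Nz <- sum(P)
  i <- matrix(seq_len(Ng), Ng, Nd)
  jj <- matrix(seq_len(Nd), Ng, Nd, byrow = TRUE)
  p <- P / Nz
  mu_i <- sum(i * p); mu_j <- sum(jj * p)
  c(
    small_dependence_emphasis = sum(P / jj^2) / Nz,
    large_dependence_emphasis = sum(P * jj^2) / Nz,
    grey_level_non_uniformity = sum(rowSums(P)^2) / Nz,
    dependence_non_uniformity = sum(colSums(P)^2) / Nz,
    dependence_non_uniformity_normalised = sum(colSums(P)^2) / Nz^2,
    grey_level_variance = sum((i - mu_i)^2 * p),
    dependence_variance = sum((jj - mu_j)^2 * p),
    dependence_entropy = entropy2(p),
    low_grey_level_emphasis = sum(P / i^2) / Nz,
    high_grey_level_emphasis = sum(P * i^2) / Nz,
    small_dependence_low_grey_level_emphasis = sum(P / (i^2 * jj^2)) / Nz,
    small_dependence_high_grey_level_emphasis = sum(P * i^2 / jj^2) / Nz,
    large_dependence_low_grey_level_emphasis = sum(P * jj^2 / i^2) / Nz,
    large_dependence_high_grey_level_emphasis = sum(P * i^2 * jj^2) / Nz
  )
}

# ---- NGTDM (5) --------------------------------------------------------------

features_ngtdm <- function(L, Ng) {
  n <- nrow(L); m <- ncol(L)
  nb_sum <- matrix(0, n, m)
  nb_cnt <- matrix(0L, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r1 <- max(1L, 1L - dr):min(n, n - dr)
    c1 <- max(1L, 1L - dc):min(m, m - dc)
    b <- L[r1 + dr, c1 + dc, drop = FALSE]
    valid <- !is.na(b)
    bv <- b; bv[!valid] <- 0L
    nb_sum[r1, c1] <- nb_sum[r1, c1] + bv
    nb_cnt[r1, c1] <- nb_cnt[r1, c1] + valid
  }
  ok <- !is.na(L) & nb_cnt > 0
  Nvp <- sum(ok)
  lev <- L[ok]
  abar <- nb_sum[ok] / nb_cnt[ok]
  s <- vapply(seq_len(Ng), function(i) sum(abs(lev[lev == i] - abar[lev == i])),
              numeric(1))
  ni <- tabulate(lev, Ng)
  p <- ni / Nvp
  present <- p > 0
  Ngp <- sum(present)
  iv <- seq_len(Ng)

  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (Ngp > 1) {
    (sum(outer(p, p) * outer(iv, iv, `-`)^2) / (Ngp * (Ngp - 1))) * (sum(s) / Nvp)
  } else 0
  ip <- iv * p
  busy_den <- sum(abs(outer(ip[present], ip[present], `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  pi_ <- p[present]; si <- s[present]; ii <- iv[present]
  cx <- outer(pi_ * si, pi_ * si, `+`)        # p_i s_i + p_j s_j
  psum <- outer(pi_, pi_, `+`)
  complexity <- sum(abs(outer(ii, ii, `-`)) * cx / psum) / Nvp
  strength_den <- sum(s)
  strength <- if (strength_den > 0) {
    sum(psum * outer(ii, ii, `-`)^2) / strength_den
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
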