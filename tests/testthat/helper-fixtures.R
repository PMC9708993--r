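# Shared fixtures: all generated in code, nothing stored on disk.

tiny_phantom_config <- function(size = 64) {
  phantom_config(image_size = size)
}

# a small GAN configuration sized for fast unit tests
tiny_gan_config <- function(image_size = 32, steps = 10, seed = 1L) {
  gan_config(image_size = image_size, roi_size = 8, n_res_blocks = 1,
             base_channels = 4, learning_rate = 1e-3, batch_size = 2,
             steps = steps, seed = seed)
}

# brute-force 4-connected component of `grid < threshold` containing `seed`
# (independent oracle for the seed-filling segmentation)
bfs_component <- function(grid, seed, threshold) {
  n <- nrow(grid); m <- ncol(grid)
  fill <- grid < threshold
  mask <- matrix(FALSE, n, m)
  if (!fill[seed[1], seed[2]]) return(mask)
  queue <- list(seed)
  mask[seed[1], seed[2]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= n && q[2] >= 1 && q[2] <= m &&
          fill[q[1], q[2]] && !mask[q[1], q[2]]) {
        mask[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  mask
}

# O(n^2) concordant-pair AUC oracle (ties count 1/2)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# exact two-sample KS p-value by enumeration over all assignments of the
# pooled sample to the two groups (requires all pooled values distinct)
ks_exact_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  ks_D <- function(x, y) {
    g <- sort(unique(c(x, y)))
    Fx <- vapply(g, function(v) mean(x <= v), numeric(1))
    Fy <- vapply(g, function(v) mean(y <= v), numeric(1))
    max(abs(Fx - Fy))
  }
  d_obs <- ks_D(a, b)
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2, function(ix) ks_D(pooled[ix], pooled[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# a deterministic set of VTT records reproducing published study counts:
# 51 synthetic (8 confidently real, 11 leaning real, 20 leaning fake,
# 12 confidently fake) and 49 real cases
vtt_reference_records <- function() {
  synth <- rep(c("confidently real", "leaning real", "leaning fake",
                 "confidently fake"), c(8, 11, 20, 12))
  real <- rep(c("confidently real", "leaning real", "leaning fake",
                "confidently fake"), c(20, 12, 10, 7))
  tibble::tibble(
    case_id = paste0("case", seq_len(51 + 49)),
    truth = rep(c("synthetic", "real"), c(51, 49)),
    rating = c(synth, real),
    reader_id = "reader1"
  )
}
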