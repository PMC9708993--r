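# Minimal convolutional-network engine.
#
# Feature maps are 4-D arrays laid out (H, W, N, C) — channel-last, so that
# a per-channel matrix view is a plain `dim<-` with no transposition.
# Convolutions are evaluated as one BLAS matrix product per layer via
# im2col; the full gather index table (all samples, all channels) is cached
# per layer and input shape, so forward is a single vector gather plus one
# GEMM. Every layer is an environment holding parameters, gradients and
# Adam state with forward()/backward() closures. All randomness flows
# through the caller's seed and every operation is deterministic, so a
# whole training run is a pure function of (data, config, seed).

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list(); e$grads <- list(); e$adam_m <- list(); e$adam_v <- list()
  e
}

layer_init_adam <- function(layer) {
  layer$adam_m <- lapply(layer$params, function(p) array(0, dim = dim(p) %||% length(p)))
  layer$adam_v <- layer$adam_m
  layer$adam_t <- 0L
  invisible(layer)
}

layer_zero_grads <- function(layer) {
  layer$grads <- lapply(layer$params, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(layer)
}

layer_adam_step <- function(layer, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (length(layer$params) == 0L) return(invisible(layer))
  layer$adam_t <- layer$adam_t + 1L
  t <- layer$adam_t
  for (nm in names(layer$params)) {
    g <- layer$grads[[nm]]
    layer$adam_m[[nm]] <- beta1 * layer$adam_m[[nm]] + (1 - beta1) * g
    layer$adam_v[[nm]] <- beta2 * layer$adam_v[[nm]] + (1 - beta2) * g^2
    mhat <- layer$adam_m[[nm]] / (1 - beta1^t)
    vhat <- layer$adam_v[[nm]] / (1 - beta2^t)
    layer$params[[nm]] <- layer$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(layer)
}

# ---- conv2d (3x3, pad 1, stride 1 or 2) -------------------------------------

layer_conv <- function(in_ch, out_ch, stride = 1L, gain = sqrt(2)) {
  l <- new_layer("conv")
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$stride <- as.integer(stride)
  fan_in <- 9 * in_ch
  l$params$W <- array(rnorm(9 * in_ch * out_ch, 0, gain / sqrt(fan_in)),
                      dim = c(9 * in_ch, out_ch))
  l$params$b <- array(0, dim = out_ch)
  layer_init_adam(l); layer_zero_grads(l)
  l$idx_cache <- list()

  # full im2col gather index for padded input (Hp, Wp, N, C):
  # row = (sample - 1) * npos + pos, col = (channel - 1) * 9 + offset
  l$get_idx <- function(H, W, N, C) {
    key <- paste(H, W, N, C, sep = "x")
    hit <- l$idx_cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- l$stride
    Hp <- H + 2L; Wp <- W + 2L
    Ho <- (Hp - 3L) %/% s + 1L; Wo <- (Wp - 3L) %/% s + 1L
    r0 <- (seq_len(Ho) - 1L) * s + 1L
    c0 <- (seq_len(Wo) - 1L) * s + 1L
    pos_r <- rep(r0, times = Wo)             # column-major over (Ho, Wo)
    pos_c <- rep(c0, each = Ho)
    off_r <- rep(0:2, times = 3)             # column-major over the 3x3 kernel
    off_c <- rep(0:2, each = 3)
    base <- outer(pos_r, off_r, `+`) + (outer(pos_c, off_c, `+`) - 1L) * Hp
    npos <- Ho * Wo
    base_n <- base[rep.int(seq_len(npos), N), , drop = FALSE] +
      rep((seq_len(N) - 1L) * (Hp * Wp), each = npos)
    idx <- matrix(0L, nrow = npos * N, ncol = 9L * C)
    for (ch in seq_len(C)) {
      idx[, (ch - 1L) * 9L + 1:9] <- base_n + (ch - 1L) * (Hp * Wp * N)
    }
    out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
    l$idx_cache[[key]] <- out
    out
  }

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
    g <- l$get_idx(H, W, N, C)
    xp <- array(0, dim = c(g$Hp, g$Wp, N, C))
    xp[2:(H + 1L), 2:(W + 1L), , ] <- x
    Xcol <- xp[g$idx]
    dim(Xcol) <- dim(g$idx)
    Y <- Xcol %*% l$params$W
    Y <- Y + rep(l$params$b, each = nrow(Y))
    l$cache <- list(Xcol = Xcol, in_dim = d, g = g)
    dim(Y) <- c(g$Ho, g$Wo, N, l$out_ch)
    Y
  }

  l$backward <- function(dout) {
    cache <- l$cache
    d <- cache$in_dim; H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
    g <- cache$g
    dY <- dout
    dim(dY) <- c(g$Ho * g$Wo * N, l$out_ch)
    l$grads$W <- l$grads$W + crossprod(cache$Xcol, dY)
    l$grads$b <- l$grads$b + colSums(dY)
    if (l$stride == 1L) {
      # transposed convolution: dx = dY (*) flipped(W), one gather + one GEMM
      O <- l$out_ch
      gy <- l$get_idx(H, W, N, O)
      dYp <- array(0, dim = c(gy$Hp, gy$Wp, N, O))
      dYp[2:(H + 1L), 2:(W + 1L), , ] <- dY
      Ycol <- dYp[gy$idx]
      dim(Ycol) <- dim(gy$idx)
      W4 <- l$params$W
      dim(W4) <- c(9L, C, O)
      Wt <- aperm(W4[9:1, , , drop = FALSE], c(1, 3, 2))
      dim(Wt) <- c(9L * O, C)
      dx <- Ycol %*% Wt
      dim(dx) <- c(H, W, N, C)
      return(dx)
    }
    dXcol <- dY %*% t(l$params$W)
    dxp <- numeric(g$Hp * g$Wp * N * C)
    idx <- g$idx
    for (k in seq_len(ncol(idx))) {
      ind <- idx[, k]
      dxp[ind] <- dxp[ind] + dXcol[, k]
    }
    dim(dxp) <- c(g$Hp, g$Wp, N, C)
    dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
  }
  l
}

# ---- batch normalisation (per channel over H, W, N) -------------------------

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm")
  l$params$gamma <- array(1, dim = ch)
  l$params$beta <- array(0, dim = ch)
  l$running_mean <- array(0, dim = ch)
  l$running_var <- array(1, dim = ch)
  l$momentum <- momentum; l$eps <- eps
  layer_init_adam(l); layer_zero_grads(l)

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[4]; m <- d[1] * d[2] * d[3]
    xm <- x; dim(xm) <- c(m, C)
    if (train) {
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = m)
      v <- colMeans(xc * xc)
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
    } else {
      mu <- l$running_mean; v <- l$running_var
      xc <- xm - rep(mu, each = m)
    }
    inv_std <- 1 / sqrt(v + l$eps)
    xhat <- xc * rep(inv_std, each = m)
    y <- xhat * rep(l$params$gamma, each = m) + rep(l$params$beta, each = m)
    l$cache <- list(xhat = xhat, inv_std = inv_std, d = d, m = m, train = train)
    dim(y) <- d
    y
  }

  l$backward <- function(dout) {
    cache <- l$cache; d <- cache$d; C <- d[4]; m <- cache$m
    dy <- dout; dim(dy) <- c(m, C)
    l$grads$gamma <- l$grads$gamma + colSums(dy * cache$xhat)
    l$grads$beta <- l$grads$beta + colSums(dy)
    dxhat <- dy * rep(l$params$gamma, each = m)
    if (cache$train) {
      t1 <- dxhat - rep(colMeans(dxhat), each = m)
      t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
      dxm <- (t1 - t2) * rep(cache$inv_std, each = m)
    } else {
      dxm <- dxhat * rep(cache$inv_std, each = m)
    }
    dim(dxm) <- d
    dxm
  }
  l
}

# ---- activations ------------------------------------------------------------

layer_prelu <- function(ch, init = 0.25) {
  l <- new_layer("prelu")
  l$params$a <- array(init, dim = ch)
  layer_init_adam(l); layer_zero_grads(l)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); m <- d[1] * d[2] * d[3]
    pos <- x > 0
    neg <- x * !pos
    a_full <- rep(l$params$a, each = m)
    y <- x * pos + a_full * neg
    dim(y) <- d
    l$cache <- list(pos = pos, neg = neg, a_full = a_full, d = d, m = m)
    y
  }
  l$backward <- function(dout) {
    cache <- l$cache
    da <- dout * cache$neg
    dim(da) <- c(cache$m, cache$d[4])
    l$grads$a <- l$grads$a + colSums(da)
    dx <- dout * cache$pos + dout * cache$a_full * !cache$pos
    dim(dx) <- cache$d
    dx
  }
  l
}

layer_leaky <- function(slope = 0.2) {
  l <- new_layer("leaky")
  l$slope <- slope
  l$forward <- function(x, train = TRUE) {
    mult <- slope + (1 - slope) * (x > 0)
    l$cache <- mult
    x * mult
  }
  l$backward <- function(dout) dout * l$cache
  l
}

layer_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$forward <- function(x, train = TRUE) {
    y <- 1 / (1 + exp(-x))
    l$cache <- y
    y
  }
  l$backward <- function(dout) dout * l$cache * (1 - l$cache)
  l
}

# ---- dense over pooled features ---------------------------------------------

layer_dense <- function(in_f, out_f) {
  l <- new_layer("dense")
  l$params$W <- array(rnorm(in_f * out_f, 0, 1 / sqrt(in_f)), dim = c(in_f, out_f))
  l$params$b <- array(0, dim = out_f)
  layer_init_adam(l); layer_zero_grads(l)
  l$forward <- function(x, train = TRUE) {   # x: (features, N)
    l$cache <- x
    crossprod(l$params$W, x) + as.vector(l$params$b)
  }
  l$backward <- function(dout) {             # dout: (out_f, N)
    l$grads$W <- l$grads$W + l$cache %*% t(dout)
    l$grads$b <- l$grads$b + rowSums(dout)
    l$params$W %*% dout
  }
  l
}

layer_global_pool <- function() {
  l <- new_layer("gpool")
  l$forward <- function(x, train = TRUE) {   # (H, W, N, C) -> (C, N)
    d <- dim(x)
    l$cache <- d
    xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
    m <- colMeans(xm)                        # ordered N fastest, then C
    dim(m) <- c(d[3], d[4])
    t(m)
  }
  l$backward <- function(dout) {             # (C, N) -> (H, W, N, C)
    d <- l$cache
    v <- rep(as.vector(t(dout)), each = d[1] * d[2]) / (d[1] * d[2])
    dim(v) <- d
    v
  }
  l
}

# ---- parameter (de)serialisation --------------------------------------------

layers_get_params <- function(layers) {
  lapply(layers, function(l) {
    list(params = l$params, running_mean = l$running_mean,
         running_var = l$running_var)
  })
}

layers_set_params <- function(layers, state) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- state[[i]]$params
    if (!is.null(state[[i]]$running_mean)) {
      layers[[i]]$running_mean <- state[[i]]$running_mean
      layers[[i]]$running_var <- state[[i]]$running_var
    }
  }
  invisible(layers)
}

net_zero_grads <- function(net) {
  for (l in net$layers) layer_zero_grads(l)
  invisible(net)
}

net_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999) {
  for (l in net$layers) layer_adam_step(l, lr, beta1, beta2)
  invisible(net)
}
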