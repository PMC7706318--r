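# Minimal convolutional-network layers on base R + BLAS.
#
# Feature tensors are channels-first arrays of dim (C, H, W, N): channels,
# rows, columns, batch. Channels-first makes 1x1 convolutions, batch-norm
# statistics and the softmax plain matrix views (matrix(x, C)) with no
# transposition, which keeps the per-batch cost dominated by the GEMMs.
# Each layer is an environment with $forward(x, train), $backward(dy), a
# $param_names vector, and for every parameter `P` a gradient `gP` and a
# momentum buffer `vP`. Convolution is im2col + one GEMM per layer and
# batch; the gather-index matrix is cached per input shape.

xavier_uniform <- function(fan_in, fan_out, n) {
  a <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -a, a)
}

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$param_names <- character(0)
  e
}

layer_zero_grads <- function(l) {
  for (p in l$param_names) l[[paste0("g", p)]] <- l[[paste0("g", p)]] * 0
  invisible(NULL)
}

# ---- convolution ------------------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 0L, bias = TRUE,
                    input_grad = TRUE) {
  l <- new_layer("conv")
  l$input_grad <- input_grad
  l$cin <- as.integer(cin); l$cout <- as.integer(cout)
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  # weight rows: output channel; columns ordered (c, ky, kx) to match im2col
  l$W <- matrix(xavier_uniform(k * k * cin, k * k * cout, cout * k * k * cin),
                nrow = cout)
  l$gW <- l$W * 0; l$vW <- l$W * 0
  l$param_names <- "W"
  if (bias) {
    l$b <- numeric(cout); l$gb <- numeric(cout); l$vb <- numeric(cout)
    l$param_names <- c("W", "b")
  }
  l$idx_cache <- list()

  # gather indices into an (C, Hp, Wp) volume: column per output cell,
  # rows ordered channel-fastest, then kernel row, then kernel column
  conv_idx <- function(Hp, Wp, C, k, s) {
    key <- paste(Hp, Wp, C, k, s, sep = "x")
    got <- l$idx_cache[[key]]
    if (!is.null(got)) return(got)
    Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
    off <- as.vector(outer(seq_len(C), (seq_len(k) - 1L) * C, "+"))
    off <- as.vector(outer(off, (seq_len(k) - 1L) * C * Hp, "+"))
    start <- as.vector(outer((seq_len(Ho) - 1L) * s * C,
                             (seq_len(Wo) - 1L) * s * C * Hp, "+"))
    idx <- outer(off, start, "+")
    out <- list(idx = idx, Ho = Ho, Wo = Wo)
    l$idx_cache[[key]] <- out
    out
  }

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1L]; H <- d[2L]; W_ <- d[3L]; N <- d[4L]
    if (C != l$cin) stop(sprintf("conv expected %d channels, got %d", l$cin, C))
    if (l$k == 1L && l$stride == 1L && l$pad == 0L) {
      xm <- matrix(x, nrow = C)
      y <- l$W %*% xm
      if (!is.null(l$b)) y <- y + l$b
      l$cache <- list(xm = xm, dims = d, mode = "1x1")
      dim(y) <- c(l$cout, H, W_, N)
      return(y)
    }
    p <- l$pad
    if (p > 0L) {
      xp <- array(0, c(C, H + 2L * p, W_ + 2L * p, N))
      xp[, p + seq_len(H), p + seq_len(W_), ] <- x
    } else xp <- x
    Hp <- H + 2L * p; Wp <- W_ + 2L * p
    ci <- conv_idx(Hp, Wp, C, l$k, l$stride)
    bkey <- paste(Hp, Wp, C, N, sep = "x")
    if (is.null(l$idx_cache[[bkey]])) {
      L1 <- C * Hp * Wp
      ncell <- length(ci$idx)
      l$idx_cache[[bkey]] <- rep(as.vector(ci$idx), times = N) +
        rep((seq_len(N) - 1L) * L1, each = ncell)
    }
    cols <- matrix(xp[l$idx_cache[[bkey]]], nrow = l$k * l$k * C)
    y <- l$W %*% cols
    if (!is.null(l$b)) y <- y + l$b
    l$cache <- list(cols = cols, dims = d, Hp = Hp, Wp = Wp,
                    Ho = ci$Ho, Wo = ci$Wo, mode = "im2col")
    dim(y) <- c(l$cout, ci$Ho, ci$Wo, N)
    y
  }

  l$backward <- function(dy) {
    ca <- l$cache
    d <- ca$dims; C <- d[1L]; H <- d[2L]; W_ <- d[3L]; N <- d[4L]
    dym <- matrix(dy, nrow = l$cout)
    if (ca$mode == "1x1") {
      l$gW <- l$gW + tcrossprod(dym, ca$xm)
      if (!is.null(l$b)) l$gb <- l$gb + rowSums(dym)
      dxm <- crossprod(l$W, dym)
      dim(dxm) <- d
      return(dxm)
    }
    Ho <- ca$Ho; Wo <- ca$Wo
    l$gW <- l$gW + tcrossprod(dym, ca$cols)
    if (!is.null(l$b)) l$gb <- l$gb + rowSums(dym)
    if (!l$input_grad) return(NULL)              # first layer: dX unused
    dcols <- crossprod(l$W, dym)                 # (k*k*C) x (Ho*Wo*N)
    k <- l$k; s <- l$stride; p <- l$pad
    dxp <- array(0, c(C, ca$Hp, ca$Wp, N))
    for (kx in seq_len(k)) {
      cc <- (seq_len(Wo) - 1L) * s + kx
      for (ky in seq_len(k)) {
        rr <- (seq_len(Ho) - 1L) * s + ky
        rows <- ((kx - 1L) * k + (ky - 1L)) * C + seq_len(C)
        blk <- dcols[rows, , drop = FALSE]
        dim(blk) <- c(C, Ho, Wo, N)
        dxp[, rr, cc, ] <- dxp[, rr, cc, ] + blk
      }
    }
    if (p > 0L) dxp[, p + seq_len(H), p + seq_len(W_), , drop = FALSE] else dxp
  }
  l
}

# ---- batch normalization ----------------------------------------------------

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("bn")
  l$c <- as.integer(c); l$eps <- eps; l$momentum <- momentum
  l$gamma <- rep(1, c); l$beta <- numeric(c)
  l$ggamma <- numeric(c); l$gbeta <- numeric(c)
  l$vgamma <- numeric(c); l$vbeta <- numeric(c)
  l$param_names <- c("gamma", "beta")
  l$run_mean <- numeric(c); l$run_var <- rep(1, c)

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1L]
    xm <- matrix(x, nrow = C)
    if (train) {
      m <- rowMeans(xm)
      v <- pmax(rowMeans(xm * xm) - m * m, 0)
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * m
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    } else {
      m <- l$run_mean; v <- l$run_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- (xm - m) * invstd           # length-C vectors recycle down rows
    y <- xhat * l$gamma + l$beta
    if (train) l$cache <- list(xhat = xhat, invstd = invstd, dims = d)
    dim(y) <- d
    y
  }

  l$backward <- function(dy) {
    ca <- l$cache
    d <- ca$dims; C <- d[1L]
    Nn <- length(dy) / C
    dym <- matrix(dy, nrow = C)
    l$ggamma <- l$ggamma + rowSums(dym * ca$xhat)
    l$gbeta <- l$gbeta + rowSums(dym)
    dxhat <- dym * l$gamma
    s1 <- rowSums(dxhat) / Nn
    s2 <- rowSums(dxhat * ca$xhat) / Nn
    dx <- (dxhat - s1 - ca$xhat * s2) * ca$invstd
    dim(dx) <- d
    dx
  }
  l
}

# ---- activation -------------------------------------------------------------

nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, train = TRUE) {
    l$mask <- x > 0
    x * l$mask
  }
  l$backward <- function(dy) dy * l$mask
  l
}

# ---- bilinear x2 upsampling -------------------------------------------------

# Half-pixel-aligned bilinear interpolation matrix mapping n -> 2n samples.
upsample2_matrix <- function(n) {
  src <- (seq_len(2L * n) - 0.5) / 2 - 0.5        # 0-based source positions
  src <- pmin(pmax(src, 0), n - 1)
  lo <- floor(src)
  w <- src - lo
  hi <- pmin(lo + 1, n - 1)
  R <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    R[i, lo[i] + 1L] <- R[i, lo[i] + 1L] + (1 - w[i])
    R[i, hi[i] + 1L] <- R[i, hi[i] + 1L] + w[i]
  }
  R
}

nn_upsample2 <- function() {
  l <- new_layer("upsample2")
  l$Rcache <- list()
  getR <- function(n) {
    key <- as.character(n)
    if (is.null(l$Rcache[[key]])) l$Rcache[[key]] <- upsample2_matrix(n)
    l$Rcache[[key]]
  }
  # apply interpolation matrices over dims 2 (rows) and 3 (cols)
  apply_hw <- function(x, Rh, Rw) {
    d <- dim(x)
    a <- aperm(x, c(2L, 1L, 3L, 4L))                       # (H, C, W, N)
    a <- array(Rh %*% matrix(a, d[2L]), c(nrow(Rh), d[1L], d[3L], d[4L]))
    a <- aperm(a, c(4L, 2L, 1L, 3L))                       # (N, C, H2, W)
    da <- dim(a)
    a <- matrix(a, da[1L] * da[2L] * da[3L])               # rows: (N,C,H2)
    a <- tcrossprod(a, Rw)                                 # cols -> W2
    a <- array(a, c(da[1L], da[2L], da[3L], nrow(Rw)))
    aperm(a, c(2L, 3L, 4L, 1L))                            # (C, H2, W2, N)
  }
  l$forward <- function(x, train = TRUE) {
    l$dims <- dim(x)
    apply_hw(x, getR(dim(x)[2L]), getR(dim(x)[3L]))
  }
  l$backward <- function(dy) {
    d <- l$dims
    apply_hw(dy, t(getR(d[2L])), t(getR(d[3L])))
  }
  l
}

# ---- unpadded average pooling, stride 1 -------------------------------------

nn_avgpool <- function(k = 4L) {
  l <- new_layer("avgpool")
  l$k <- as.integer(k)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (d[2L] < l$k || d[3L] < l$k)
      stop(sprintf("average pooling needs spatial dims >= %d", l$k))
    Ho <- d[2L] - l$k + 1L; Wo <- d[3L] - l$k + 1L
    acc <- array(0, c(d[1L], Ho, Wo, d[4L]))
    for (ky in seq_len(l$k)) for (kx in seq_len(l$k))
      acc <- acc + x[, ky:(ky + Ho - 1L), kx:(kx + Wo - 1L), , drop = FALSE]
    l$dims <- d
    acc / (l$k * l$k)
  }
  l$backward <- function(dy) {
    d <- l$dims
    Ho <- d[2L] - l$k + 1L; Wo <- d[3L] - l$k + 1L
    dx <- array(0, d)
    g <- dy / (l$k * l$k)
    for (ky in seq_len(l$k)) for (kx in seq_len(l$k))
      dx[, ky:(ky + Ho - 1L), kx:(kx + Wo - 1L), ] <-
        dx[, ky:(ky + Ho - 1L), kx:(kx + Wo - 1L), ] + g
    dx
  }
  l
}

# ---- softmax over the channel dimension -------------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits); C <- d[1L]
  lm <- matrix(logits, nrow = C)
  mx <- lm[1L, ]
  for (i in seq_len(C - 1L) + 1L) mx <- pmax(mx, lm[i, ])
  e <- exp(lm - rep(mx, each = C))
  p <- e / rep(colSums(e), each = C)
  dim(p) <- d
  p
}

# Fused softmax + cross-entropy on a (C, H, W, N) logit tensor against
# integer class targets (H, W, N) in 0..C-1. Returns loss and dlogits.
softmax_ce <- function(logits, targets) {
  d <- dim(logits); C <- d[1L]
  M <- d[2L] * d[3L] * d[4L]
  p <- matrix(softmax_channels(logits), nrow = C)
  sel <- cbind(as.integer(targets) + 1L, seq_len(M))
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  dp <- p
  dp[sel] <- dp[sel] - 1
  dp <- dp / M
  dim(dp) <- d
  list(loss = loss, dlogits = dp, probs = array(p, d))
}

# ---- SGD with momentum ------------------------------------------------------

sgd_step <- function(layers, lr, momentum = 0.9, weight_decay = 0) {
  for (l in layers) {
    for (p in l$param_names) {
      g <- l[[paste0("g", p)]]
      if (weight_decay > 0 && p == "W") g <- g + weight_decay * l[[p]]
      v <- momentum * l[[paste0("v", p)]] - lr * g
      l[[paste0("v", p)]] <- v
      l[[p]] <- l[[p]] + v
    }
  }
  invisible(NULL)
}

zero_grads <- function(layers) {
  for (l in layers) layer_zero_grads(l)
  invisible(NULL)
}

# Flatten all parameters of a layer list into a named list of arrays (for
# checkpointing) and restore them.
collect_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(l$param_names,
                if (l$kind == "bn") c("run_mean", "run_var"))) {
      out[[sprintf("layer%03d.%s", i, p)]] <- l[[p]]
    }
  }
  out
}

restore_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(l$param_names,
                if (l$kind == "bn") c("run_mean", "run_var"))) {
      key <- sprintf("layer%03d.%s", i, p)
      if (is.null(params[[key]])) stop("checkpoint is missing ", key)
      stored <- params[[key]]
      if (is.matrix(l[[p]])) stored <- matrix(stored, nrow(l[[p]]), ncol(l[[p]]))
      l[[p]] <- stored
    }
  }
  invisible(NULL)
}
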