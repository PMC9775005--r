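# Minimal feed-forward CNN engine used by the adaptation models.
#
# Data layout: a batch is a D x N matrix, one image per column, with the
# feature vector ordered (row fastest, then column, then channel) — i.e. the
# column-major flattening of an H x W x C array. Convolutions are realized
# as im2col matrix products; 3x3 kernels, stride 1, zero padding 1, so
# spatial size is preserved and 2x2 max pooling halves it.

# --- geometry -------------------------------------------------------------

# Precomputed index maps for one conv layer over an H x W x C input.
.conv_geom <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  h <- rep(seq_len(H), times = W * C)
  w <- rep(rep(seq_len(W), each = H), times = C)
  cc <- rep(seq_len(C), each = H * W)
  pad_idx <- (cc - 1L) * Hp * Wp + w * Hp + h + 1L

  dh <- rep(0:2, times = 3L * C)
  dw <- rep(rep(0:2, each = 3L), times = C)
  ci <- rep(seq_len(C), each = 9L)
  oh <- rep(seq_len(H), times = W)
  ow <- rep(seq_len(W), each = H)
  # (ow + dw - 1) * Hp + (oh + dh) + (ci - 1) * Hp * Wp, separable in
  # patch-element and output-position parts.
  col_idx <- outer((ci - 1L) * Hp * Wp + dw * Hp + dh,
                   (ow - 1L) * Hp + oh, `+`)
  list(H = H, W = W, C = C, Hp = Hp, Wp = Wp,
       P = 9L * C, POS = H * W,
       pad_idx = pad_idx, col_vec = as.vector(col_idx))
}

.he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}
# --- layer constructors ---------------------------------------------------

layer_conv <- function(H, W, C, c_out, stage, weights = NULL) {
  g <- .conv_geom(H, W, C)
  Wm <- if (is.null(weights)) .he_init(c_out, g$P) else weights
  stopifnot(nrow(Wm) == c_out, ncol(Wm) == g$P)
  list(type = "conv", stage = stage, geom = g, c_out = as.integer(c_out),
       in_shape = c(H, W, C), out_shape = c(H, W, c_out),
       params = list(W = Wm, b = numeric(c_out)))
}

# 2x2 pooling. op "max" routes gradients to the winning quadrant; op "avg"
# is average pooling with a fixed gain of 2, which keeps the activation
# scale of sparse rectified feature maps roughly constant through depth
# (plain averaging quarters their variance per stage).
layer_pool <- function(H, W, C, stage, op = c("max", "avg")) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  list(type = "pool", stage = stage, op = match.arg(op),
       in_shape = c(H, W, C),
       out_shape = c(H %/% 2L, W %/% 2L, C), params = list())
}

layer_relu <- function(shape, stage, hook = FALSE) {
  list(type = "relu", stage = stage, in_shape = shape, out_shape = shape,
       hook = hook, params = list())
}

layer_fc <- function(d_in, d_out, stage, hook = FALSE) {
  list(type = "fc", stage = stage, in_shape = d_in, out_shape = d_out,
       hook = hook,
       params = list(W = .he_init(d_out, d_in), b = numeric(d_out)))
}

layer_residual <- function(H, W, C, stage) {
  g <- .conv_geom(H, W, C)
  list(type = "residual", stage = stage, geom = g, c_out = as.integer(C),
       in_shape = c(H, W, C), out_shape = c(H, W, C),
       params = list(Wa = .he_init(C, g$P), ba = numeric(C),
                     Wb = .he_init(C, g$P), bb = numeric(C)))
}

# --- primitive forward/backward ------------------------------------------

.conv_fwd <- function(X, Wm, b, g, c_out) {
  N <- ncol(X)
  Xp <- matrix(0, g$Hp * g$Wp * g$C, N)
  Xp[g$pad_idx, ] <- X
  cols <- Xp[g$col_vec, , drop = FALSE]
  dim(cols) <- c(g$P, g$POS * N)
  Y <- Wm %*% cols + b
  Y <- aperm(array(Y, c(c_out, g$POS, N)), c(2, 1, 3))
  dim(Y) <- c(g$POS * c_out, N)
  list(out = Y, cols = cols, N = N)
}

.conv_bwd <- function(dOut, Wm, cols, g, c_out, N, need_dx = TRUE) {
  dY <- aperm(array(dOut, c(g$POS, c_out, N)), c(2, 1, 3))
  dim(dY) <- c(c_out, g$POS * N)
  dW <- tcrossprod(dY, cols)
  db <- rowSums(dY)
  dX <- NULL
  if (need_dx) {
    dcols <- crossprod(Wm, dY)
    dim(dcols) <- c(g$P * g$POS, N)
    acc <- rowsum(dcols, group = g$col_vec)
    dXp <- matrix(0, g$Hp * g$Wp * g$C, N)
    dXp[as.integer(rownames(acc)), ] <- acc
    dX <- dXp[g$pad_idx, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

layer_forward <- function(layer, X) {
  switch(layer$type,
    conv = {
      r <- .conv_fwd(X, layer$params$W, layer$params$b, layer$geom, layer$c_out)
      list(out = r$out, cache = list(cols = r$cols, N = r$N))
    },
    pool = {
      s <- layer$in_shape; H <- s[1]; W <- s[2]; C <- s[3]; N <- ncol(X)
      A <- array(X, c(H, W, C * N))
      ro <- seq(1L, H, 2L); co <- seq(1L, W, 2L)
      if (identical(layer$op, "avg")) {
        Y <- (A[ro, co, , drop = FALSE] + A[ro + 1L, co, , drop = FALSE] +
              A[ro, co + 1L, , drop = FALSE] +
              A[ro + 1L, co + 1L, , drop = FALSE]) / 2  # mean x gain 2
        dim(Y) <- c((H %/% 2L) * (W %/% 2L) * C, N)
        list(out = Y, cache = list(N = N))
      } else {
        # max pool; remember which quadrant won (ties -> first) so the
        # backward pass can route the gradient there.
        m <- A[ro, co, , drop = FALSE]
        wh <- array(1L, dim(m))
        for (k in 2:4) {
          qk <- switch(k - 1L,
                       A[ro + 1L, co, , drop = FALSE],
                       A[ro, co + 1L, , drop = FALSE],
                       A[ro + 1L, co + 1L, , drop = FALSE])
          upd <- qk > m
          m[upd] <- qk[upd]
          wh[upd] <- k
        }
        dim(m) <- c((H %/% 2L) * (W %/% 2L) * C, N)
        list(out = m, cache = list(N = N, wh = wh))
      }
    },
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = list(mask = mask))
    },
    fc = {
      list(out = layer$params$W %*% X + layer$params$b, cache = list(X = X))
    },
    residual = {
      g <- layer$geom; C <- layer$c_out
      a <- .conv_fwd(X, layer$params$Wa, layer$params$ba, g, C)
      m1 <- a$out > 0
      r1 <- a$out * m1
      bfw <- .conv_fwd(r1, layer$params$Wb, layer$params$bb, g, C)
      s <- bfw$out + X
      m2 <- s > 0
      list(out = s * m2,
           cache = list(cols_a = a$cols, cols_b = bfw$cols, m1 = m1, m2 = m2,
                        N = a$N))
    },
    stop_invalid("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dOut, cache, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      r <- .conv_bwd(dOut, layer$params$W, cache$cols, layer$geom,
                     layer$c_out, cache$N, need_dx)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    pool = {
      s <- layer$in_shape; H <- s[1]; W <- s[2]; C <- s[3]; N <- cache$N
      q <- array(dOut, c(H %/% 2L, W %/% 2L, C * N))
      dA <- array(0, c(H, W, C * N))
      ro <- seq(1L, H, 2L); co <- seq(1L, W, 2L)
      if (identical(layer$op, "avg")) {
        q <- q / 2
        dA[ro, co, ] <- q; dA[ro + 1L, co, ] <- q
        dA[ro, co + 1L, ] <- q; dA[ro + 1L, co + 1L, ] <- q
      } else {
        wh <- cache$wh
        dA[ro, co, ] <- q * (wh == 1L)
        dA[ro + 1L, co, ] <- q * (wh == 2L)
        dA[ro, co + 1L, ] <- q * (wh == 3L)
        dA[ro + 1L, co + 1L, ] <- q * (wh == 4L)
      }
      dim(dA) <- c(H * W * C, N)
      list(dX = dA, grads = list())
    },
    relu = list(dX = dOut * cache$mask, grads = list()),
    fc = {
      list(dX = if (need_dx) crossprod(layer$params$W, dOut) else NULL,
           grads = list(W = tcrossprod(dOut, cache$X), b = rowSums(dOut)))
    },
    residual = {
      g <- layer$geom; C <- layer$c_out
      ds <- dOut * cache$m2
      rb <- .conv_bwd(ds, layer$params$Wb, cache$cols_b, g, C, cache$N, TRUE)
      dr1 <- rb$dX * cache$m1
      ra <- .conv_bwd(dr1, layer$params$Wa, cache$cols_a, g, C, cache$N, need_dx)
      dX <- if (need_dx) ra$dX + ds else NULL
      list(dX = dX,
           grads = list(Wa = ra$dW, ba = ra$db, Wb = rb$dW, bb = rb$db))
    }
  )
}

# Forward a batch through a contiguous run of layers; optionally keep caches
# (training) and collect activations at hook layers.
run_layers <- function(layers, X, keep_cache = FALSE, collect_hooks = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  hooks <- if (collect_hooks) list() else NULL
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X)
    X <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (collect_hooks && isTRUE(layers[[i]]$hook)) {
      hooks[[length(hooks) + 1L]] <- list(index = i, act = X)
    }
  }
  list(out = X, caches = caches, hooks = hooks)
}

# softmax over rows of a (classes x N) score matrix, numerically stabilized.
softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}
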