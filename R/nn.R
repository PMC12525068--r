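# Minimal convolutional-network engine.
#
# A deliberately small, pure-R implementation of the handful of layer types
# the fusion classifier needs: 3x3 same-padding convolution (im2col + one
# matrix product per batch), ReLU, 2x2 average pooling, global average
# pooling, dense layers, inverted dropout, and a softmax/cross-entropy head,
# trained with Adam. Batches are height x width x channels x n arrays
# (column-major); forward and backward passes are fully vectorized over the
# batch, which keeps desk-scale training (thousands of 32x32 frames) fast
# without compiled code.
#
# Each layer is a list carrying its `type`, parameters (`W`, `b`), Adam
# moment estimates, and a `trainable` flag. Parameter-free layers carry the
# flag too so that "the last k layers" of a backbone is a well-defined slice
# of its layer list.

nn_layer_conv <- function(c_in, c_out, seed_offset = 0L) {
  # He-uniform fan-in initialization
  fan_in <- 9L * c_in
  lim <- sqrt(6 / fan_in)
  W <- matrix(stats::runif(9L * c_in * c_out, -lim, lim), 9L * c_in, c_out)
  list(type = "conv", c_in = c_in, c_out = c_out,
       W = W, b = numeric(c_out),
       mW = W * 0, vW = W * 0, mb = numeric(c_out), vb = numeric(c_out),
       trainable = TRUE)
}

nn_layer_dense <- function(d_in, d_out) {
  lim <- sqrt(6 / d_in)
  W <- matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = W, b = numeric(d_out),
       mW = W * 0, vW = W * 0, mb = numeric(d_out), vb = numeric(d_out),
       trainable = TRUE)
}

nn_layer_simple <- function(type, ...) {
  c(list(type = type, trainable = TRUE), list(...))
}

# im2col index table for a 3x3 same-padding convolution on an h x w x c
# input padded by 1. Rows: output pixels (h fastest); columns: (dh, dw, c).
conv_index_table <- function(h, w, c_in) {
  hp <- h + 2L; wp <- w + 2L
  oh <- rep(seq_len(h), times = w)       # output row, column-major order
  ow <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 9L * c_in)
  q <- 0L
  for (cc in seq_len(c_in)) {
    for (dw in 0:2) {
      for (dh in 0:2) {
        q <- q + 1L
        idx[, q] <- (oh + dh) + (ow + dw - 1L) * hp + (cc - 1L) * hp * wp
      }
    }
  }
  idx
}

conv_forward <- function(layer, x, cache) {
  d <- dim(x)  # h, w, c, n
  h <- d[1]; w <- d[2]; c_in <- d[3]; n <- d[4]
  hp <- h + 2L; wp <- w + 2L
  xp <- array(0, dim = c(hp, wp, c_in, n))
  xp[2:(h + 1L), 2:(w + 1L), , ] <- x
  key <- paste0(h, "x", w, "x", c_in)
  idx <- cache$idx[[key]]
  if (is.null(idx)) {
    idx <- conv_index_table(h, w, c_in)
    cache$idx[[key]] <- idx
  }
  per_sample <- hp * wp * c_in
  # patches for the whole batch: samples stacked along rows
  offs <- rep((seq_len(n) - 1L) * per_sample, each = h * w)
  big_idx <- idx[rep(seq_len(h * w), times = n), , drop = FALSE] + offs
  patches <- matrix(xp[big_idx], nrow = h * w * n)
  y <- patches %*% layer$W
  y <- sweep(y, 2L, layer$b, "+")
  # patch rows are ordered (pixel within sample, then sample); reshape to
  # (h, w, n, c_out) and permute to the canonical (h, w, c_out, n)
  out <- aperm(array(y, dim = c(h, w, n, layer$c_out)), c(1L, 2L, 4L, 3L))
  list(out = out,
       ctx = list(patches = patches, big_idx = big_idx, dims = d,
                  padded_len = length(xp)))
}

conv_backward <- function(layer, dy, ctx) {
  d <- ctx$dims
  h <- d[1]; w <- d[2]; c_in <- d[3]; n <- d[4]
  # reorder dy from (h, w, c_out, n) to rows (pixel within sample, sample)
  dymat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), nrow = h * w * n)  # x c_out
  grads <- NULL
  if (isTRUE(layer$trainable)) {
    grads <- list(W = crossprod(ctx$patches, dymat), b = colSums(dymat))
  }
  dpatch <- tcrossprod(dymat, layer$W)   # (h*w*n) x (9*c_in)
  dxp <- numeric(ctx$padded_len)
  # for a fixed kernel offset the output->input map is injective, so a
  # column-wise vectorized accumulate is exact
  for (q in seq_len(ncol(dpatch))) {
    ii <- ctx$big_idx[, q]
    dxp[ii] <- dxp[ii] + dpatch[, q]
  }
  dxp <- array(dxp, dim = c(h + 2L, w + 2L, c_in, n))
  list(dx = dxp[2:(h + 1L), 2:(w + 1L), , , drop = FALSE], grads = grads)
}

pool_forward <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("average pooling requires even spatial dimensions", call. = FALSE)
  }
  oi <- seq(1L, h, by = 2L); oj <- seq(1L, w, by = 2L)
  y <- (x[oi, oj, , , drop = FALSE] + x[oi + 1L, oj, , , drop = FALSE] +
          x[oi, oj + 1L, , , drop = FALSE] + x[oi + 1L, oj + 1L, , , drop = FALSE]) / 4
  list(out = y, ctx = list(dims = d))
}

pool_backward <- function(dy, ctx) {
  d <- ctx$dims
  dx <- array(0, dim = d)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  g <- dy / 4
  dx[oi, oj, , ] <- g; dx[oi + 1L, oj, , ] <- g
  dx[oi, oj + 1L, , ] <- g; dx[oi + 1L, oj + 1L, , ] <- g
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])           # (h*w) x (c*n)
  y <- matrix(colMeans(m), nrow = d[3])        # c x n
  list(out = t(y), ctx = list(dims = d))       # n x c
}

gap_backward <- function(dy, ctx) {
  d <- ctx$dims
  per <- d[1] * d[2]
  g <- t(dy) / per                             # c x n
  array(rep(as.numeric(g), each = per), dim = d)
}

# Forward pass through a layer list. `training` enables dropout masks.
nn_forward <- function(layers, x, cache, training = FALSE) {
  ctxs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- conv_forward(ly, x, cache); x <- r$out; ctxs[[i]] <- r$ctx
    } else if (ly$type == "relu") {
      ctxs[[i]] <- list(mask = x > 0); x <- x * ctxs[[i]]$mask
    } else if (ly$type == "pool") {
      r <- pool_forward(x); x <- r$out; ctxs[[i]] <- r$ctx
    } else if (ly$type == "gap") {
      r <- gap_forward(x); x <- r$out; ctxs[[i]] <- r$ctx
    } else if (ly$type == "dense") {
      ctxs[[i]] <- list(x = x)
      x <- sweep(x %*% ly$W, 2L, ly$b, "+")
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- matrix(stats::rbinom(length(x), 1L, 1 - ly$rate), nrow(x)) / (1 - ly$rate)
        ctxs[[i]] <- list(mask = mask); x <- x * mask
      } else ctxs[[i]] <- list(mask = NULL)
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, ctxs = ctxs)
}

# Backward pass; returns gradients per layer (NULL for frozen/parameter-free)
# and the input gradient. `stop_at` truncates backpropagation once every
# remaining upstream layer is frozen.
nn_backward <- function(layers, dy, ctxs, stop_at = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      r <- conv_backward(ly, dy, ctxs[[i]])
      grads[[i]] <- r$grads; dy <- r$dx
    } else if (ly$type == "relu") {
      dy <- dy * ctxs[[i]]$mask
    } else if (ly$type == "pool") {
      dy <- pool_backward(dy, ctxs[[i]])
    } else if (ly$type == "gap") {
      dy <- gap_backward(dy, ctxs[[i]])
    } else if (ly$type == "dense") {
      if (isTRUE(ly$trainable)) {
        grads[[i]] <- list(W = crossprod(ctxs[[i]]$x, dy), b = colSums(dy))
      }
      dy <- tcrossprod(dy, ly$W)
    } else if (ly$type == "dropout") {
      if (!is.null(ctxs[[i]]$mask)) dy <- dy * ctxs[[i]]$mask
    }
    if (i <= stop_at) break
  }
  list(grads = grads, dx = dy)
}

# Adam update applied in place on a layer list.
nn_adam_step <- function(layers, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g) || !isTRUE(layers[[i]]$trainable)) next
    ly <- layers[[i]]
    ly$mW <- beta1 * ly$mW + (1 - beta1) * g$W
    ly$vW <- beta2 * ly$vW + (1 - beta2) * g$W^2
    ly$W <- ly$W - lr * (ly$mW / bc1) / (sqrt(ly$vW / bc2) + eps)
    ly$mb <- beta1 * ly$mb + (1 - beta1) * g$b
    ly$vb <- beta2 * ly$vb + (1 - beta2) * g$b^2
    ly$b <- ly$b - lr * (ly$mb / bc1) / (sqrt(ly$vb / bc2) + eps)
    layers[[i]] <- ly
  }
  layers
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Index of the first frozen-to-trainable boundary in a layer list (0 when
# everything is trainable): backprop below this point is unnecessary.
first_trainable <- function(layers) {
  tr <- vapply(layers, function(l) isTRUE(l$trainable), logical(1))
  if (!any(tr)) return(length(layers) + 1L)
  which(tr)[1L]
}
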