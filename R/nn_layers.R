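# Layer primitives for the residual network. Activations are numeric
# arrays (H, W, C, N); convolution weights are (kh, kw, C_in, C_out).
# Each layer has a forward returning output + cache and a backward taking
# the cache + upstream gradient.

nn_conv_forward <- function(x, w, stride = 1L, pad = 0L) {
  .conv2d_forward(x, w, as.integer(stride), as.integer(pad))
}

nn_conv_backward <- function(x, w, dy, stride = 1L, pad = 0L) {
  .conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad))
}

nn_maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  .maxpool_forward(x, as.integer(k), as.integer(stride), as.integer(pad))
}

nn_maxpool_backward <- function(idx, dy, x_dim) {
  .maxpool_backward(idx, dy, as.integer(x_dim))
}

# Batch normalization over (H, W, N) per channel. In pass-through mode the
# layer is the identity (used for algebraic unit checks of the residual
# identities). Returns y, a backward cache, and the updated running stats.
nn_bn_forward <- function(x, gamma, beta, run_mean, run_var,
                          train = FALSE, momentum = 0.1, eps = 1e-5,
                          passthrough = FALSE) {
  if (passthrough) {
    return(list(y = x, cache = list(passthrough = TRUE),
                run_mean = run_mean, run_var = run_var))
  }
  d <- dim(x)
  C <- d[3]
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  if (train) {
    mu <- colMeans(m)
    xc <- sweep(m, 2, mu)
    va <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean
    va <- run_var
    xc <- sweep(m, 2, mu)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv_sd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y,
       cache = list(passthrough = FALSE, xhat = xhat, inv_sd = inv_sd,
                    gamma = gamma, dims = d, train = train),
       run_mean = run_mean, run_var = run_var)
}

nn_bn_backward <- function(cache, dy) {
  if (isTRUE(cache$passthrough)) {
    return(list(dx = dy, dgamma = NULL, dbeta = NULL))
  }
  d <- cache$dims
  C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, `*`)
  if (cache$train) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
    t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / m, `*`)
    dxm <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
  } else {
    dxm <- sweep(dxhat, 2, cache$inv_sd, `*`)
  }
  dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, cache = x > 0)
}

nn_relu_backward <- function(cache, dy) dy * cache

# Global average pooling: (H, W, C, N) -> (C, N)
nn_gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  feat <- matrix(colMeans(m), nrow = d[3], ncol = d[4])
  list(y = feat, cache = d)
}

nn_gap_backward <- function(cache, dfeat) {
  d <- cache
  scale <- 1 / (d[1] * d[2])
  array(rep(as.numeric(dfeat), each = d[1] * d[2]) * scale, dim = d)
}

# Fully connected head: feat (C, N) -> logits (K, N); W is (C, K).
nn_fc_forward <- function(feat, W, b) {
  z <- crossprod(W, feat) + b
  list(y = z, cache = feat)
}

nn_fc_backward <- function(cache, W, dz) {
  list(dfeat = W %*% dz,
       dW = cache %*% t(dz),
       db = rowSums(dz))
}

nn_softmax <- function(z) {
  zs <- sweep(z, 2, apply(z, 2, max))
  e <- exp(zs)
  sweep(e, 2, colSums(e), `/`)
}
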