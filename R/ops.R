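# Low-level differentiable layer primitives.
#
# All feature maps travel as a C x (H*W*N) matrix (one column per pixel,
# spatial index column-major within an image, images consecutive); dense
# activations as a features x N matrix. Every *_fwd returns list(out, cache);
# every *_bwd takes (dout, cache) and returns list(dx, grads) where `grads`
# parallels the layer's parameter list.

init_dense <- function(n_in, n_out, sd = sqrt(2 / n_in)) {
  list(W = matrix(rnorm(n_out * n_in, sd = sd), n_out, n_in),
       b = numeric(n_out))
}

init_conv <- function(in_c, out_c, k) {
  fan_in <- in_c * k * k
  list(W = matrix(rnorm(out_c * fan_in, sd = sqrt(2 / fan_in)), out_c, fan_in),
       b = numeric(out_c))
}

init_depthwise <- function(C, k) {
  list(W = matrix(rnorm(k * k * C, sd = sqrt(2 / (k * k))), k * k, C),
       b = numeric(C))
}

init_bn <- function(C) list(gamma = rep(1, C), beta = numeric(C))
init_ln <- function(F) list(gamma = rep(1, F), beta = numeric(F))

conv_fwd <- function(X, H, W, N, p, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  cols <- if (k == 1L && stride == 1L && pad == 0L) X
          else cpp_im2col(X, H, W, N, k, stride, pad)
  out <- p$W %*% cols + p$b
  list(out = out,
       Ho = conv_out_dim(H, k, stride, pad), Wo = conv_out_dim(W, k, stride, pad),
       cache = list(cols = cols, C_in = nrow(X), H = H, W = W, N = N,
                    k = k, stride = stride, pad = pad))
}

conv_bwd <- function(dout, cache, p) {
  k <- cache$k
  onebyone <- k == 1L && cache$stride == 1L && cache$pad == 0L
  dW <- tcrossprod(dout, cache$cols)
  db <- rowSums(dout)
  dcols <- crossprod(p$W, dout)
  dx <- if (onebyone) dcols
        else cpp_col2im(dcols, cache$C_in, cache$H, cache$W, cache$N,
                        k, cache$stride, cache$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

# Depthwise k x k convolution, stride 1, same padding.
depthwise_fwd <- function(X, H, W, N, p, k) {
  out <- cpp_depthwise_fwd(X, H, W, N, k, p$W, p$b)
  list(out = out, cache = list(X = X, H = H, W = W, N = N, k = k))
}

depthwise_bwd <- function(dout, cache, p) {
  r <- cpp_depthwise_bwd(dout, cache$X, cache$H, cache$W, cache$N, cache$k, p$W)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

maxpool_fwd <- function(X, H, W, N, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool_fwd(X, H, W, N, k, stride, pad)
  list(out = r$out,
       Ho = conv_out_dim(H, k, stride, pad), Wo = conv_out_dim(W, k, stride, pad),
       cache = list(arg = r$arg, ncol_in = ncol(X)))
}

maxpool_bwd <- function(dout, cache) cpp_maxpool_bwd(dout, cache$arg, cache$ncol_in)

relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, cache = X > 0)
}
relu_bwd <- function(dout, mask) dout * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

bn_fwd <- function(X, p, state, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    m <- ncol(X)
    mu <- rowMeans(X)
    v <- rowMeans(X * X) - mu * mu
    v[v < 0] <- 0
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * ivar
  out <- p$gamma * xhat + p$beta
  list(out = out, state = state,
       cache = list(xhat = xhat, ivar = ivar, gamma = p$gamma, train = train))
}

bn_bwd <- function(dout, cache) {
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * cache$gamma
  if (cache$train) {
    m <- ncol(dout)
    dx <- (cache$ivar / m) * (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$ivar
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

dense_fwd <- function(X, p) {
  list(out = p$W %*% X + p$b, cache = X)
}
dense_bwd <- function(dout, X, p) {
  list(dx = crossprod(p$W, dout),
       grads = list(W = tcrossprod(dout, X), b = rowSums(dout)))
}

# Layer normalization over the feature axis, per sample (column).
ln_fwd <- function(X, p, eps = 1e-5) {
  F <- nrow(X)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = F)
  v <- colMeans(Xc * Xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- Xc * rep(ivar, each = F)
  out <- p$gamma * xhat + p$beta
  list(out = out, cache = list(xhat = xhat, ivar = ivar, gamma = p$gamma))
}

ln_bwd <- function(dout, cache) {
  F <- nrow(dout)
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * cache$gamma
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (rep(cache$ivar, each = F) / F) *
    (F * dxhat - rep(s1, each = F) - cache$xhat * rep(s2, each = F))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

dropout_fwd <- function(X, p_drop, train) {
  if (!train || p_drop <= 0) return(list(out = X, cache = NULL))
  mask <- (matrix(runif(length(X)), nrow(X)) >= p_drop) / (1 - p_drop)
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dout, mask) if (is.null(mask)) dout else dout * mask

# Column-wise softmax.
softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(E))
}

# Cross-entropy over a K x N logit matrix; labels in 1..K.
softmax_ce <- function(logits, labels) {
  N <- ncol(logits)
  P <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(P[idx] + 1e-12))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = P, dlogits = dlogits / N)
}

# Global average pooling: C x (T*N) -> C x N.
gap_fwd <- function(X, T, N) {
  out <- matrix(0, nrow(X), N)
  for (n in seq_len(N))
    out[, n] <- rowMeans(X[, ((n - 1) * T + 1):(n * T), drop = FALSE])
  list(out = out, cache = list(T = T, N = N))
}
gap_bwd <- function(dout, cache) rep_cols(dout, cache$T) / cache$T

# Pooling matrix (T_in x g^2) for adaptive average pooling of an H x W grid
# to a g x g grid; columns are output cells, entries are averaging weights.
adaptive_pool_matrix <- function(H, W, g) {
  seg <- function(n) {
    lo <- floor((seq_len(g) - 1) * n / g) + 1
    hi <- ceiling(seq_len(g) * n / g)
    cbind(lo, hi)
  }
  sh <- seg(H); sw <- seg(W)
  P <- matrix(0, H * W, g * g)
  for (jw in seq_len(g)) {
    for (jh in seq_len(g)) {
      col <- (jw - 1) * g + jh
      hs <- sh[jh, 1]:sh[jh, 2]
      ws <- sw[jw, 1]:sw[jw, 2]
      idx <- as.vector(outer(hs, (ws - 1) * H, `+`))
      P[idx, col] <- 1 / length(idx)
    }
  }
  P
}
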