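# The three attention mechanisms of the network body.
#
# Internal *_fwd/*_bwd functions work on the C x (T*N) matrix layout used by
# the rest of the network; the exported wrappers accept N x C x H x W arrays
# so the blocks can be exercised (and oracle-tested) in isolation.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## ---- channel attention (CAM) -------------------------------------------

#' Initialize CBAM weights
#'
#' Creates the learnable parameters for a convolutional block attention
#' module acting on feature maps with `C` channels: the shared two-layer MLP
#' of the channel gate (hidden width `floor(C / r)`) and the `kernel` x
#' `kernel` convolution of the spatial gate (2 input channels: channel-wise
#' mean and max).
#'
#' @param C number of input channels.
#' @param r channel-gate reduction ratio; `floor(C / r)` must be >= 1.
#' @param kernel spatial-gate convolution size (odd).
#' @return list with components `channel` (fc1, fc2) and `spatial` (conv).
#' @export
cbam_init <- function(C, r = 16, kernel = 7) {
  hidden <- C %/% r
  if (hidden < 1) stop("channel reduction ratio too large: floor(C/r) < 1", call. = FALSE)
  list(channel = list(fc1 = init_dense(C, hidden), fc2 = init_dense(hidden, C)),
       spatial = list(conv = init_conv(2, 1, kernel), kernel = kernel),
       r = r)
}

# Per-image global max pool with argmax: X is C x (T*N).
gmp_cols <- function(X, T, N) {
  C <- nrow(X)
  val <- matrix(0, C, N)
  arg <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    blk <- X[, ((n - 1) * T + 1):(n * T), drop = FALSE]
    j <- max.col(blk, ties.method = "first")
    arg[, n] <- j
    val[, n] <- blk[cbind(seq_len(C), j)]
  }
  list(val = val, arg = arg)
}

ca_fwd <- function(X, T, N, p) {
  avg <- gap_fwd(X, T, N)$out
  mx <- gmp_cols(X, T, N)
  a1 <- p$fc1$W %*% avg + p$fc1$b
  m1 <- p$fc1$W %*% mx$val + p$fc1$b
  a1r <- a1 * (a1 > 0)
  m1r <- m1 * (m1 > 0)
  s <- a1r + m1r
  z <- p$fc2$W %*% s + p$fc2$b
  G <- sigmoid(z)
  out <- X * rep_cols(G, T)
  list(out = out, M_c = G,
       cache = list(X = X, T = T, N = N, avg = avg, mxval = mx$val, mxarg = mx$arg,
                    a1 = a1, m1 = m1, s = s, G = G))
}

ca_bwd <- function(dout, cache, p) {
  X <- cache$X; T <- cache$T; N <- cache$N; G <- cache$G
  C <- nrow(X)
  dX <- dout * rep_cols(G, T)
  dG <- gap_fwd(dout * X, T, N)$out * T
  dz <- dG * G * (1 - G)
  dW2 <- tcrossprod(dz, cache$s)
  db2 <- rowSums(dz)
  ds <- crossprod(p$fc2$W, dz)
  da1 <- ds * (cache$a1 > 0)
  dm1 <- ds * (cache$m1 > 0)
  dW1 <- tcrossprod(da1, cache$avg) + tcrossprod(dm1, cache$mxval)
  db1 <- rowSums(da1) + rowSums(dm1)
  davg <- crossprod(p$fc1$W, da1)
  dmx <- crossprod(p$fc1$W, dm1)
  dX <- dX + rep_cols(davg, T) / T
  gcol <- sweep(cache$mxarg, 2, (seq_len(N) - 1) * T, `+`)
  idx <- cbind(rep(seq_len(C), times = N), as.vector(gcol))
  dXmax <- matrix(0, C, T * N)
  dXmax[idx] <- as.vector(dmx)
  dX <- dX + dXmax
  list(dx = dX, grads = list(fc1 = list(W = dW1, b = db1), fc2 = list(W = dW2, b = db2)))
}

## ---- spatial attention (SPAM) ------------------------------------------

sa_fwd <- function(X, H, W, N, p) {
  C <- nrow(X)
  TN <- ncol(X)
  avg <- colMeans(X)
  jc <- max.col(t(X), ties.method = "first")
  mx <- X[cbind(jc, seq_len(TN))]
  cat2 <- rbind(avg, mx)
  cv <- conv_fwd(cat2, H, W, N, p$conv, k = p$kernel, stride = 1L)
  Ms <- sigmoid(cv$out)
  out <- X * rep(as.vector(Ms), each = C)
  list(out = out, M_s = Ms,
       cache = list(X = X, jc = jc, Ms = Ms, conv_cache = cv$cache, C = C))
}

sa_bwd <- function(dout, cache, p) {
  C <- cache$C
  X <- cache$X
  Msv <- rep(as.vector(cache$Ms), each = C)
  dX <- dout * Msv
  dMs <- matrix(colSums(dout * X), 1)
  dz <- dMs * cache$Ms * (1 - cache$Ms)
  cb <- conv_bwd(dz, cache$conv_cache, p$conv)
  dcat <- cb$dx
  dX <- dX + rep(dcat[1, ], each = C) / C
  dXmax <- matrix(0, C, ncol(X))
  dXmax[cbind(cache$jc, seq_len(ncol(X)))] <- dcat[2, ]
  dX <- dX + dXmax
  list(dx = dX, grads = list(conv = cb$grads))
}

cbam_fwd <- function(X, H, W, N, p) {
  T <- H * W
  ca <- ca_fwd(X, T, N, p$channel)
  sa <- sa_fwd(ca$out, H, W, N, p$spatial)
  list(out = sa$out, M_c = ca$M_c, M_s = sa$M_s,
       cache = list(ca = ca$cache, sa = sa$cache))
}

cbam_bwd <- function(dout, cache, p) {
  sb <- sa_bwd(dout, cache$sa, p$spatial)
  cb <- ca_bwd(sb$dx, cache$ca, p$channel)
  list(dx = cb$dx, grads = list(channel = cb$grads, spatial = sb$grads))
}

## ---- multi-head self-attention (MHSAM) ---------------------------------

#' Initialize multi-head self-attention weights
#'
#' Linear projections for queries, keys, values (`C -> d`) and the output
#' projection (`d -> C`) of self-attention over the flattened spatial
#' positions of a feature map.
#'
#' @param C input channel count (token width).
#' @param d embedding dimension; must be divisible by `heads`. Defaults to `C`.
#' @param heads number of attention heads.
#' @return weight list (`Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`, `Wo`, `bo`).
#' @export
mhsa_init <- function(C, d = C, heads = 4) {
  if (d %% heads != 0) stop("embedding dimension d must be divisible by heads", call. = FALSE)
  sdq <- sqrt(1 / C)
  list(Wq = matrix(rnorm(d * C, sd = sdq), d, C), bq = numeric(d),
       Wk = matrix(rnorm(d * C, sd = sdq), d, C), bk = numeric(d),
       Wv = matrix(rnorm(d * C, sd = sdq), d, C), bv = numeric(d),
       Wo = matrix(rnorm(C * d, sd = sqrt(1 / d)), C, d), bo = numeric(C),
       heads = heads, d = d)
}

mhsa_fwd <- function(X, T, N, p) {
  C <- nrow(X)
  h <- p$heads; d <- p$d
  dh <- d / h
  scale <- 1 / sqrt(dh)
  out <- matrix(0, C, T * N)
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    blk <- ((n - 1) * T + 1):(n * T)
    Tok <- t(X[, blk, drop = FALSE])                      # T x C
    Q <- tcrossprod(Tok, p$Wq) + rep(p$bq, each = T)
    K <- tcrossprod(Tok, p$Wk) + rep(p$bk, each = T)
    V <- tcrossprod(Tok, p$Wv) + rep(p$bv, each = T)
    O <- matrix(0, T, d)
    As <- vector("list", h)
    for (i in seq_len(h)) {
      hi <- ((i - 1) * dh + 1):(i * dh)
      S <- tcrossprod(Q[, hi, drop = FALSE], K[, hi, drop = FALSE]) * scale
      A <- t(softmax_cols(t(S)))                          # row softmax
      As[[i]] <- A
      O[, hi] <- A %*% V[, hi, drop = FALSE]
    }
    Y <- tcrossprod(O, p$Wo) + rep(p$bo, each = T)
    out[, blk] <- t(Y)
    caches[[n]] <- list(Tok = Tok, Q = Q, K = K, V = V, O = O, As = As)
  }
  list(out = out, cache = list(per_image = caches, T = T, N = N, scale = scale))
}

mhsa_bwd <- function(dout, cache, p) {
  T <- cache$T; N <- cache$N
  h <- p$heads; d <- p$d
  dh <- d / h
  scale <- cache$scale
  C <- nrow(dout)
  dX <- matrix(0, C, T * N)
  g <- list(Wq = 0 * p$Wq, bq = 0 * p$bq, Wk = 0 * p$Wk, bk = 0 * p$bk,
            Wv = 0 * p$Wv, bv = 0 * p$bv, Wo = 0 * p$Wo, bo = 0 * p$bo)
  for (n in seq_len(N)) {
    blk <- ((n - 1) * T + 1):(n * T)
    cc <- cache$per_image[[n]]
    dY <- t(dout[, blk, drop = FALSE])                    # T x C
    g$Wo <- g$Wo + crossprod(dY, cc$O)
    g$bo <- g$bo + colSums(dY)
    dO <- dY %*% p$Wo
    dQ <- matrix(0, T, d); dK <- matrix(0, T, d); dV <- matrix(0, T, d)
    for (i in seq_len(h)) {
      hi <- ((i - 1) * dh + 1):(i * dh)
      A <- cc$As[[i]]
      dOh <- dO[, hi, drop = FALSE]
      Vh <- cc$V[, hi, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, hi] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, hi] <- dS %*% cc$K[, hi, drop = FALSE] * scale
      dK[, hi] <- crossprod(dS, cc$Q[, hi, drop = FALSE]) * scale
    }
    g$Wq <- g$Wq + crossprod(dQ, cc$Tok); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(dK, cc$Tok); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(dV, cc$Tok); g$bv <- g$bv + colSums(dV)
    dTok <- dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
    dX[, blk] <- t(dTok)
  }
  list(dx = dX, grads = g[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")])
}

## ---- slot attention (SAM) ----------------------------------------------

#' Initialize slot attention weights
#'
#' Learnable parameters of the slot-attention branch: the token projection
#' (`C -> dim`), slot initialization mean `mu` and (softplus-parameterized)
#' scale `sigma_raw`, the slot layer norm, and the residual update MLP
#' (`dim -> dim -> dim`, ReLU hidden).
#'
#' @param C input channel count.
#' @param dim slot width.
#' @return weight list.
#' @export
slot_init <- function(C, dim = 16) {
  list(proj = init_dense(C, dim, sd = sqrt(1 / C)),
       mu = rnorm(dim, sd = 0.5),
       sigma_raw = rep(log(expm1(0.5)), dim),
       ln = init_ln(dim),
       mlp = list(W1 = matrix(rnorm(dim * dim, sd = sqrt(2 / dim)), dim, dim),
                  b1 = rep(0.01, dim),  # small positive: avoids an all-dead ReLU hidden layer at narrow widths
                  W2 = matrix(rnorm(dim * dim, sd = sqrt(2 / dim)), dim, dim),
                  b2 = numeric(dim)))
}

# Token pooling matrix for the slot branch: `grid` mode pools the H x W map
# to a g x g token grid; `literal` mode pools to a single global-average
# token, exactly as the pseudo-code reads.
slot_pool_matrix <- function(H, W, mode, g) {
  if (mode == "literal") matrix(1 / (H * W), H * W, 1)
  else adaptive_pool_matrix(H, W, min(g, H, W))
}

slot_fwd <- function(X, H, W, N, p, num_slots, iters, mode = "grid", g = 7,
                     train = FALSE) {
  C <- nrow(X)
  T <- H * W
  P <- slot_pool_matrix(H, W, mode, g)
  K <- ncol(P)
  dim_ <- length(p$mu)
  sig <- softplus(p$sigma_raw)
  scale <- 1 / sqrt(dim_)
  out <- matrix(0, dim_, N)
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    blk <- ((n - 1) * T + 1):(n * T)
    Xn <- X[, blk, drop = FALSE]
    Tn <- Xn %*% P                                        # C x K tokens
    En <- p$proj$W %*% Tn + p$proj$b                      # dim x K
    eps <- if (train) matrix(rnorm(num_slots * dim_), num_slots, dim_)
           else matrix(0, num_slots, dim_)
    S <- rep(p$mu, each = num_slots) + sweep(eps, 2, sig, `*`)
    iter_caches <- vector("list", iters)
    if (iters > 0) for (t in seq_len(iters)) {
      lnr <- ln_fwd(t(S), p$ln)
      Sn <- t(lnr$out)                                    # num_slots x dim
      logits <- Sn %*% En * scale                         # num_slots x K
      A <- softmax_cols(logits)                           # slots compete per token
      U <- A %*% t(En)                                    # num_slots x dim
      H1 <- U %*% t(p$mlp$W1) + rep(p$mlp$b1, each = num_slots)
      H1r <- H1 * (H1 > 0)
      Upd <- H1r %*% t(p$mlp$W2) + rep(p$mlp$b2, each = num_slots)
      iter_caches[[t]] <- list(ln_cache = lnr$cache, Sn = Sn, A = A, U = U, H1 = H1, H1r = H1r)
      S <- Sn + Upd
    }
    out[, n] <- colMeans(S)
    caches[[n]] <- list(Tn = Tn, En = En, eps = eps, iters = iter_caches, A_last = if (iters > 0) iter_caches[[iters]]$A else NULL)
  }
  list(out = out, P = P,
       cache = list(per_image = caches, P = P, T = T, N = N, num_slots = num_slots,
                    iters = iters, sig = sig, scale = scale, dim = dim_))
}

slot_bwd <- function(dout, cache, p) {
  N <- cache$N; T <- cache$T
  S_n <- cache$num_slots
  iters <- cache$iters
  scale <- cache$scale
  dim_ <- cache$dim
  P <- cache$P
  C <- ncol(p$proj$W)
  dX <- matrix(0, C, T * N)
  g <- list(proj = list(W = 0 * p$proj$W, b = 0 * p$proj$b),
            mu = 0 * p$mu, sigma_raw = 0 * p$sigma_raw,
            ln = list(gamma = 0 * p$ln$gamma, beta = 0 * p$ln$beta),
            mlp = list(W1 = 0 * p$mlp$W1, b1 = 0 * p$mlp$b1,
                       W2 = 0 * p$mlp$W2, b2 = 0 * p$mlp$b2))
  for (n in seq_len(N)) {
    cc <- cache$per_image[[n]]
    En <- cc$En
    dS <- matrix(rep(dout[, n] / S_n, each = S_n), S_n, dim_)
    dEn <- matrix(0, dim_, ncol(En))
    if (iters > 0) for (t in rev(seq_len(iters))) {
      ic <- cc$iters[[t]]
      dUpd <- dS
      dSn <- dS
      g$mlp$W2 <- g$mlp$W2 + crossprod(dUpd, ic$H1r)
      g$mlp$b2 <- g$mlp$b2 + colSums(dUpd)
      dH1 <- (dUpd %*% p$mlp$W2) * (ic$H1 > 0)
      g$mlp$W1 <- g$mlp$W1 + crossprod(dH1, ic$U)
      g$mlp$b1 <- g$mlp$b1 + colSums(dH1)
      dU <- dH1 %*% p$mlp$W1
      dA <- dU %*% En
      dEn <- dEn + crossprod(dU, ic$A)                    # dim x K
      A <- ic$A
      dlogits <- A * (dA - rep(colSums(dA * A), each = S_n))
      dSn <- dSn + dlogits %*% t(En) * scale
      dEn <- dEn + crossprod(ic$Sn, dlogits) * scale
      lb <- ln_bwd(t(dSn), ic$ln_cache)
      g$ln$gamma <- g$ln$gamma + lb$grads$gamma
      g$ln$beta <- g$ln$beta + lb$grads$beta
      dS <- t(lb$dx)
    }
    # S0 = mu + eps * sigma
    g$mu <- g$mu + colSums(dS)
    dsig <- colSums(dS * cc$eps)
    g$sigma_raw <- g$sigma_raw + dsig * sigmoid(p$sigma_raw)
    g$proj$W <- g$proj$W + tcrossprod(dEn, cc$Tn)
    g$proj$b <- g$proj$b + rowSums(dEn)
    dTn <- crossprod(p$proj$W, dEn)                        # C x K
    blk <- ((n - 1) * T + 1):(n * T)
    dX[, blk] <- tcrossprod(dTn, P)
  }
  list(dx = dX, grads = g)
}

## ---- exported array wrappers -------------------------------------------

#' Channel attention gate
#'
#' Applies the channel-attention stage of CBAM to a batch of feature maps:
#' per-image global average and max pooling over space, a shared two-layer
#' MLP on both pooled vectors (hidden ReLU), a sigmoid gate on the summed
#' hidden responses, and channel-wise rescaling of the input.
#'
#' @param x numeric array of dim `N x C x H x W`.
#' @param weights CBAM weights from [cbam_init()] (the `channel` part is used).
#' @return list with `out` (gated array, same dim as `x`) and `M_c`
#'   (`C x N` gate matrix with entries in (0,1)).
#' @export
channel_attention <- function(x, weights) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- ca_fwd(X, d[3] * d[4], d[1], weights$channel)
  list(out = mat_to_nchw(r$out, d[2], d[3], d[4], d[1]), M_c = r$M_c)
}

#' Spatial attention gate
#'
#' Applies the spatial-attention stage of CBAM: channel-wise mean and max
#' maps, 2-channel same-padding convolution, sigmoid gate, and pixel-wise
#' rescaling of the input.
#'
#' @inheritParams channel_attention
#' @return list with `out` and `M_s` (`1 x (H*W*N)` gate, reshapeable to
#'   `H x W` per image, entries in (0,1)).
#' @export
spatial_attention <- function(x, weights) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- sa_fwd(X, d[3], d[4], d[1], weights$spatial)
  list(out = mat_to_nchw(r$out, d[2], d[3], d[4], d[1]), M_s = r$M_s)
}

#' Convolutional block attention module
#'
#' Channel attention followed by spatial attention ([channel_attention()]
#' then [spatial_attention()]), the refinement block of the network body.
#'
#' @inheritParams channel_attention
#' @return list with `out`, `M_c`, `M_s`.
#' @export
cbam <- function(x, weights) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- cbam_fwd(X, d[3], d[4], d[1], weights)
  list(out = mat_to_nchw(r$out, d[2], d[3], d[4], d[1]), M_c = r$M_c, M_s = r$M_s)
}

#' Multi-head self-attention over spatial positions
#'
#' Flattens each feature map to `H*W` tokens of width `C`, projects queries,
#' keys and values, computes per-head scaled dot-product attention
#' `softmax(Q K' / sqrt(d/h))`, concatenates heads and applies the output
#' projection, returning a feature map of the input's shape.
#'
#' @param x numeric array of dim `N x C x H x W`.
#' @param weights from [mhsa_init()].
#' @return list with `out` (same dim as `x`) and `attention` (list over
#'   images of lists over heads of `(H*W) x (H*W)` row-stochastic matrices).
#' @export
mhsa <- function(x, weights) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- mhsa_fwd(X, d[3] * d[4], d[1], weights)
  list(out = mat_to_nchw(r$out, d[2], d[3], d[4], d[1]),
       attention = lapply(r$cache$per_image, `[[`, "As"))
}

#' Slot attention feature clustering
#'
#' Pools the feature map to a token set (a `token_grid` x `token_grid`
#' adaptive-average grid by default, or a single global-average token in
#' `"literal"` mode), projects tokens to the slot width, then iteratively
#' refines `num_slots` slot vectors: layer-normalize slots, soft-assign
#' tokens by a softmax over the *slot* axis of `S E' / sqrt(dim)` (slots
#' compete for tokens), and apply a residual MLP update. The branch summary
#' is the mean over slots.
#'
#' @param x numeric array of dim `N x C x H x W`.
#' @param weights from [slot_init()].
#' @param num_slots number of slots.
#' @param iters refinement iterations (0 returns the mean of the initial slots).
#' @param mode `"grid"` or `"literal"` token pooling.
#' @param token_grid grid side length for `"grid"` mode.
#' @param train if `TRUE` the slot initialization draws Gaussian noise from
#'   the current RNG stream; if `FALSE` slots start exactly at `mu`.
#' @return list with `out` (`N x dim` summary matrix) and `A` (per-image
#'   slot-token attention from the final iteration; columns sum to 1 over slots).
#' @export
slot_attention <- function(x, weights, num_slots = 4, iters = 3,
                           mode = c("grid", "literal"), token_grid = 7,
                           train = FALSE) {
  mode <- match.arg(mode)
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- slot_fwd(X, d[3], d[4], d[1], weights, num_slots, iters, mode, token_grid, train)
  list(out = t(r$out), A = lapply(r$cache$per_image, `[[`, "A_last"))
}
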