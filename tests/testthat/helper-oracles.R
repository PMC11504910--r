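# Independent brute-force oracles used to verify the vectorized / compiled
# implementation paths. These deliberately use naive scalar loops and stay
# free of the package's internal layer code.

# Bilinear interpolation at half-pixel centers, evaluated point by point.
oracle_bilinear <- function(img, Ho, Wo) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, Ho, Wo)
  for (r in seq_len(Ho)) {
    for (c in seq_len(Wo)) {
      ys <- min(max((r - 0.5) * H / Ho - 0.5, 0), H - 1)
      xs <- min(max((c - 0.5) * W / Wo - 0.5, 0), W - 1)
      y0 <- floor(ys); x0 <- floor(xs)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      wy <- ys - y0; wx <- xs - x0
      out[r, c] <- img[y0 + 1, x0 + 1] * (1 - wy) * (1 - wx) +
                   img[y1 + 1, x0 + 1] * wy * (1 - wx) +
                   img[y0 + 1, x1 + 1] * (1 - wy) * wx +
                   img[y1 + 1, x1 + 1] * wy * wx
    }
  }
  out
}

# Same-padding 2-D convolution by scalar loops; x and out are C x H x W
# arrays, W_mat is out_c x (in_c*k^2) with patch position fastest per channel
# (column-major within the k x k patch).
oracle_conv2d <- function(x, W_mat, b, k) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  out_c <- nrow(W_mat)
  pad <- (k - 1) %/% 2
  out <- array(0, dim = c(out_c, H, W))
  for (o in seq_len(out_c)) {
    for (h in seq_len(H)) {
      for (w in seq_len(W)) {
        acc <- b[o]
        for (ci in seq_len(C)) {
          for (kw in seq_len(k)) {
            for (kh in seq_len(k)) {
              hi <- h + kh - 1 - pad
              wi <- w + kw - 1 - pad
              if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
                widx <- (ci - 1) * k * k + (kw - 1) * k + kh
                acc <- acc + x[ci, hi, wi] * W_mat[o, widx]
              }
            }
          }
        }
        out[o, h, w] <- acc
      }
    }
  }
  out
}

sigmoid_o <- function(z) 1 / (1 + exp(-z))

# Channel attention for one image (C x H x W array), scalar loops.
oracle_channel_attention <- function(x, w) {
  C <- dim(x)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[c, , ])
    mx[c] <- max(x[c, , ])
  }
  hid <- nrow(w$fc1$W)
  a1 <- numeric(hid); m1 <- numeric(hid)
  for (j in seq_len(hid)) {
    a1[j] <- max(0, sum(w$fc1$W[j, ] * avg) + w$fc1$b[j])
    m1[j] <- max(0, sum(w$fc1$W[j, ] * mx) + w$fc1$b[j])
  }
  gate <- numeric(C)
  for (c in seq_len(C))
    gate[c] <- sigmoid_o(sum(w$fc2$W[c, ] * (a1 + m1)) + w$fc2$b[c])
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * gate[c]
  list(out = out, gate = gate)
}

# Spatial attention for one image, scalar loops (conv via oracle_conv2d).
oracle_spatial_attention <- function(x, w) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  avg <- apply(x, c(2, 3), mean)
  mx <- apply(x, c(2, 3), max)
  cat2 <- array(0, dim = c(2, H, W))
  cat2[1, , ] <- avg; cat2[2, , ] <- mx
  z <- oracle_conv2d(cat2, w$conv$W, w$conv$b, w$kernel)
  Ms <- sigmoid_o(z[1, , ])
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * Ms
  list(out = out, Ms = Ms)
}

# Multi-head self-attention for one image (C x H x W), triple loops over
# heads, query positions and key positions.
oracle_mhsa <- function(x, w) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  T <- H * W
  h <- w$heads; d <- w$d; dh <- d / h
  tok <- matrix(0, T, C)          # spatial index column-major, matching layout
  for (wi in seq_len(W)) for (hi in seq_len(H))
    tok[(wi - 1) * H + hi, ] <- x[, hi, wi]
  Q <- matrix(0, T, d); K <- matrix(0, T, d); V <- matrix(0, T, d)
  for (t in seq_len(T)) {
    for (j in seq_len(d)) {
      Q[t, j] <- sum(w$Wq[j, ] * tok[t, ]) + w$bq[j]
      K[t, j] <- sum(w$Wk[j, ] * tok[t, ]) + w$bk[j]
      V[t, j] <- sum(w$Wv[j, ] * tok[t, ]) + w$bv[j]
    }
  }
  O <- matrix(0, T, d)
  for (head in seq_len(h)) {
    cols <- ((head - 1) * dh + 1):(head * dh)
    for (q in seq_len(T)) {
      logits <- numeric(T)
      for (kk in seq_len(T))
        logits[kk] <- sum(Q[q, cols] * K[kk, cols]) / sqrt(dh)
      a <- exp(logits - max(logits)); a <- a / sum(a)
      for (j in seq_along(cols))
        O[q, cols[j]] <- sum(a * V[, cols[j]])
    }
  }
  Y <- matrix(0, T, C)
  for (t in seq_len(T))
    for (c in seq_len(C))
      Y[t, c] <- sum(w$Wo[c, ] * O[t, ]) + w$bo[c]
  out <- array(0, dim = c(C, H, W))
  for (wi in seq_len(W)) for (hi in seq_len(H))
    out[, hi, wi] <- Y[(wi - 1) * H + hi, ]
  out
}

# One slot-attention refinement iteration in literal (single-token) mode,
# unrolled with explicit arithmetic. x: C x H x W; returns the slot summary.
oracle_slot_one_iter <- function(x, w, num_slots) {
  C <- dim(x)[1]
  dim_ <- length(w$mu)
  xavg <- numeric(C)
  for (c in seq_len(C)) xavg[c] <- mean(x[c, , ])
  e <- as.numeric(w$proj$W %*% xavg + w$proj$b)       # single token, width dim
  S <- matrix(rep(w$mu, each = num_slots), num_slots) # sigma contributes 0 noise in eval
  # layer norm each slot vector
  Sn <- S
  for (i in seq_len(num_slots)) {
    v <- S[i, ]
    mu <- mean(v); sd2 <- mean((v - mu)^2)
    Sn[i, ] <- w$ln$gamma * (v - mu) / sqrt(sd2 + 1e-5) + w$ln$beta
  }
  logits <- as.numeric(Sn %*% e) / sqrt(dim_)
  a <- exp(logits - max(logits)); a <- a / sum(a)     # softmax over slots
  U <- outer(a, e)                                    # A %*% t(E), K = 1
  H1 <- pmax(U %*% t(w$mlp$W1) + rep(w$mlp$b1, each = num_slots), 0)
  Upd <- H1 %*% t(w$mlp$W2) + rep(w$mlp$b2, each = num_slots)
  S1 <- Sn + Upd
  colMeans(S1)
}

# Metric oracle: direct per-sample counting.
oracle_metrics <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  acc <- (tp + tn) / length(pred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

# Rank-statistic AUC (Mann-Whitney U normalization, average ranks for ties).
oracle_auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small deterministic phantom dataset for training-path tests.
tiny_phantoms <- function(n = 60, size = 64, seed = 3, frac = 0.3) {
  generate_phantoms(phantom_spec(image_size = size, n_images = n,
                                 severe_fraction = frac,
                                 canal_radius_mild = round(size / 10),
                                 canal_radius_severe = round(size / 20),
                                 jitter_sd = 2, seed = seed))
}

# Minimal network config for fast structural tests.
tiny_net <- function(dropout_p = 0.5, ...) {
  network_config(preset = "desk", head_widths = c(3L, 4L), body_channels = 8L,
                 eim_branch_width = 2L, cbam_r = 2L, mhsa_heads = 2L,
                 mhsa_dim = 8L, sam_slots = 2L, sam_dim = 8L, sam_iters = 2L,
                 sam_grid = 2L, tail_widths = c(6L, 4L), dropout_p = dropout_p,
                 ...)
}
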