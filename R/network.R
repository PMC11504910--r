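# Full classifier: convolutional head with Enhanced Inception Modules,
# three-branch attention body (CBAM / MHSAM / SAM) fused by global average
# pooling, and a fully connected tail ending in a 2-class softmax.

#' Network configuration
#'
#' Assembles the hyperparameters of the multi-attention classifier. The
#' topology is fixed (conv7-BN-ReLU, conv3-BN-ReLU, max-pool, two Enhanced
#' Inception Modules, optional max-pool, attention body, FC tail); widths,
#' attention settings and enabled branches are configurable. The `"desk"`
#' preset shrinks every width for CPU-scale experiments; `"full"` keeps the
#' package's full-size defaults.
#'
#' @param preset `"desk"` (small widths, CPU-friendly) or `"full"`.
#' @param in_channels input image channels.
#' @param head_widths channel counts of the two head conv stages.
#' @param head_strides strides of the two head convolutions; the `"desk"`
#'   preset uses `c(4, 2)` (7x7 body map from 224 input), `"full"` uses
#'   `c(2, 2)` (14x14 body map).
#' @param body_channels output width of the Enhanced Inception Modules (the
#'   channel count entering the attention body).
#' @param eim_branch_width channels of each depthwise-separable branch inside
#'   an Enhanced Inception Module.
#' @param body_pool add a 3x3/2 max-pool after the Enhanced Inception Modules.
#' @param cbam_r channel-attention reduction ratio.
#' @param cbam_kernel spatial-attention convolution size.
#' @param mhsa_heads,mhsa_dim multi-head self-attention heads and embedding
#'   dimension (`NULL` dim means "= body_channels").
#' @param sam_slots,sam_dim,sam_iters,sam_grid,sam_mode slot-attention branch
#'   settings (see [slot_attention()]).
#' @param tail_widths widths of the two hidden FC layers of the tail.
#' @param dropout_p dropout probability in the tail (train mode only).
#' @param num_classes number of output classes.
#' @param enabled_branches subset of `c("cbam", "mhsam", "sam")`.
#' @return an object of class `lssnet_config`.
#' @export
network_config <- function(preset = c("desk", "full"),
                           in_channels = 1L,
                           head_widths = NULL,
                           head_strides = NULL,
                           body_channels = NULL,
                           eim_branch_width = NULL,
                           body_pool = TRUE,
                           cbam_r = 16L,
                           cbam_kernel = 7L,
                           mhsa_heads = 4L,
                           mhsa_dim = NULL,
                           sam_slots = 4L,
                           sam_dim = NULL,
                           sam_iters = 3L,
                           sam_grid = 7L,
                           sam_mode = "grid",
                           tail_widths = NULL,
                           dropout_p = 0.5,
                           num_classes = 2L,
                           enabled_branches = c("cbam", "mhsam", "sam")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    head_widths <- head_widths %||% c(32L, 64L)
    head_strides <- head_strides %||% c(2L, 2L)
    body_channels <- body_channels %||% 128L
    eim_branch_width <- eim_branch_width %||% 32L
    sam_dim <- sam_dim %||% 64L
    tail_widths <- tail_widths %||% c(256L, 64L)
  } else {
    head_widths <- head_widths %||% c(8L, 16L)
    head_strides <- head_strides %||% c(4L, 2L)
    body_channels <- body_channels %||% 32L
    eim_branch_width <- eim_branch_width %||% 8L
    sam_dim <- sam_dim %||% 16L
    tail_widths <- tail_widths %||% c(64L, 32L)
    cbam_r <- if (missing(cbam_r)) 8L else cbam_r
  }
  mhsa_dim <- mhsa_dim %||% body_channels
  stop_field(dropout_p >= 0 && dropout_p < 1, "dropout_p", "must be in [0,1)")
  stop_field(num_classes >= 2, "num_classes", "must be >= 2")
  enabled_branches <- match.arg(enabled_branches, c("cbam", "mhsam", "sam"),
                                several.ok = TRUE)
  stop_field(length(enabled_branches) >= 1, "enabled_branches", "must be nonempty")
  stop_field(mhsa_dim %% mhsa_heads == 0, "mhsa_dim", "must be divisible by mhsa_heads")
  stop_field(body_channels %/% cbam_r >= 1, "cbam_r", "floor(body_channels/cbam_r) must be >= 1")
  structure(list(preset = preset, in_channels = as.integer(in_channels),
                 head_widths = as.integer(head_widths),
                 head_strides = as.integer(head_strides),
                 body_channels = as.integer(body_channels),
                 eim_branch_width = as.integer(eim_branch_width),
                 body_pool = isTRUE(body_pool),
                 cbam_r = as.integer(cbam_r), cbam_kernel = as.integer(cbam_kernel),
                 mhsa_heads = as.integer(mhsa_heads), mhsa_dim = as.integer(mhsa_dim),
                 sam_slots = as.integer(sam_slots), sam_dim = as.integer(sam_dim),
                 sam_iters = as.integer(sam_iters), sam_grid = as.integer(sam_grid),
                 sam_mode = sam_mode,
                 tail_widths = as.integer(tail_widths), dropout_p = dropout_p,
                 num_classes = as.integer(num_classes),
                 enabled_branches = enabled_branches),
            class = "lssnet_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an ablation variant of a configuration
#'
#' Implements the two ablation designs: the minus-one design removes one
#' attention branch from the full model (`drop`), the only-one design keeps a
#' single branch (`keep_only`). All other settings are unchanged.
#'
#' @param cfg an `lssnet_config`.
#' @param drop branch name to remove.
#' @param keep_only branch name to retain alone.
#' @return a modified `lssnet_config`.
#' @export
build_ablation_variant <- function(cfg, drop = NULL, keep_only = NULL) {
  stopifnot(inherits(cfg, "lssnet_config"))
  if (!is.null(drop) && !is.null(keep_only))
    stop("give either `drop` or `keep_only`, not both", call. = FALSE)
  if (!is.null(drop)) {
    drop <- match.arg(drop, c("cbam", "mhsam", "sam"))
    keep <- setdiff(cfg$enabled_branches, drop)
    if (length(keep) == 0)
      stop("cannot drop the only enabled branch", call. = FALSE)
    cfg$enabled_branches <- keep
  } else if (!is.null(keep_only)) {
    keep_only <- match.arg(keep_only, c("cbam", "mhsam", "sam"))
    cfg$enabled_branches <- keep_only
  }
  cfg
}

# Width of the concatenated branch-summary vector entering the tail.
tail_input_width <- function(cfg) {
  sum(c(cbam = cfg$body_channels, mhsam = cfg$body_channels,
        sam = cfg$sam_dim)[cfg$enabled_branches])
}

init_eim <- function(in_c, branch_w, out_c) {
  list(dsc1 = list(dw = init_depthwise(in_c, 1L), pw = init_conv(in_c, branch_w, 1L)),
       dsc3 = list(dw = init_depthwise(in_c, 3L), pw = init_conv(in_c, branch_w, 1L)),
       dsc5 = list(dw = init_depthwise(in_c, 5L), pw = init_conv(in_c, branch_w, 1L)),
       fuse = init_conv(3L * branch_w + in_c, out_c, 1L),
       bn = init_bn(out_c))
}

#' Initialize the network
#'
#' Draws all learnable parameters (He/Xavier initialization) from the current
#' RNG stream, and creates the batch-norm running-statistics state.
#'
#' @param cfg an `lssnet_config`.
#' @param seed optional integer; if given, initialization is performed under
#'   this seed without disturbing the caller's RNG.
#' @return an object of class `lssnet_model` with elements `cfg`, `params`,
#'   `state`.
#' @export
init_network <- function(cfg, seed = NULL) {
  build <- function() {
    hw <- cfg$head_widths
    bc <- cfg$body_channels
    params <- list(
      head = list(conv1 = init_conv(cfg$in_channels, hw[1], 7L),
                  bn1 = init_bn(hw[1]),
                  conv2 = init_conv(hw[1], hw[2], 3L),
                  bn2 = init_bn(hw[2]),
                  eim1 = init_eim(hw[2], cfg$eim_branch_width, bc),
                  eim2 = init_eim(bc, cfg$eim_branch_width, bc)))
    if ("cbam" %in% cfg$enabled_branches)
      params$cbam <- cbam_init(bc, cfg$cbam_r, cfg$cbam_kernel)[c("channel", "spatial")]
    if ("mhsam" %in% cfg$enabled_branches)
      params$mhsa <- mhsa_init(bc, cfg$mhsa_dim, cfg$mhsa_heads)
    if ("sam" %in% cfg$enabled_branches)
      params$sam <- slot_init(bc, cfg$sam_dim)
    fin <- tail_input_width(cfg)
    tw <- cfg$tail_widths
    params$tail <- list(fc1 = init_dense(fin, tw[1]),
                        ln = init_ln(tw[1]),
                        fc2 = init_dense(tw[1], tw[2]),
                        fc3 = init_dense(tw[2], cfg$num_classes))
    params$tail$fc2$b[] <- 0.01  # keep the post-LN ReLU stack alive at init
    state <- list(bn1 = list(mean = numeric(hw[1]), var = rep(1, hw[1])),
                  bn2 = list(mean = numeric(hw[2]), var = rep(1, hw[2])),
                  eim1 = list(mean = numeric(bc), var = rep(1, bc)),
                  eim2 = list(mean = numeric(bc), var = rep(1, bc)))
    structure(list(cfg = cfg, params = params, state = state), class = "lssnet_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Depthwise-separable convolution
#'
#' A depthwise `k x k` convolution (one filter per input channel, same
#' padding) followed by a pointwise 1x1 convolution mixing channels, as used
#' by the Enhanced Inception Module branches.
#'
#' @param x numeric array of dim `N x C x H x W`.
#' @param weights list with `dw` (from `init_depthwise`) and `pw`
#'   (from `init_conv(C, out_c, 1)`); use [dsc_init()].
#' @param k depthwise kernel size (odd).
#' @return array `N x out_c x H x W`.
#' @export
depthwise_separable_conv <- function(x, weights, k) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  r <- dsc_fwd(X, d[3], d[4], d[1], weights, k)
  mat_to_nchw(r$out, nrow(r$out), d[3], d[4], d[1])
}

#' Initialize depthwise-separable convolution weights
#' @param in_c,out_c input and output channel counts.
#' @param k depthwise kernel size.
#' @return list with `dw`, `pw`.
#' @export
dsc_init <- function(in_c, out_c, k) {
  list(dw = init_depthwise(in_c, k), pw = init_conv(in_c, out_c, 1L))
}

#' Parameter count of a depthwise-separable convolution
#'
#' `k^2 * in_c + in_c * out_c` weights plus `in_c + out_c` biases — compare
#' `k^2 * in_c * out_c + out_c` for a standard convolution.
#'
#' @inheritParams dsc_init
#' @param bias include bias terms in the count.
#' @return integer parameter count.
#' @export
dsc_param_count <- function(in_c, out_c, k, bias = TRUE) {
  n <- k^2 * in_c + in_c * out_c
  if (bias) n <- n + in_c + out_c
  as.integer(n)
}

dsc_fwd <- function(X, H, W, N, p, k) {
  dw <- depthwise_fwd(X, H, W, N, p$dw, k)
  pw <- conv_fwd(dw$out, H, W, N, p$pw, 1L, 1L, 0L)
  list(out = pw$out, cache = list(dw = dw$cache, pw = pw$cache, k = k))
}

dsc_bwd <- function(dout, cache, p) {
  pb <- conv_bwd(dout, cache$pw, p$pw)
  db <- depthwise_bwd(pb$dx, cache$dw, p$dw)
  list(dx = db$dx, grads = list(dw = db$grads, pw = pb$grads))
}

eim_fwd <- function(X, H, W, N, p, state, train) {
  b1 <- dsc_fwd(X, H, W, N, p$dsc1, 1L)
  b3 <- dsc_fwd(X, H, W, N, p$dsc3, 3L)
  b5 <- dsc_fwd(X, H, W, N, p$dsc5, 5L)
  mp <- maxpool_fwd(X, H, W, N, 3L, 1L, 1L)
  cat4 <- rbind(b1$out, b3$out, b5$out, mp$out)
  fu <- conv_fwd(cat4, H, W, N, p$fuse, 1L, 1L, 0L)
  bn <- bn_fwd(fu$out, p$bn, state, train)
  rl <- relu_fwd(bn$out)
  widths <- c(nrow(b1$out), nrow(b3$out), nrow(b5$out), nrow(mp$out))
  list(out = rl$out, state = bn$state,
       cache = list(b1 = b1$cache, b3 = b3$cache, b5 = b5$cache, mp = mp$cache,
                    fuse = fu$cache, bn = bn$cache, relu = rl$cache,
                    widths = widths))
}

eim_bwd <- function(dout, cache, p) {
  d <- relu_bwd(dout, cache$relu)
  bn <- bn_bwd(d, cache$bn)
  fu <- conv_bwd(bn$dx, cache$fuse, p$fuse)
  w <- cache$widths
  o <- cumsum(c(0, w))
  d1 <- fu$dx[(o[1] + 1):o[2], , drop = FALSE]
  d3 <- fu$dx[(o[2] + 1):o[3], , drop = FALSE]
  d5 <- fu$dx[(o[3] + 1):o[4], , drop = FALSE]
  dm <- fu$dx[(o[4] + 1):o[5], , drop = FALSE]
  r1 <- dsc_bwd(d1, cache$b1, p$dsc1)
  r3 <- dsc_bwd(d3, cache$b3, p$dsc3)
  r5 <- dsc_bwd(d5, cache$b5, p$dsc5)
  dmp <- maxpool_bwd(dm, cache$mp)
  list(dx = r1$dx + r3$dx + r5$dx + dmp,
       grads = list(dsc1 = r1$grads, dsc3 = r3$grads, dsc5 = r5$grads,
                    fuse = fu$grads, bn = bn$grads))
}

#' Enhanced Inception Module
#'
#' Four parallel branches — depthwise-separable convolutions with 1x1, 3x3
#' and 5x5 kernels plus a 3x3 stride-1 max-pool — concatenated along channels
#' and fused by a 1x1 convolution, batch normalization and ReLU.
#'
#' @param x numeric array of dim `N x C x H x W`.
#' @param weights from `init_eim` (via [init_network()]) — or build standalone
#'   with `lssnet:::init_eim(C, branch_w, out_c)`.
#' @param train use batch statistics (`TRUE`) or running statistics.
#' @return array `N x out_c x H x W`.
#' @export
enhanced_inception <- function(x, weights, train = TRUE) {
  d <- dim(x)
  X <- nchw_to_mat(x)
  out_c <- length(weights$bn$gamma)
  st <- list(mean = numeric(out_c), var = rep(1, out_c))
  r <- eim_fwd(X, d[3], d[4], d[1], weights, st, train)
  mat_to_nchw(r$out, out_c, d[3], d[4], d[1])
}

# Full forward pass. X: in_channels x (H*W*N) matrix. Returns logits,
# probabilities, per-stage caches and the updated BN state.
network_fwd <- function(model, X, H, W, N, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  st <- model$state
  if (H < 8 || W < 8)
    stop("input too small for the head striding (stage: head conv 7x7, need >= 8 px)",
         call. = FALSE)
  cv1 <- conv_fwd(X, H, W, N, p$head$conv1, 7L, cfg$head_strides[1], 3L)
  bn1 <- bn_fwd(cv1$out, p$head$bn1, st$bn1, train)
  r1 <- relu_fwd(bn1$out)
  H1 <- cv1$Ho; W1 <- cv1$Wo
  cv2 <- conv_fwd(r1$out, H1, W1, N, p$head$conv2, 3L, cfg$head_strides[2], 1L)
  bn2 <- bn_fwd(cv2$out, p$head$bn2, st$bn2, train)
  r2 <- relu_fwd(bn2$out)
  H2 <- cv2$Ho; W2 <- cv2$Wo
  mp <- maxpool_fwd(r2$out, H2, W2, N, 3L, 2L, 1L)
  H3 <- mp$Ho; W3 <- mp$Wo
  if (H3 < 1 || W3 < 1)
    stop("input too small for the head striding (stage: head max-pool)", call. = FALSE)
  e1 <- eim_fwd(mp$out, H3, W3, N, p$head$eim1, st$eim1, train)
  e2 <- eim_fwd(e1$out, H3, W3, N, p$head$eim2, st$eim2, train)
  if (cfg$body_pool) {
    bp <- maxpool_fwd(e2$out, H3, W3, N, 3L, 2L, 1L)
    Xb <- bp$out; Hb <- bp$Ho; Wb <- bp$Wo
  } else {
    bp <- NULL; Xb <- e2$out; Hb <- H3; Wb <- W3
  }
  Tb <- Hb * Wb
  summaries <- list()
  caches <- list()
  if ("cbam" %in% cfg$enabled_branches) {
    cb <- cbam_fwd(Xb, Hb, Wb, N, p$cbam)
    g <- gap_fwd(cb$out, Tb, N)
    summaries$cbam <- g$out
    caches$cbam <- list(block = cb$cache, gap = g$cache)
  }
  if ("mhsam" %in% cfg$enabled_branches) {
    mh <- mhsa_fwd(Xb, Tb, N, p$mhsa)
    g <- gap_fwd(mh$out, Tb, N)
    summaries$mhsam <- g$out
    caches$mhsam <- list(block = mh$cache, gap = g$cache)
  }
  if ("sam" %in% cfg$enabled_branches) {
    sl <- slot_fwd(Xb, Hb, Wb, N, p$sam, cfg$sam_slots, cfg$sam_iters,
                   cfg$sam_mode, cfg$sam_grid, train)
    summaries$sam <- sl$out
    caches$sam <- sl$cache
  }
  feat <- do.call(rbind, summaries[cfg$enabled_branches])
  f1 <- dense_fwd(feat, p$tail$fc1)
  l1 <- ln_fwd(f1$out, p$tail$ln)
  t1 <- relu_fwd(l1$out)
  d1 <- dropout_fwd(t1$out, cfg$dropout_p, train)
  f2 <- dense_fwd(d1$out, p$tail$fc2)
  t2 <- relu_fwd(f2$out)
  d2 <- dropout_fwd(t2$out, cfg$dropout_p, train)
  f3 <- dense_fwd(d2$out, p$tail$fc3)
  probs <- softmax_cols(f3$out)
  state <- list(bn1 = bn1$state, bn2 = bn2$state, eim1 = e1$state, eim2 = e2$state)
  list(logits = f3$out, probs = probs, state = state,
       cache = list(cv1 = cv1$cache, bn1 = bn1$cache, r1 = r1$cache,
                    cv2 = cv2$cache, bn2 = bn2$cache, r2 = r2$cache,
                    mp = mp$cache, e1 = e1$cache, e2 = e2$cache,
                    bp = if (is.null(bp)) NULL else bp$cache,
                    Hb = Hb, Wb = Wb, N = N,
                    branches = caches,
                    feat = f1$cache, f1 = f1, l1 = l1$cache, t1 = t1$cache,
                    d1 = d1$cache, f2c = f2$cache, t2 = t2$cache, d2 = d2$cache,
                    f3c = f3$cache))
}

# Backward pass from dlogits; returns gradients paralleling model$params.
network_bwd <- function(model, dlogits, cache) {
  cfg <- model$cfg
  p <- model$params
  f3 <- dense_bwd(dlogits, cache$f3c, p$tail$fc3)
  d <- dropout_bwd(f3$dx, cache$d2)
  d <- relu_bwd(d, cache$t2)
  f2 <- dense_bwd(d, cache$f2c, p$tail$fc2)
  d <- dropout_bwd(f2$dx, cache$d1)
  d <- relu_bwd(d, cache$t1)
  l1 <- ln_bwd(d, cache$l1)
  f1 <- dense_bwd(l1$dx, cache$feat, p$tail$fc1)
  grads <- list(tail = list(fc1 = f1$grads, ln = l1$grads, fc2 = f2$grads, fc3 = f3$grads))
  # split the concatenated branch summaries
  widths <- c(cbam = cfg$body_channels, mhsam = cfg$body_channels, sam = cfg$sam_dim)
  widths <- widths[cfg$enabled_branches]
  o <- cumsum(c(0, widths))
  dfeat <- f1$dx
  Hb <- cache$Hb; Wb <- cache$Wb; N <- cache$N
  Tb <- Hb * Wb
  dXb <- 0
  for (i in seq_along(cfg$enabled_branches)) {
    br <- cfg$enabled_branches[i]
    dsum <- dfeat[(o[i] + 1):o[i + 1], , drop = FALSE]
    if (br == "cbam") {
      dg <- gap_bwd(dsum, cache$branches$cbam$gap)
      bb <- cbam_bwd(dg, cache$branches$cbam$block, p$cbam)
      grads$cbam <- bb$grads
      dXb <- dXb + bb$dx
    } else if (br == "mhsam") {
      dg <- gap_bwd(dsum, cache$branches$mhsam$gap)
      bb <- mhsa_bwd(dg, cache$branches$mhsam$block, p$mhsa)
      grads$mhsa <- bb$grads
      dXb <- dXb + bb$dx
    } else {
      bb <- slot_bwd(dsum, cache$branches$sam, p$sam)
      grads$sam <- bb$grads
      dXb <- dXb + bb$dx
    }
  }
  if (!is.null(cache$bp)) dXb <- maxpool_bwd(dXb, cache$bp)
  e2 <- eim_bwd(dXb, cache$e2, p$head$eim2)
  e1 <- eim_bwd(e2$dx, cache$e1, p$head$eim1)
  d <- maxpool_bwd(e1$dx, cache$mp)
  d <- relu_bwd(d, cache$r2)
  bn2 <- bn_bwd(d, cache$bn2)
  cv2 <- conv_bwd(bn2$dx, cache$cv2, p$head$conv2)
  d <- relu_bwd(cv2$dx, cache$r1)
  bn1 <- bn_bwd(d, cache$bn1)
  cv1 <- conv_bwd(bn1$dx, cache$cv1, p$head$conv1)
  grads$head <- list(conv1 = cv1$grads, bn1 = bn1$grads,
                     conv2 = cv2$grads, bn2 = bn2$grads,
                     eim1 = e1$grads, eim2 = e2$grads)
  grads[names(model$params)]
}

#' Classify a batch of images
#'
#' Runs the forward pass in eval mode (running batch-norm statistics, no
#' dropout, deterministic slot initialization) and returns class
#' probabilities and hard predictions.
#'
#' @param model an `lssnet_model`.
#' @param images numeric array `N x H x W` (single channel) or
#'   `N x C x H x W`.
#' @return list with `probabilities` (`N x num_classes`, rows sum to 1) and
#'   `predicted_class` (0-based class indices, matching the "0 = normal/mild,
#'   1 = severe" label convention).
#' @export
predict_network <- function(model, images) {
  d <- dim(images)
  if (length(d) == 3) dim(images) <- c(d[1], 1L, d[2], d[3])
  d <- dim(images)
  X <- nchw_to_mat(images)
  r <- network_fwd(model, X, d[3], d[4], d[1], train = FALSE)
  probs <- t(r$probs)
  list(probabilities = probs,
       predicted_class = max.col(probs, ties.method = "first") - 1L)
}

#' Count learnable parameters
#' @param model an `lssnet_model`.
#' @return total number of scalar learnable parameters.
#' @export
count_parameters <- function(model) {
  leaves <- param_flatten(model$params)
  num <- vapply(leaves, is.numeric, logical(1))
  sum(vapply(leaves[num], length, integer(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, parameters, batch-norm state and
#' (optionally) training history, so ablation variants are self-describing.
#'
#' @param model an `lssnet_model`.
#' @param path file path.
#' @param extra optional list stored alongside (e.g. training log).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model with attribute `"extra"`.
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(model = model, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(obj$model, extra = obj$extra)
}
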