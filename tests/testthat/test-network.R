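test_that("depthwise-separable parameter count beats a standard convolution", {
  for (k in c(3, 5)) for (in_c in c(4, 16)) for (out_c in c(8, 32)) {
    dsc <- dsc_param_count(in_c, out_c, k, bias = FALSE)
    std <- k^2 * in_c * out_c
    expect_equal(dsc, k^2 * in_c + in_c * out_c)
    expect_lt(dsc, std)
  }
  # and the weight containers agree with the formula
  w <- dsc_init(4, 8, 3)
  expect_equal(length(w$dw$W) + length(w$pw$W) + length(w$dw$b) + length(w$pw$b),
               dsc_param_count(4, 8, 3))
})

test_that("k = 1 depthwise-separable conv equals two chained 1x1 convolutions", {
  set.seed(30)
  w <- dsc_init(3, 5, 1)
  x <- array(rnorm(2 * 3 * 4 * 4), dim = c(2, 3, 4, 4))
  got <- depthwise_separable_conv(x, w, k = 1)
  for (n in 1:2) for (h in 1:4) for (wd in 1:4) {
    v <- x[n, , h, wd] * w$dw$W[1, ] + w$dw$b        # depthwise 1x1 = per-channel scaling
    expect_equal(as.numeric(got[n, , h, wd]),
                 as.numeric(w$pw$W %*% v + w$pw$b), tolerance = 1e-9)
  }
  wz <- dsc_init(3, 5, 3)
  wz$dw$W[] <- 0; wz$dw$b[] <- 0; wz$pw$W[] <- 0; wz$pw$b[] <- 0
  expect_true(all(depthwise_separable_conv(x, wz, k = 3) == 0))
})

test_that("standard convolution path matches the scalar-loop oracle", {
  set.seed(31)
  ns <- asNamespace("lssnet")
  C <- 3; H <- 5; W <- 4; k <- 3
  p <- ns$init_conv(C, 2, k)
  xarr <- array(rnorm(C * H * W), dim = c(C, H, W))
  X <- ns$nchw_to_mat(array(xarr, dim = c(1, C, H, W)))
  got <- ns$conv_fwd(X, H, W, 1L, p, k, 1L)$out
  ref <- oracle_conv2d(xarr, p$W, p$b, k)
  expect_equal(ns$mat_to_nchw(got, 2, H, W, 1)[1, , , ], ref, tolerance = 1e-9)
})

test_that("max pooling matches a windowed oracle and routes gradients to argmax", {
  set.seed(32)
  ns <- asNamespace("lssnet")
  H <- 6; W <- 6
  x <- matrix(rnorm(H * W), 1)
  r <- ns$maxpool_fwd(x, H, W, 1L, k = 3L, stride = 2L, pad = 1L)
  img <- matrix(as.numeric(x), H, W)
  for (ho in 1:r$Ho) for (wo in 1:r$Wo) {
    hs <- max(1, 2 * ho - 2):min(H, 2 * ho)
    ws <- max(1, 2 * wo - 2):min(W, 2 * wo)
    expect_equal(r$out[1, (wo - 1) * r$Ho + ho], max(img[hs, ws]))
  }
  d <- matrix(1, 1, ncol(r$out))
  dx <- ns$maxpool_bwd(d, r$cache)
  expect_equal(sum(dx), ncol(r$out))          # each output routes one unit
  expect_true(all(dx[x != max(x)] >= 0))
})

test_that("enhanced inception preserves spatial size, sets channels, stays nonnegative", {
  set.seed(33)
  ns <- asNamespace("lssnet")
  w <- ns$init_eim(4L, 3L, 10L)
  x <- array(rnorm(2 * 4 * 6 * 6), dim = c(2, 4, 6, 6))
  out <- enhanced_inception(x, w)
  expect_equal(dim(out), c(2L, 10L, 6L, 6L))
  expect_true(all(out >= 0))
})

test_that("every ablation variant maps a 224x224 image to a 2-class simplex point", {
  set.seed(34)
  img <- array(rnorm(1 * 224 * 224, sd = 40), dim = c(1, 224, 224))
  base <- tiny_net()
  variants <- list(base)
  for (br in c("cbam", "mhsam", "sam")) {
    variants <- c(variants, list(build_ablation_variant(base, drop = br),
                                 build_ablation_variant(base, keep_only = br)))
  }
  for (cfg in variants) {
    model <- init_network(cfg, seed = 1)
    pr <- predict_network(model, img)
    expect_equal(dim(pr$probabilities), c(1L, 2L))
    expect_equal(sum(pr$probabilities), 1, tolerance = 1e-6)
    expect_true(all(pr$probabilities >= 0))
    expect_true(pr$predicted_class %in% c(0L, 1L))
  }
})

test_that("eval mode is deterministic and independent of batch composition", {
  set.seed(35)
  model <- init_network(tiny_net(), seed = 2)
  imgs <- array(rnorm(3 * 64 * 64, sd = 30), dim = c(3, 64, 64))
  a <- predict_network(model, imgs)
  b <- predict_network(model, imgs)
  expect_identical(a$probabilities, b$probabilities)
  solo <- predict_network(model, imgs[1, , , drop = FALSE])
  expect_equal(solo$probabilities[1, ], a$probabilities[1, ], tolerance = 1e-5)
})

test_that("dropout and slot noise act in train mode only", {
  ns <- asNamespace("lssnet")
  model <- init_network(tiny_net(), seed = 3)
  set.seed(36)
  X <- matrix(rnorm(64 * 64), 1)
  set.seed(1); a <- ns$network_fwd(model, X, 64L, 64L, 1L, train = TRUE)$probs
  set.seed(2); b <- ns$network_fwd(model, X, 64L, 64L, 1L, train = TRUE)$probs
  expect_false(identical(a, b))
  e1 <- ns$network_fwd(model, X, 64L, 64L, 1L, train = FALSE)$probs
  e2 <- ns$network_fwd(model, X, 64L, 64L, 1L, train = FALSE)$probs
  expect_identical(e1, e2)
})

test_that("ablation variants edit enabled branches and tail width bookkeeping holds", {
  cfg <- network_config("desk")
  m_full <- init_network(cfg, seed = 1)
  expect_setequal(build_ablation_variant(cfg, drop = "cbam")$enabled_branches,
                  c("mhsam", "sam"))
  expect_equal(build_ablation_variant(cfg, keep_only = "mhsam")$enabled_branches,
               "mhsam")
  # drop then restore reproduces the original branch set
  dropped <- build_ablation_variant(cfg, drop = "sam")
  restored <- dropped
  restored$enabled_branches <- c(restored$enabled_branches, "sam")
  expect_setequal(restored$enabled_branches, cfg$enabled_branches)
  expect_error(build_ablation_variant(
    build_ablation_variant(cfg, keep_only = "sam"), drop = "sam"), "only enabled")
  # first tail layer shrinks by exactly the removed branch's summary width
  m_drop <- init_network(build_ablation_variant(cfg, drop = "cbam"), seed = 1)
  expect_equal(ncol(m_full$params$tail$fc1$W) - ncol(m_drop$params$tail$fc1$W),
               cfg$body_channels)
  m_sam <- init_network(build_ablation_variant(cfg, drop = "sam"), seed = 1)
  expect_equal(ncol(m_full$params$tail$fc1$W) - ncol(m_sam$params$tail$fc1$W),
               cfg$sam_dim)
})

test_that("inputs too small for the head striding fail with a stage-naming error", {
  model <- init_network(tiny_net(), seed = 4)
  expect_error(predict_network(model, array(1, dim = c(1, 2, 2))), "head")
})

test_that("checkpoints round-trip the model and its configuration", {
  model <- init_network(tiny_net(), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(note = "unit"))
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  expect_equal(back$cfg, model$cfg)
  expect_equal(attr(back, "extra")$note, "unit")
  set.seed(37)
  img <- array(rnorm(64 * 64, sd = 20), dim = c(1, 64, 64))
  expect_identical(predict_network(model, img)$probabilities,
                   predict_network(back, img)$probabilities)
  unlink(path)
})

test_that("analytic gradients match central finite differences on a tiny model", {
  ns <- asNamespace("lssnet")
  cfg <- network_config(preset = "desk", head_widths = c(3L, 4L), body_channels = 6L,
                        eim_branch_width = 2L, cbam_r = 2L, mhsa_heads = 2L,
                        mhsa_dim = 4L, sam_slots = 2L, sam_dim = 3L, sam_iters = 2L,
                        sam_grid = 2L, tail_widths = c(5L, 4L), dropout_p = 0)
  model <- init_network(cfg, seed = 1)
  set.seed(40)
  H <- W <- 32L; N <- 2L
  X <- matrix(rnorm(H * W * N), 1)
  y <- c(1L, 2L)
  loss_at <- function(m) {
    set.seed(123)
    r <- ns$network_fwd(m, X, H, W, N, train = TRUE)
    ns$softmax_ce(r$logits, y)$loss
  }
  set.seed(123)
  fwd <- ns$network_fwd(model, X, H, W, N, train = TRUE)
  ce <- ns$softmax_ce(fwd$logits, y)
  grads <- ns$network_bwd(model, ce$dlogits, fwd$cache)
  flat_g <- ns$param_flatten(grads)
  flat_p <- ns$param_flatten(model$params)
  set.seed(41)
  checked <- 0
  for (nm in names(flat_g)) {
    g <- flat_g[[nm]]
    if (!is.numeric(g) || length(g) == 0) next
    i <- sample.int(length(g), 1)
    p0 <- flat_p[[nm]][i]
    eps <- 1e-5 * max(1, abs(p0))
    poke <- function(val) {
      m2 <- model
      path <- strsplit(nm, "/")[[1]]
      leaf <- m2$params
      for (k in path) leaf <- leaf[[k]]
      leaf[i] <- val
      expr <- paste0("m2$params", paste0("[['", path, "']]", collapse = ""))
      eval(parse(text = paste0(expr, " <- leaf")))
      m2
    }
    fd <- (loss_at(poke(p0 + eps)) - loss_at(poke(p0 - eps))) / (2 * eps)
    denom <- max(abs(fd) + abs(g[i]), 1e-4)
    expect_lt(abs(fd - g[i]) / denom, 1e-3, label = sprintf("gradient of %s", nm))
    checked <- checked + 1
  }
  expect_gt(checked, 30)  # every parameter tensor was exercised
})

test_that("every learnable parameter receives gradient on a generic batch", {
  ns <- asNamespace("lssnet")
  model <- init_network(tiny_net(dropout_p = 0), seed = 6)
  set.seed(42)
  X <- matrix(rnorm(64 * 64 * 3), 1)
  set.seed(7)
  fwd <- ns$network_fwd(model, X, 64L, 64L, 3L, train = TRUE)
  ce <- ns$softmax_ce(fwd$logits, c(1L, 2L, 1L))
  grads <- ns$network_bwd(model, ce$dlogits, fwd$cache)
  for (leaf in ns$param_flatten(grads)) {
    if (is.numeric(leaf)) expect_gt(max(abs(leaf)), 0)
  }
})
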