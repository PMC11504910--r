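test_that("channel attention matches the scalar-loop oracle", {
  set.seed(10)
  w <- cbam_init(C = 4, r = 2, kernel = 3)
  x <- array(rnorm(1 * 4 * 2 * 2), dim = c(1, 4, 2, 2))
  got <- channel_attention(x, w)
  ref <- oracle_channel_attention(x[1, , , ], w$channel)
  expect_equal(got$out[1, , , ], ref$out, tolerance = 1e-6)
  expect_equal(as.numeric(got$M_c), ref$gate, tolerance = 1e-6)
})

test_that("channel attention gates lie strictly in (0,1) and fix zero inputs", {
  set.seed(11)
  w <- cbam_init(C = 6, r = 3, kernel = 3)
  x <- array(rnorm(2 * 6 * 3 * 3), dim = c(2, 6, 3, 3))
  got <- channel_attention(x, w)
  expect_true(all(got$M_c > 0 & got$M_c < 1))
  z <- channel_attention(array(0, dim = c(1, 6, 3, 3)), w)
  expect_true(all(z$out == 0))
})

test_that("channel attention rejects an excessive reduction ratio", {
  expect_error(cbam_init(C = 4, r = 8), "reduction ratio")
})

test_that("spatial attention matches the scalar-loop convolution oracle", {
  set.seed(12)
  w <- cbam_init(C = 3, r = 1, kernel = 3)
  x <- array(rnorm(1 * 3 * 4 * 4), dim = c(1, 3, 4, 4))
  got <- spatial_attention(x, w)
  ref <- oracle_spatial_attention(x[1, , , ], w$spatial)
  expect_equal(got$out[1, , , ], ref$out, tolerance = 1e-6)
})

test_that("spatial attention is constant on spatially constant maps and contracts", {
  set.seed(13)
  w <- cbam_init(C = 5, r = 1, kernel = 3)
  x <- array(0, dim = c(1, 5, 6, 6))
  vals <- rnorm(5)
  for (c in 1:5) x[1, c, , ] <- vals[c]
  got <- spatial_attention(x, w)
  # interior pixels see identical 3x3 neighborhoods (borders feel the
  # zero padding of the gate convolution)
  Ms <- matrix(as.numeric(got$M_s), 6, 6)
  expect_lt(diff(range(Ms[2:5, 2:5])), 1e-12)
  set.seed(14)
  y <- array(rnorm(2 * 5 * 4 * 4), dim = c(2, 5, 4, 4))
  gy <- spatial_attention(y, w)
  expect_true(all(abs(gy$out) <= abs(y)))
})

test_that("cbam equals its two stages applied in sequence and contracts magnitudes", {
  set.seed(15)
  w <- cbam_init(C = 4, r = 2, kernel = 3)
  x <- array(rnorm(2 * 4 * 3 * 3), dim = c(2, 4, 3, 3))
  whole <- cbam(x, w)
  staged <- spatial_attention(channel_attention(x, w)$out, w)
  expect_identical(whole$out, staged$out)
  expect_true(all(abs(whole$out) <= abs(x)))
  expect_true(all(cbam(array(0, dim = dim(x)), w)$out == 0))
})

test_that("multi-head self-attention matches the triple-loop oracle", {
  set.seed(16)
  w <- mhsa_init(C = 8, d = 8, heads = 2)
  x <- array(rnorm(2 * 8 * 2 * 2), dim = c(2, 8, 2, 2))
  got <- mhsa(x, w)
  for (n in 1:2) {
    ref <- oracle_mhsa(x[n, , , ], w)
    expect_equal(got$out[n, , , ], ref, tolerance = 1e-5)
  }
})

test_that("attention rows are stochastic and a single token attends to itself", {
  set.seed(17)
  w <- mhsa_init(C = 6, d = 6, heads = 3)
  x <- array(rnorm(2 * 6 * 3 * 2), dim = c(2, 6, 3, 2))
  got <- mhsa(x, w)
  for (img in got$attention) for (A in img) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  x1 <- array(rnorm(1 * 6 * 1 * 1), dim = c(1, 6, 1, 1))
  g1 <- mhsa(x1, w)
  for (A in g1$attention[[1]]) expect_equal(A, matrix(1, 1, 1))
  # single token: O = Wo (V) + bo with V = Wv x + bv, attention weight 1
  v <- as.numeric(w$Wv %*% x1[1, , 1, 1] + w$bv)
  expect_equal(as.numeric(g1$out[1, , 1, 1]),
               as.numeric(w$Wo %*% v + w$bo), tolerance = 1e-9)
})

test_that("embedding dimension must divide into heads", {
  expect_error(mhsa_init(C = 8, d = 6, heads = 4), "divisible")
  expect_error(network_config(mhsa_dim = 6L, mhsa_heads = 4L), "mhsa_dim")
})

test_that("slot attention with one literal-mode iteration matches the unrolled oracle", {
  set.seed(18)
  w <- slot_init(C = 5, dim = 3)
  x <- array(rnorm(1 * 5 * 2 * 2), dim = c(1, 5, 2, 2))
  got <- slot_attention(x, w, num_slots = 2, iters = 1, mode = "literal",
                        train = FALSE)
  ref <- oracle_slot_one_iter(x[1, , , ], w, num_slots = 2)
  expect_equal(as.numeric(got$out), ref, tolerance = 1e-6)
})

test_that("slot-token attention normalizes over the slot axis", {
  set.seed(19)
  w <- slot_init(C = 4, dim = 5)
  x <- array(rnorm(2 * 4 * 6 * 6), dim = c(2, 4, 6, 6))
  got <- slot_attention(x, w, num_slots = 3, iters = 2, token_grid = 3)
  for (A in got$A) {
    expect_equal(dim(A), c(3L, 9L))
    expect_equal(colSums(A), rep(1, 9), tolerance = 1e-6)
  }
})

test_that("zero iterations return the mean initial slot, deterministically", {
  set.seed(20)
  w <- slot_init(C = 4, dim = 4)
  x <- array(rnorm(1 * 4 * 3 * 3), dim = c(1, 4, 3, 3))
  got <- slot_attention(x, w, num_slots = 3, iters = 0)
  expect_equal(as.numeric(got$out), w$mu, tolerance = 1e-12)
})

test_that("slot attention with sigma forced to zero ignores the RNG entirely", {
  set.seed(21)
  w <- slot_init(C = 4, dim = 4)
  w$sigma_raw[] <- -Inf    # softplus(-Inf) = 0 exactly
  x <- array(rnorm(1 * 4 * 4 * 4), dim = c(1, 4, 4, 4))
  set.seed(1); a <- slot_attention(x, w, num_slots = 2, iters = 3, train = TRUE)
  set.seed(999); b <- slot_attention(x, w, num_slots = 2, iters = 3, train = TRUE)
  expect_identical(a$out, b$out)
})

test_that("all three blocks honor the shape contract across sizes", {
  set.seed(22)
  for (dims in list(c(1, 4, 1, 1), c(2, 4, 2, 3), c(1, 4, 5, 2))) {
    x <- array(rnorm(prod(dims)), dim = dims)
    wc <- cbam_init(4, r = 2, kernel = 3)
    expect_equal(dim(cbam(x, wc)$out), dims)
    wm <- mhsa_init(4, d = 4, heads = 2)
    expect_equal(dim(mhsa(x, wm)$out), dims)
    ws <- slot_init(4, dim = 3)
    expect_equal(dim(slot_attention(x, ws, num_slots = 2, iters = 1,
                                    token_grid = 2)$out), c(dims[1], 3L))
  }
})
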