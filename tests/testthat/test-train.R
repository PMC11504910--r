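test_that("stratified 80:20 split of the full dataset yields 6528/1632", {
  tab <- lss_condition_table()
  labels <- unlist(mapply(function(m, s) c(rep(0L, m), rep(1L, s)),
                          tab$n_mild, tab$n_severe, SIMPLIFY = FALSE))
  expect_length(labels, 8160)
  sp <- stratified_split(labels, split_ratio = 0.8, seed = 1)
  expect_equal(length(sp$train), 6528)
  expect_equal(length(sp$test), 1632)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # per-class proportions match within rounding
  for (cl in 0:1) {
    n_cl <- sum(labels == cl)
    expect_equal(sum(labels[sp$train] == cl) / n_cl, 0.8,
                 tolerance = 1 / n_cl + 1e-12)
  }
})

test_that("splits are seed-reproducible and fail on singleton classes", {
  labels <- c(rep(0, 30), rep(1, 10))
  a <- stratified_split(labels, 0.8, seed = 9)
  b <- stratified_split(labels, 0.8, seed = 9)
  expect_identical(a, b)
  c <- stratified_split(labels, 0.8, seed = 10)
  expect_false(identical(a$train, c$train))
  expect_error(stratified_split(c(0, 0, 0, 1), 0.8), "fewer than 2")
  expect_error(stratified_split(rep(0, 10), 0.8), "both classes")
})

test_that("early stopping halts after the patience budget, keeping the best epoch", {
  ns <- asNamespace("lssnet")
  r <- ns$early_stop_scan(c(1.0, 0.9, 0.9, 0.9, 0.9), patience = 3)
  expect_equal(r$best, 2)
  expect_equal(r$stopped_at, 5)
  # monotone improvement never stops
  r2 <- ns$early_stop_scan(c(5, 4, 3, 2, 1), patience = 2)
  expect_equal(r2$best, 5)
  expect_true(is.na(r2$stopped_at))
  # best epoch never follows the stopping epoch
  set.seed(60)
  for (i in 1:50) {
    v <- runif(sample(3:12, 1))
    r3 <- ns$early_stop_scan(v, patience = 2)
    expect_equal(v[r3$best], min(v[seq_len(if (is.na(r3$stopped_at)) length(v) else r3$stopped_at)]))
    if (!is.na(r3$stopped_at)) expect_lte(r3$best, r3$stopped_at)
  }
  # max mode tracks the largest value
  r4 <- ns$early_stop_scan(c(0.5, 0.8, 0.7, 0.7), patience = 5, mode = "max")
  expect_equal(r4$best, 2)
})

test_that("one Adam step matches the closed-form update", {
  ns <- asNamespace("lssnet")
  params <- list(w = c(1, 2))
  grads <- list(w = c(0.5, -0.2))
  st <- list(m = NULL, v = NULL, t = 0L)
  r <- ns$adam_step(params, grads, st, lr = 0.001)
  # t = 1: mhat = g, vhat = g^2  =>  step ~= lr * sign(g)
  expected <- c(1, 2) - 0.001 * grads$w / (abs(grads$w) + 1e-8)
  expect_equal(r$params$w, expected, tolerance = 1e-9)
  # second step with zero gradient decays the moment but moves less
  r2 <- ns$adam_step(r$params, list(w = c(0, 0)), r$state, lr = 0.001)
  expect_lt(max(abs(r2$params$w - r$params$w)), 0.001)
})

test_that("training is a deterministic function of the seed", {
  ph <- tiny_phantoms(n = 40, size = 64, frac = 0.3)
  cfg <- tiny_net()
  tcfg <- train_config(max_epochs = 2, batch_size = 16, seed = 21)
  pre <- preprocess_config(target_size = 64)
  f1 <- train_network(ph, cfg, tcfg, pre_cfg = pre)
  f2 <- train_network(ph, cfg, tcfg, pre_cfg = pre)
  expect_identical(f1$split, f2$split)
  expect_equal(f1$model$params, f2$model$params)
  expect_equal(f1$metrics$accuracy, f2$metrics$accuracy)
  expect_equal(f1$log, f2$log)
  f3 <- train_network(ph, cfg, train_config(max_epochs = 2, batch_size = 16,
                                            seed = 22), pre_cfg = pre)
  expect_false(identical(f1$model$params, f3$model$params))
})

test_that("the fit records a usable log, split and test metrics", {
  ph <- tiny_phantoms(n = 40, size = 64, frac = 0.3)
  fit <- train_network(ph, tiny_net(),
                       train_config(max_epochs = 3, batch_size = 16, seed = 2),
                       pre_cfg = preprocess_config(target_size = 64))
  expect_s3_class(fit, "lssnet_fit")
  expect_equal(nrow(fit$log), 3)
  expect_named(fit$log, c("epoch", "train_loss", "val_loss", "val_accuracy"))
  expect_true(all(is.finite(fit$log$train_loss)))
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  m <- fit$metrics
  expect_gte(m$accuracy, 0)
  expect_lte(m$accuracy, 1)
  expect_equal(m$confusion$TP + m$confusion$TN + m$confusion$FP + m$confusion$FN,
               length(fit$split$test))
  # evaluate_network on raw images reproduces the recorded test metrics
  ev <- evaluate_network(fit, ph$images[fit$split$test, , , drop = FALSE],
                         ph$labels[fit$split$test])
  expect_equal(ev$accuracy, m$accuracy)
  expect_equal(ev$auc, m$auc)
})

test_that("an optional inner validation split separates monitoring from testing", {
  ph <- tiny_phantoms(n = 60, size = 64, frac = 0.3)
  fit <- train_network(ph, tiny_net(),
                       train_config(max_epochs = 2, batch_size = 16,
                                    val_fraction = 0.2, seed = 4),
                       pre_cfg = preprocess_config(target_size = 64))
  expect_s3_class(fit, "lssnet_fit")
  expect_equal(nrow(fit$log), 2)
})

test_that("the ablation harness produces seven rows under one shared split", {
  ph <- tiny_phantoms(n = 40, size = 64, frac = 0.3)
  res <- run_ablation(ph, tiny_net(),
                      train_config(max_epochs = 1, batch_size = 16, seed = 11),
                      pre_cfg = preprocess_config(target_size = 64))
  expect_equal(nrow(res$table), 7)
  expect_setequal(res$table$variant,
                  c("full", "without_cbam", "only_cbam", "without_mhsam",
                    "only_mhsam", "without_sam", "only_sam"))
  for (fit in res$fits) expect_identical(fit$split, res$split)
  expect_equal(res$table$branches[res$table$variant == "without_cbam"],
               "mhsam+sam")
  dir <- file.path(tempdir(), "abl_out")
  res2 <- run_ablation(ph, tiny_net(),
                       train_config(max_epochs = 1, batch_size = 16, seed = 11),
                       out_dir = dir, pre_cfg = preprocess_config(target_size = 64))
  expect_true(file.exists(file.path(dir, "ablation.csv")))
  expect_true(file.exists(file.path(dir, "ablation.json")))
  expect_equal(read.csv(file.path(dir, "ablation.csv"))$variant, res2$table$variant)
  unlink(dir, recursive = TRUE)
})
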