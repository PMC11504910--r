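# Training loop (Adam, early stopping), stratified 80:20 split, evaluation,
# and the ablation harness over attention branches.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without improvement of the monitored quantity
#'   before early stopping.
#' @param split_ratio training fraction of the stratified split.
#' @param monitor `"val_loss"` (minimized) or `"val_accuracy"` (maximized).
#' @param augment apply stochastic augmentation to training batches.
#' @param val_fraction fraction of the *training* split held out as a
#'   separate validation set; 0 (default) monitors the test split directly —
#'   a faithful reproduction of a two-way protocol, at the cost of
#'   early-stopping leakage into the reported test metrics.
#' @param seed master seed: initialization, split, shuffling, augmentation,
#'   dropout and slot noise all derive from it.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 50L, patience = 10L,
                         split_ratio = 0.8, monitor = c("val_loss", "val_accuracy"),
                         augment = TRUE, val_fraction = 0, seed = 1L) {
  stop_field(learning_rate > 0, "learning_rate", "must be > 0")
  stop_field(split_ratio > 0 && split_ratio < 1, "split_ratio", "must be in (0,1)")
  stop_field(patience >= 1, "patience", "must be >= 1")
  stop_field(val_fraction >= 0 && val_fraction < 1, "val_fraction", "must be in [0,1)")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 split_ratio = split_ratio, monitor = match.arg(monitor),
                 augment = isTRUE(augment), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Partitions indices per class at `split_ratio`, seeded, disjoint and
#' exhaustive, so rare severe cases appear in both partitions.
#'
#' @param labels 0/1 label vector (or a dataset list with `$labels`).
#' @param split_ratio training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, split_ratio = 0.8, seed = 1L) {
  if (is.list(labels)) labels <- labels$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes required for a stratified split", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < 2)
        stop(sprintf("class %s has fewer than 2 members", cl), call. = FALSE)
      n_tr <- round(length(idx) * split_ratio)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = sort(setdiff(seq_along(labels), train)))
  })
}

# Scan a monitored sequence; returns the best epoch and the epoch after
# which training stops (NA if the patience budget is never exhausted).
# mode "min": lower is better; improvement must be strict.
early_stop_scan <- function(values, patience, mode = c("min", "max")) {
  mode <- match.arg(mode)
  v <- if (mode == "max") -values else values
  best <- Inf
  best_epoch <- NA_integer_
  wait <- 0L
  for (i in seq_along(v)) {
    if (v[i] < best) {
      best <- v[i]
      best_epoch <- i
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(best = best_epoch, stopped_at = i))
    }
  }
  list(best = best_epoch, stopped_at = NA_integer_)
}

# One Adam update; state holds t and per-leaf first/second moments shaped
# like the gradient structure (created lazily on the first call). Leaves
# present in `grads` update the matching leaves of `params`.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- param_map(grads, function(x) 0 * x)
    state$v <- param_map(grads, function(x) 0 * x)
    state$t <- 0L
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# images: n x H x W preprocessed+demeaned array -> internal batch matrix.
stack_batch <- function(images, idx) {
  H <- dim(images)[2]; W <- dim(images)[3]
  X <- matrix(0, 1, H * W * length(idx))
  for (j in seq_along(idx))
    X[1, ((j - 1) * H * W + 1):(j * H * W)] <- images[idx[j], , ]
  X
}

eval_pass <- function(model, images, labels, batch_size = 64L) {
  n <- dim(images)[1]
  H <- dim(images)[2]; W <- dim(images)[3]
  probs <- matrix(0, n, model$cfg$num_classes)
  loss <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    X <- stack_batch(images, idx)
    r <- network_fwd(model, X, H, W, length(idx), train = FALSE)
    probs[idx, ] <- t(r$probs)
    ce <- -log(pmax(r$probs[cbind(labels[idx] + 1L, seq_along(idx))], 1e-12))
    loss <- loss + sum(ce)
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  list(probs = probs, pred = pred, loss = loss / n,
       accuracy = mean(pred == labels))
}

#' Train the multi-attention classifier
#'
#' Full training protocol on a raw-intensity dataset: per-image min-max
#' normalization and bilinear resize, stratified 80:20 split, per-channel
#' demeaning with training-split statistics, mini-batch Adam on the
#' cross-entropy loss with on-the-fly augmentation, and early stopping on
#' the monitored validation quantity with best-epoch weight restoration.
#' The entire run is a deterministic function of `train_cfg$seed`.
#'
#' @param dataset list with `images` (`n x H x W` raw intensities) and
#'   `labels` (0/1), e.g. from [generate_phantoms()].
#' @param net_cfg an [network_config()].
#' @param train_cfg a [train_config()].
#' @param pre_cfg a [preprocess_config()].
#' @param aug_cfg an [augment_config()].
#' @param split optional precomputed split (list with `train`, `test`);
#'   defaults to a stratified split seeded by `train_cfg$seed`.
#' @param verbose print one line per epoch.
#' @return object of class `lssnet_fit`: list with `model` (best-epoch
#'   weights), `log` (per-epoch data.frame), `best_epoch`, `stopped_epoch`,
#'   `split`, `channel_mean`, `metrics` (test-split evaluation of the best
#'   model, see [evaluate_network()]).
#' @export
train_network <- function(dataset, net_cfg, train_cfg = train_config(),
                          pre_cfg = preprocess_config(),
                          aug_cfg = augment_config(),
                          split = NULL, verbose = FALSE) {
  labels <- dataset$labels
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  if (is.null(split))
    split <- stratified_split(labels, train_cfg$split_ratio, train_cfg$seed)
  proc <- preprocess_images(dataset$images, pre_cfg)
  tr_idx <- split$train
  te_idx <- split$test
  val_idx <- te_idx
  if (train_cfg$val_fraction > 0) {
    inner <- stratified_split(labels[tr_idx], 1 - train_cfg$val_fraction,
                              train_cfg$seed + 1L)
    val_idx <- tr_idx[inner$test]
    tr_idx <- tr_idx[inner$train]
  }
  st <- channel_stats(proc[tr_idx, , , drop = FALSE])
  demean <- function(a) {
    out <- a
    if (pre_cfg$demean) out <- out - st$mean
    if (pre_cfg$divide_by_sd) out <- out / max(st$sd, 1e-8)
    out
  }
  sz <- pre_cfg$target_size
  y_tr <- labels[tr_idx]
  y_val <- labels[val_idx]
  val_images <- demean(proc[val_idx, , , drop = FALSE])
  fit <- with_seed(train_cfg$seed, {
    model <- init_network(net_cfg)
    adam <- list(m = NULL, v = NULL, t = 0L)
    log <- data.frame()
    best_model <- model
    best_val <- Inf
    best_epoch <- NA_integer_
    wait <- 0L
    stopped <- NA_integer_
    mode_min <- train_cfg$monitor == "val_loss"
    n_tr <- length(tr_idx)
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      for (s in seq(1, n_tr, by = train_cfg$batch_size)) {
        bidx <- ord[s:min(s + train_cfg$batch_size - 1, n_tr)]
        nb <- length(bidx)
        batch <- array(0, dim = c(nb, sz, sz))
        for (j in seq_len(nb)) {
          img <- proc[tr_idx[bidx[j]], , ]
          if (train_cfg$augment) img <- augment(img, aug_cfg)
          batch[j, , ] <- img
        }
        batch <- demean(batch)
        X <- stack_batch(batch, seq_len(nb))
        fwd <- network_fwd(model, X, sz, sz, nb, train = TRUE)
        model$state <- fwd$state
        ce <- softmax_ce(fwd$logits, y_tr[bidx] + 1L)
        if (!is.finite(ce$loss))
          stop(sprintf("training diverged: non-finite loss at epoch %d", epoch), call. = FALSE)
        ep_loss <- ep_loss + ce$loss * nb
        grads <- network_bwd(model, ce$dlogits, fwd$cache)
        upd <- adam_step(model$params, grads, adam, train_cfg$learning_rate)
        model$params <- upd$params
        adam <- upd$state
      }
      ev <- eval_pass(model, val_images, y_val)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / n_tr,
                                   val_loss = ev$loss, val_accuracy = ev$accuracy))
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %.3f",
                        epoch, ep_loss / n_tr, ev$loss, ev$accuracy))
      mon <- if (mode_min) ev$loss else -ev$accuracy
      if (mon < best_val) {
        best_val <- mon
        best_epoch <- epoch
        best_model <- model
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) { stopped <- epoch; break }
      }
    }
    list(model = best_model, log = log, best_epoch = best_epoch, stopped = stopped)
  })
  test_images <- demean(proc[te_idx, , , drop = FALSE])
  metrics <- evaluate_images(fit$model, test_images, labels[te_idx])
  structure(list(model = fit$model, log = fit$log, best_epoch = fit$best_epoch,
                 stopped_epoch = fit$stopped, split = split,
                 channel_mean = st$mean, channel_sd = st$sd,
                 metrics = metrics,
                 net_cfg = net_cfg, train_cfg = train_cfg, pre_cfg = pre_cfg),
            class = "lssnet_fit")
}

# Evaluate a model on already-demeaned images.
evaluate_images <- function(model, images, labels) {
  ev <- eval_pass(model, images, labels)
  counts <- confusion_counts(ev$pred, labels)
  m <- compute_metrics(counts)
  roc <- if (length(unique(labels)) > 1)
    roc_auc(ev$probs[, 2], labels) else list(roc_points = NULL, auc = NA_real_)
  c(m, list(roc_points = roc$roc_points, auc = roc$auc,
            probabilities = ev$probs, loss = ev$loss))
}

#' Evaluate a trained model on raw images
#'
#' Applies the fit's preprocessing (normalization, resize, training-split
#' demeaning) and reports the full metrics set: confusion counts, accuracy,
#' precision, recall, F1, ROC points and AUC.
#'
#' @param fit an `lssnet_fit` from [train_network()].
#' @param images `n x H x W` raw intensity array.
#' @param labels 0/1 labels.
#' @return metrics list (see [compute_metrics()], plus `roc_points`, `auc`,
#'   `probabilities`, `loss`).
#' @export
evaluate_network <- function(fit, images, labels) {
  proc <- preprocess_images(images, fit$pre_cfg)
  if (fit$pre_cfg$demean) proc <- proc - fit$channel_mean
  if (fit$pre_cfg$divide_by_sd) proc <- proc / max(fit$channel_sd, 1e-8)
  evaluate_images(fit$model, proc, labels)
}

#' @export
print.lssnet_fit <- function(x, ...) {
  cat(sprintf("<lssnet_fit> branches: %s | best epoch %s | test acc %.3f, F1 %.3f, AUC %.3f\n",
              paste(x$net_cfg$enabled_branches, collapse = "+"),
              x$best_epoch, x$metrics$accuracy, x$metrics$f1, x$metrics$auc))
  invisible(x)
}

#' Run the attention-branch ablation study
#'
#' Trains the full three-branch model, the three minus-one variants and the
#' three only-one variants under an identical seed, split and schedule, and
#' tabulates their test metrics.
#'
#' @param dataset raw dataset (as for [train_network()]).
#' @param net_cfg base full-model [network_config()] (all three branches).
#' @param train_cfg shared [train_config()].
#' @param out_dir optional directory; if given, writes `ablation.csv` and
#'   `ablation.json`.
#' @param ... passed on to [train_network()].
#' @return list with `table` (one row per variant: accuracy, precision,
#'   recall, f1, auc), `split`, and `fits` (named list of `lssnet_fit`).
#' @export
run_ablation <- function(dataset, net_cfg, train_cfg = train_config(),
                         out_dir = NULL, ...) {
  variants <- list(full = net_cfg)
  for (br in c("cbam", "mhsam", "sam")) {
    variants[[paste0("without_", br)]] <- build_ablation_variant(net_cfg, drop = br)
    variants[[paste0("only_", br)]] <- build_ablation_variant(net_cfg, keep_only = br)
  }
  split <- stratified_split(dataset$labels, train_cfg$split_ratio, train_cfg$seed)
  fits <- list()
  rows <- list()
  for (nm in names(variants)) {
    fit <- train_network(dataset, variants[[nm]], train_cfg, split = split, ...)
    fits[[nm]] <- fit
    m <- fit$metrics
    rows[[nm]] <- data.frame(variant = nm,
                             branches = paste(variants[[nm]]$enabled_branches, collapse = "+"),
                             accuracy = m$accuracy, precision = m$precision,
                             recall = m$recall, f1 = m$f1, auc = m$auc,
                             stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(table, file.path(out_dir, "ablation.csv"), row.names = FALSE)
    jsonlite::write_json(table, file.path(out_dir, "ablation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(table = table, split = split, fits = fits)
}
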