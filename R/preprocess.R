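# Deterministic preprocessing: per-image min-max intensity normalization to
# 0-255, bilinear resize to the model's input size, and per-channel
# demeaning with statistics taken from the training split.

#' Preprocessing configuration
#'
#' @param target_size output side length in pixels.
#' @param normalize_lo,normalize_hi output intensity bounds of the min-max
#'   rescale.
#' @param demean subtract the per-channel mean (computed over the training
#'   collection) from every pixel.
#' @param divide_by_sd additionally divide by the per-channel standard
#'   deviation (guard: sd < 1e-8 divides by 1).
#' @param dataset_wide use one min/max over the whole collection instead of
#'   per-image rescaling.
#' @param replicate_channels replicate grayscale to 3 channels (for
#'   pretrained-backbone comparisons; off by default).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L, normalize_lo = 0,
                              normalize_hi = 255, demean = TRUE,
                              divide_by_sd = FALSE, dataset_wide = FALSE,
                              replicate_channels = FALSE) {
  stop_field(normalize_lo < normalize_hi, "normalize_lo", "must be < normalize_hi")
  stop_field(target_size >= 1, "target_size", "must be positive")
  structure(list(target_size = as.integer(target_size),
                 normalize_lo = normalize_lo, normalize_hi = normalize_hi,
                 demean = isTRUE(demean), divide_by_sd = isTRUE(divide_by_sd),
                 dataset_wide = isTRUE(dataset_wide),
                 replicate_channels = isTRUE(replicate_channels),
                 # bilinear corner convention: half-pixel centers, so that an
                 # identity resize is exact
                 resize_convention = "half_pixel"),
            class = "preprocess_config")
}

#' Min-max intensity normalization
#'
#' Rescales an image so its minimum maps to `normalize_lo` and its maximum
#' to `normalize_hi`. A constant image maps to `normalize_lo` everywhere.
#' Idempotent.
#'
#' @param img numeric matrix (H x W) or array (H x W x C).
#' @param cfg a [preprocess_config()].
#' @return normalized image of the same shape.
#' @export
normalize_intensity <- function(img, cfg = preprocess_config()) {
  check_finite(img)
  lo <- min(img); hi <- max(img)
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    out <- img; out[] <- cfg$normalize_lo
    return(out)
  }
  out <- cfg$normalize_lo + (img - lo) * (cfg$normalize_hi - cfg$normalize_lo) / (hi - lo)
  # guard the bound invariant against one-ulp rounding overshoot
  out[out < cfg$normalize_lo] <- cfg$normalize_lo
  out[out > cfg$normalize_hi] <- cfg$normalize_hi
  out
}

# Half-pixel-center source coordinates (0-based) for resizing n_in -> n_out.
resize_coords <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s - 0.5
  pmin(pmax(src, 0), n_in - 1)
}

#' Bilinear resize
#'
#' Resizes to `cfg$target_size` x `cfg$target_size` using separable bilinear
#' interpolation with half-pixel centers (an identity resize reproduces the
#' input exactly). A 1x1 input returns a constant fill of its value.
#'
#' @inheritParams normalize_intensity
#' @return resized image.
#' @export
resize_bilinear <- function(img, cfg = preprocess_config()) {
  if (length(dim(img)) == 3) {
    out <- array(0, dim = c(cfg$target_size, cfg$target_size, dim(img)[3]))
    for (c in seq_len(dim(img)[3])) out[, , c] <- resize_bilinear(img[, , c], cfg)
    return(out)
  }
  H <- nrow(img); W <- ncol(img)
  n <- cfg$target_size
  if (H == n && W == n) return(img)
  if (H == 1 && W == 1) return(matrix(img[1, 1], n, n))
  ys <- resize_coords(H, n)
  xs <- resize_coords(W, n)
  y0 <- floor(ys); wy <- ys - y0
  x0 <- floor(xs); wx <- xs - x0
  y1 <- pmin(y0 + 1, H - 1)
  x1 <- pmin(x0 + 1, W - 1)
  top <- img[y0 + 1, , drop = FALSE] * (1 - wy) + img[y1 + 1, , drop = FALSE] * wy
  top[, x0 + 1, drop = FALSE] * rep(1 - wx, each = n) +
    top[, x1 + 1, drop = FALSE] * rep(wx, each = n)
}

#' Per-channel collection statistics
#'
#' Mean and standard deviation of each channel over an image collection —
#' computed on the training split and reused for test images to avoid
#' leakage.
#'
#' @param imgs collection: `n x H x W` array (grayscale) or list of images.
#' @return list with `mean` and `sd` (one entry per channel).
#' @export
channel_stats <- function(imgs) {
  if (is.list(imgs)) imgs <- simplify2array(imgs)
  v <- as.vector(imgs)
  list(mean = mean(v), sd = stats::sd(v))
}

#' Demean (and optionally scale) an image collection
#'
#' Subtracts the per-channel mean from every pixel; with
#' `cfg$divide_by_sd`, divides by the per-channel standard deviation
#' (sd < 1e-8 divides by 1). Statistics default to the collection itself but
#' should be the training-split statistics (`stats`) when applied to held-out
#' images.
#'
#' @param imgs `n x H x W` array or list of equal-shaped matrices.
#' @param cfg a [preprocess_config()].
#' @param stats optional precomputed [channel_stats()].
#' @return collection of the same form, demeaned.
#' @export
standardize <- function(imgs, cfg = preprocess_config(), stats = NULL) {
  was_list <- is.list(imgs)
  if (was_list) {
    shapes <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), character(1))
    if (length(unique(shapes)) > 1)
      stop("images in the collection have mismatched shapes", call. = FALSE)
    imgs <- simplify2array(imgs)  # H x W x n
  }
  if (is.null(stats)) stats <- channel_stats(imgs)
  out <- imgs
  if (cfg$demean) out <- out - stats$mean
  if (cfg$divide_by_sd) {
    s <- if (is.na(stats$sd) || stats$sd < 1e-8) 1 else stats$sd
    out <- out / s
  }
  if (was_list) out <- lapply(seq_len(dim(out)[3]), function(i) out[, , i])
  out
}

#' Normalize and resize a stack of raw images
#'
#' Applies [normalize_intensity()] then [resize_bilinear()] to each image of
#' an `n x H x W` array (the deterministic part of the pipeline; demeaning
#' is applied separately with training-split statistics).
#'
#' @param images `n x H x W` numeric array of raw intensities.
#' @param cfg a [preprocess_config()].
#' @return `n x target_size x target_size` array.
#' @export
preprocess_images <- function(images, cfg = preprocess_config()) {
  n <- dim(images)[1]
  out <- array(0, dim = c(n, cfg$target_size, cfg$target_size))
  if (cfg$dataset_wide) {
    lo <- min(images); hi <- max(images)
    rng <- if (hi - lo < 1e-12) 1 else hi - lo
    for (i in seq_len(n)) {
      img <- cfg$normalize_lo + (images[i, , ] - lo) * (cfg$normalize_hi - cfg$normalize_lo) / rng
      out[i, , ] <- resize_bilinear(img, cfg)
    }
  } else {
    for (i in seq_len(n))
      out[i, , ] <- resize_bilinear(normalize_intensity(images[i, , ], cfg), cfg)
  }
  out
}

#' Read a region-of-interest image file
#'
#' Reads a PNG (values scaled to 0-255) or TIFF (values scaled to 0-65535)
#' grayscale image into a numeric matrix; multi-channel files are averaged
#' to one channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix of intensities.
#' @export
read_roi_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path) * 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path) * 65535
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}
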