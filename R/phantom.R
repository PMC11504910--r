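# Synthetic lumbar-ROI phantoms.
#
# Each phantom is a single-channel raw-intensity image (DICOM-like 0-4095
# range, deliberately NOT 0-255 so the normalization step does real work)
# showing a bright elliptical "dural sac" on a textured dark background.
# Severity is encoded geometrically: severe images carry a smaller,
# flattened ellipse (canal narrowing); class frequencies are configurable to
# match the per-condition imbalance of the source dataset.

#' Per-condition class frequencies
#'
#' The normal/mild vs severe frequency table of the five lumbar stenosis
#' conditions (spinal canal stenosis, left/right neural foraminal narrowing,
#' left/right subarticular stenosis), used to parameterize per-condition
#' phantom datasets.
#'
#' @return data.frame with columns `condition`, `n_mild`, `n_severe`, `total`.
#' @export
lss_condition_table <- function() {
  data.frame(
    condition = c("spinal_stenosis",
                  "left_neural_foraminal_narrowing",
                  "right_neural_foraminal_narrowing",
                  "left_subarticular_stenosis",
                  "right_subarticular_stenosis"),
    n_mild = c(1429L, 1517L, 1525L, 1243L, 1244L),
    n_severe = c(203L, 115L, 107L, 389L, 388L),
    total = rep(1632L, 5L),
    stringsAsFactors = FALSE)
}

#' Phantom generation parameters
#'
#' @param image_size side length in pixels of the square phantom.
#' @param n_images number of images to generate.
#' @param severe_fraction proportion of severe images in `[0,1]`.
#' @param canal_radius_mild semi-major axis (pixels) of the canal ellipse in
#'   normal/mild images.
#' @param canal_radius_severe semi-major axis in severe images; must be
#'   smaller than `canal_radius_mild` (stenosis = narrowing).
#' @param canal_contrast intensity added inside the canal (raw units).
#' @param background_level mean background intensity (raw units).
#' @param background_texture_sd Gaussian background texture scale.
#' @param jitter_sd standard deviation (pixels) of canal center displacement.
#' @param condition condition name recorded on every image.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the spec including this seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 224L, n_images = 100L,
                         severe_fraction = 203 / 1632,
                         canal_radius_mild = 22, canal_radius_severe = 11,
                         canal_contrast = 2000, background_level = 600,
                         background_texture_sd = 150, jitter_sd = 6,
                         condition = "spinal_stenosis", seed = 1L) {
  stop_field(is.numeric(n_images) && n_images > 0, "n_images", "must be > 0")
  stop_field(is.numeric(severe_fraction) && severe_fraction >= 0 && severe_fraction <= 1,
             "severe_fraction", "must be in [0,1]")
  stop_field(canal_radius_severe < canal_radius_mild, "canal_radius_severe",
             "must be smaller than canal_radius_mild")
  stop_field(image_size >= 8, "image_size", "must be >= 8 pixels")
  stop_field(background_texture_sd >= 0, "background_texture_sd", "must be >= 0")
  stop_field(jitter_sd >= 0, "jitter_sd", "must be >= 0")
  structure(list(image_size = as.integer(image_size), n_images = as.integer(n_images),
                 severe_fraction = severe_fraction,
                 canal_radius_mild = canal_radius_mild,
                 canal_radius_severe = canal_radius_severe,
                 canal_contrast = canal_contrast,
                 background_level = background_level,
                 background_texture_sd = background_texture_sd,
                 jitter_sd = jitter_sd, condition = condition,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

draw_phantom <- function(sz, severe, spec) {
  img <- spec$background_level +
    matrix(rnorm(sz * sz, sd = spec$background_texture_sd), sz, sz)
  cx <- (sz + 1) / 2 + rnorm(1, sd = spec$jitter_sd)
  cy <- (sz + 1) / 2 + rnorm(1, sd = spec$jitter_sd)
  if (severe) {
    a <- spec$canal_radius_severe
    b <- spec$canal_radius_severe * 0.55   # flattened sac
  } else {
    a <- spec$canal_radius_mild
    b <- spec$canal_radius_mild * 0.85
  }
  xs <- (seq_len(sz) - cx) / a
  ys <- (seq_len(sz) - cy) / b
  dist2 <- outer(xs^2, ys^2, `+`)
  mask <- 1 / (1 + exp((sqrt(dist2) - 1) / 0.06))
  img <- img + spec$canal_contrast * mask
  img[img < 0] <- 0
  img[img > 4095] <- 4095
  round(img)
}

#' Generate a seeded phantom dataset
#'
#' Produces `n_images` single-channel raw-intensity phantoms with
#' `round(n_images * severe_fraction)` severe images in a seeded random
#' order. Identical spec (including seed) gives bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `lssnet_phantoms`: list with `images`
#'   (`n x size x size` array), `labels` (integer, 0 = normal/mild,
#'   1 = severe), `condition` (character vector), `spec`.
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_images
    sz <- spec$image_size
    n_severe <- round(n * spec$severe_fraction)
    labels <- integer(n)
    labels[sample.int(n, n_severe)] <- 1L
    images <- array(0, dim = c(n, sz, sz))
    for (i in seq_len(n)) images[i, , ] <- draw_phantom(sz, labels[i] == 1L, spec)
    structure(list(images = images, labels = labels,
                   condition = rep(spec$condition, n), spec = spec),
              class = "lssnet_phantoms")
  })
}

#' @export
print.lssnet_phantoms <- function(x, ...) {
  cat(sprintf("<lssnet_phantoms> %d images %dx%d, %d severe (%.1f%%), condition %s\n",
              length(x$labels), x$spec$image_size, x$spec$image_size,
              sum(x$labels), 100 * mean(x$labels), x$spec$condition))
  invisible(x)
}

#' Write phantoms to disk
#'
#' Writes one 16-bit grayscale TIFF per image (raw integer intensities are
#' stored exactly; a 16-bit container holds the full 0-4095 range) plus a CSV
#' manifest with columns `filename,label,condition`.
#'
#' @param phantoms an `lssnet_phantoms` object.
#' @param directory output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
phantom_to_files <- function(phantoms, directory) {
  stopifnot(inherits(phantoms, "lssnet_phantoms"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }
  n <- length(phantoms$labels)
  fns <- character(n)
  if (n > 0) for (i in seq_len(n)) {
    fns[i] <- sprintf("phantom_%04d.tiff", i)
    img <- phantoms$images[i, , ] / 65535
    tiff::writeTIFF(img, file.path(directory, fns[i]), bits.per.sample = 16L)
  }
  manifest <- data.frame(filename = fns,
                         label = phantoms$labels,
                         condition = phantoms$condition,
                         stringsAsFactors = FALSE)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a phantom directory written by [phantom_to_files()]
#'
#' @param directory directory containing `manifest.csv` and image files.
#' @return an `lssnet_phantoms`-like list (without the generating spec).
#' @export
read_phantom_dir <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in directory", call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  n <- nrow(manifest)
  images <- NULL
  for (i in seq_len(n)) {
    img <- round(tiff::readTIFF(file.path(directory, manifest$filename[i])) * 65535)
    if (is.null(images)) images <- array(0, dim = c(n, nrow(img), ncol(img)))
    images[i, , ] <- img
  }
  structure(list(images = images, labels = as.integer(manifest$label),
                 condition = manifest$condition, spec = NULL),
            class = "lssnet_phantoms")
}

#' Canal-area score of a phantom image
#'
#' Counts pixels brighter than the midpoint between the image's 5th and
#' 99.9th intensity percentiles — a direct geometric measurement of the
#' bright canal area, independent of any learned model.
#'
#' @param img numeric matrix.
#' @return bright-pixel count.
#' @export
canal_area_score <- function(img) {
  q <- stats::quantile(img, c(0.05, 0.999), names = FALSE)
  sum(img > (q[1] + q[2]) / 2)
}

#' Geometric separability oracle
#'
#' Classifies phantoms by thresholding the canal-area score at the midpoint
#' of the two class medians, certifying (without any network) how separable
#' a generated dataset is.
#'
#' @param phantoms an `lssnet_phantoms` object with both classes present.
#' @return list with `accuracy`, `threshold`, `scores`.
#' @export
phantom_separability <- function(phantoms) {
  stopifnot(inherits(phantoms, "lssnet_phantoms"))
  y <- phantoms$labels
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  scores <- apply(phantoms$images, 1, canal_area_score)
  thr <- (stats::median(scores[y == 0]) + stats::median(scores[y == 1])) / 2
  pred <- as.integer(scores < thr)   # severe canal is smaller
  list(accuracy = mean(pred == y), threshold = thr, scores = scores)
}
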