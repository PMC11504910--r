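# Stochastic training-time augmentation: random scale, translation,
# rotation and vertical flip, applied in that fixed order as one composed
# affine warp with bilinear resampling (composition is non-commutative, so
# the order is part of the configuration contract).

#' Augmentation configuration
#'
#' @param scale_range multiplicative zoom range.
#' @param translate_range translation range in pixels (each axis).
#' @param rotate_range rotation range in degrees.
#' @param vflip_prob probability of a vertical (top-bottom) flip.
#' @param fill_value intensity for regions exposed by the warp.
#' @param fill_mode `"constant"` or `"reflect"`.
#' @param seed optional seed used by [oversample_minority()].
#' @return object of class `augment_config`.
#' @export
augment_config <- function(scale_range = c(0.8, 1.2),
                           translate_range = c(-20, 20),
                           rotate_range = c(-15, 15),
                           vflip_prob = 0.5,
                           fill_value = 0,
                           fill_mode = c("constant", "reflect"),
                           seed = 1L) {
  stop_field(length(scale_range) == 2 && scale_range[1] <= scale_range[2] && scale_range[1] > 0,
             "scale_range", "must be an ordered positive pair")
  stop_field(length(translate_range) == 2 && translate_range[1] <= translate_range[2],
             "translate_range", "must be an ordered pair")
  stop_field(length(rotate_range) == 2 && rotate_range[1] <= rotate_range[2],
             "rotate_range", "must be an ordered pair")
  stop_field(vflip_prob >= 0 && vflip_prob <= 1, "vflip_prob", "must be in [0,1]")
  structure(list(scale_range = scale_range, translate_range = translate_range,
                 rotate_range = rotate_range, vflip_prob = vflip_prob,
                 fill_value = fill_value, fill_mode = match.arg(fill_mode),
                 seed = seed,
                 # transform order is fixed and recorded here
                 order = c("scale", "translate", "rotate", "vflip")),
            class = "augment_config")
}

#' Draw one set of augmentation parameters
#'
#' Samples scale, x/y translation and rotation uniformly from their
#' configured ranges and the flip as a Bernoulli draw, consuming the current
#' RNG stream.
#'
#' @param cfg an [augment_config()].
#' @return list with `scale`, `tx`, `ty`, `angle`, `vflip`.
#' @export
sample_augment_params <- function(cfg) {
  list(scale = runif(1, cfg$scale_range[1], cfg$scale_range[2]),
       tx = runif(1, cfg$translate_range[1], cfg$translate_range[2]),
       ty = runif(1, cfg$translate_range[1], cfg$translate_range[2]),
       angle = runif(1, cfg$rotate_range[1], cfg$rotate_range[2]),
       vflip = runif(1) < cfg$vflip_prob)
}

# Apply the composed affine transform for given parameters.
# Coordinates are centered at the image midpoint ((H+1)/2 in 1-based terms);
# output pixel value = input sampled at the inverse-transformed position.
apply_affine <- function(img, par, cfg) {
  H <- nrow(img); W <- ncol(img)
  th <- par$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fl <- diag(c(1, if (par$vflip) -1 else 1))   # (x, y) with y = rows
  A <- Fl %*% R * par$scale                     # p_out = Fl R (s p + t)
  b <- Fl %*% R %*% c(par$tx, par$ty)
  Ainv <- solve(A)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xo <- rep(seq_len(W) - cx, each = H)
  yo <- rep(seq_len(H) - cy, times = W)
  src <- Ainv %*% rbind(xo - b[1], yo - b[2])
  xs <- src[1, ] + cx - 1   # 0-based source column
  ys <- src[2, ] + cy - 1
  if (cfg$fill_mode == "reflect") {
    reflect <- function(v, n) {
      if (n == 1) return(0 * v)
      p <- 2 * (n - 1)
      v <- v %% p
      ifelse(v > (n - 1), p - v, v)
    }
    xs <- reflect(xs, W); ys <- reflect(ys, H)
    pad <- img
    offr <- 1; offc <- 1
    Hp <- H; Wp <- W
  } else {
    xs <- pmin(pmax(xs, -1), W)
    ys <- pmin(pmax(ys, -1), H)
    pad <- matrix(cfg$fill_value, H + 3, W + 3)
    pad[2:(H + 1), 2:(W + 1)] <- img
    offr <- 2; offc <- 2
    Hp <- H + 3; Wp <- W + 3
  }
  y0 <- floor(ys); wy <- ys - y0
  x0 <- floor(xs); wx <- xs - x0
  i0 <- y0 + offr; i1 <- pmin(y0 + 1 + offr, Hp)
  j0 <- x0 + offc; j1 <- pmin(x0 + 1 + offc, Wp)
  v <- pad[cbind(i0, j0)] * (1 - wy) * (1 - wx) +
       pad[cbind(i1, j0)] * wy * (1 - wx) +
       pad[cbind(i0, j1)] * (1 - wy) * wx +
       pad[cbind(i1, j1)] * wy * wx
  matrix(v, H, W)
}

#' Augment one image
#'
#' Applies scale, translate, rotate and vertical flip (in that order) with
#' parameters drawn from the configured ranges — or with explicitly supplied
#' `params` for a deterministic warp. Output dimensions equal input
#' dimensions; exposed borders are filled with `fill_value`.
#'
#' @param img numeric matrix.
#' @param cfg an [augment_config()].
#' @param params optional list from [sample_augment_params()]; if `NULL`,
#'   parameters are drawn from the current RNG stream.
#' @return augmented image matrix.
#' @export
augment <- function(img, cfg = augment_config(), params = NULL) {
  if (is.null(params)) params <- sample_augment_params(cfg)
  if (params$scale == 1 && params$tx == 0 && params$ty == 0 &&
      params$angle == 0 && !params$vflip) return(img)
  apply_affine(img, params, cfg)
}

#' Oversample the minority class with augmented copies
#'
#' Appends augmented copies of minority-class images (cycling through them)
#' until the minority fraction reaches `target_ratio`. Originals are
#' retained untouched; the operation is seeded by `cfg$seed`.
#'
#' @param dataset an `lssnet_phantoms` (or any list with `images` as an
#'   `n x H x W` array, `labels`, `condition`).
#' @param cfg an [augment_config()].
#' @param target_ratio desired minimum minority fraction in `[0, 1)`.
#' @return dataset of the same class with appended augmented images.
#' @export
oversample_minority <- function(dataset, cfg = augment_config(), target_ratio = 0.5) {
  y <- dataset$labels
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes required for oversampling", call. = FALSE)
  stop_field(target_ratio >= 0 && target_ratio < 1, "target_ratio", "must be in [0,1)")
  minority <- as.integer(names(which.min(tab)))
  m <- min(tab); M <- max(tab)
  needed <- ceiling(target_ratio * M / (1 - target_ratio)) - m
  if (needed <= 0) return(dataset)
  idx_min <- which(y == minority)
  pick <- rep_len(idx_min, needed)
  d <- dim(dataset$images)
  add <- array(0, dim = c(needed, d[2], d[3]))
  with_seed(cfg$seed, {
    for (i in seq_len(needed))
      add[i, , ] <- augment(dataset$images[pick[i], , ], cfg)
  })
  out <- dataset
  images <- array(0, dim = c(d[1] + needed, d[2], d[3]))
  images[seq_len(d[1]), , ] <- dataset$images
  images[d[1] + seq_len(needed), , ] <- add
  out$images <- images
  out$labels <- c(y, rep(minority, needed))
  out$condition <- c(dataset$condition, dataset$condition[pick])
  out
}
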