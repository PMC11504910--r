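#' @useDynLib lssnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_finite <- function(x, what = "image") {
  if (!all(is.finite(x))) stop(sprintf("%s contains NaN/Inf pixels", what), call. = FALSE)
  invisible(x)
}

# Recursively apply f over two parallel nested lists of numeric leaves.
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map(a[[i]], f)
    out
  } else f(a)
}

# Flatten nested numeric-leaf list to named leaves ("a/b/c") for inspection.
param_flatten <- function(p, prefix = NULL) {
  if (!is.list(p)) {
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  for (nm in names(p)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = "/")
    out <- c(out, param_flatten(p[[nm]], key))
  }
  out
}

# Convert an N x C x H x W array to the internal C x (H*W*N) matrix layout
# (columns are pixels, image-major, spatial index column-major within image).
nchw_to_mat <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 4)
  x <- aperm(a, c(2, 3, 4, 1))
  dim(x) <- c(d[2], d[3] * d[4] * d[1])
  x
}

mat_to_nchw <- function(x, C, H, W, N) {
  dim(x) <- c(C, H, W, N)
  aperm(x, c(4, 1, 2, 3))
}

conv_out_dim <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

# Expand a per-image matrix (C x N) to per-pixel columns (C x T*N).
rep_cols <- function(m, T) m[, rep(seq_len(ncol(m)), each = T), drop = FALSE]
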