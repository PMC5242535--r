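## Dimension-generic array helpers shared by the rendering, relaxometry and
## registration layers. Images are plain numeric arrays (2-D matrices or 3-D
## arrays), indexed 1-based [x, y(, z)], world coordinate = (index - 1) * spacing.

#' Shift an array along one axis, replicating the edge
#'
#' @param x numeric array (2-D or 3-D).
#' @param axis axis index (1-based).
#' @param by integer shift; positive pulls values from higher indices.
#' @return array of the same shape.
#' @keywords internal
shift_array <- function(x, axis, by) {
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

#' Separable Gaussian smoothing
#'
#' Truncated discrete Gaussian (half-width `ceiling(3*sigma)`) applied along
#' each axis in turn with replicated edges. `sigma = 0` returns the input.
#'
#' @param x numeric array.
#' @param sigma kernel standard deviation in voxels; scalar or one per axis.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth <- function(x, sigma) {
  d <- dim(x)
  if (is.null(d)) stop("x must be an array")
  sigma <- rep(sigma, length.out = length(d))
  for (ax in seq_along(d)) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- as.integer(ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_array(x, ax, j - r - 1L)
    }
    x <- acc
  }
  x
}

#' Central-difference gradient of a scalar array
#'
#' One-sided differences at the boundary. Spacing is in voxels (unit grid);
#' callers working in physical units divide by their spacing.
#'
#' @param x numeric array.
#' @return list of arrays, one per axis.
#' @keywords internal
array_gradient <- function(x) {
  d <- dim(x)
  lapply(seq_along(d), function(ax) {
    fwd <- shift_array(x, ax, 1L)
    bwd <- shift_array(x, ax, -1L)
    g <- (fwd - bwd) / 2
    ## boundary: replicated-edge shifts make the two-sided difference one-sided
    ## with half weight; rescale those faces to a true one-sided difference
    n <- d[ax]
    args <- rep(list(quote(expr = )), length(d))
    lo <- args; lo[[ax]] <- 1L
    hi <- args; hi[[ax]] <- n
    gl <- do.call(`[`, c(list(g), lo, list(drop = FALSE)))
    gh <- do.call(`[`, c(list(g), hi, list(drop = FALSE)))
    g <- do.call(`[<-`, c(list(g), lo, list(value = 2 * gl)))
    g <- do.call(`[<-`, c(list(g), hi, list(value = 2 * gh)))
    g
  })
}

#' Multilinear interpolation at fractional voxel coordinates
#'
#' Bilinear (2-D) or trilinear (3-D) sampling at 1-based fractional indices.
#' Out-of-bounds coordinates are clamped to the edge.
#'
#' @param img numeric array.
#' @param coords numeric matrix, one row per sample, one column per axis.
#' @return numeric vector of sampled values.
#' @keywords internal
interp_linear <- function(img, coords) {
  d <- dim(img)
  nd <- length(d)
  stopifnot(ncol(coords) == nd)
  for (ax in seq_len(nd)) {
    coords[, ax] <- pmin(pmax(coords[, ax], 1), d[ax])
  }
  f <- floor(coords)
  for (ax in seq_len(nd)) f[, ax] <- pmin(f[, ax], d[ax] - 1L)
  w <- coords - f
  out <- numeric(nrow(coords))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    cc <- corners[ci, ]
    wt <- rep(1, nrow(coords))
    for (ax in seq_len(nd)) {
      wt <- wt * (if (cc[ax] == 1) w[, ax] else 1 - w[, ax])
    }
    idx <- f + matrix(cc, nrow(coords), nd, byrow = TRUE)
    lin <- idx[, 1]
    mult <- 1
    for (ax in 2:nd) {
      mult <- mult * d[ax - 1]
      lin <- lin + (idx[, ax] - 1) * mult
    }
    out <- out + wt * img[lin]
  }
  out
}

#' Voxel-centre coordinate grid
#'
#' @param d integer vector of array dimensions.
#' @return matrix `prod(d) x length(d)` of 1-based indices in array order.
#' @keywords internal
index_grid <- function(d) {
  as.matrix(do.call(expand.grid, lapply(d, seq_len)))
}

#' Downsample an image by 2 with box averaging
#' @keywords internal
downsample2 <- function(img) {
  d <- dim(img)
  nd <- length(d)
  nd2 <- pmax(d %/% 2L, 1L)
  g <- index_grid(nd2)
  ## average the 2^nd block
  acc <- numeric(nrow(g))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  cnt <- 0
  for (ci in seq_len(nrow(corners))) {
    idx <- sweep(2 * g - 1, 2, corners[ci, ], `+`)
    ok <- TRUE
    for (ax in seq_len(nd)) idx[, ax] <- pmin(idx[, ax], d[ax])
    lin <- idx[, 1]
    mult <- 1
    for (ax in seq_len(nd)[-1]) {
      mult <- mult * d[ax - 1]
      lin <- lin + (idx[, ax] - 1) * mult
    }
    acc <- acc + img[lin]
    cnt <- cnt + 1
  }
  array(acc / cnt, nd2)
}

## Intensity scaling used as the registration similarity pre-step.
## "quantile" maps the 1st/99th percentiles to 0/1, so tissue-class levels
## correspond across images regardless of how much of the field each class
## occupies; "zscore" is the classic alternative; "none" passes through.
scale_intensity <- function(img, method = c("quantile", "zscore", "none"),
                            mask = NULL) {
  method <- match.arg(method)
  v <- if (is.null(mask)) as.vector(img) else img[mask]
  if (method == "none") return(img)
  if (method == "zscore") {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- 1
    return((img - mean(v)) / s)
  }
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (diff(q) <= 0) q <- range(v)
  if (diff(q) <= 0) return(img * 0)
  (img - q[1]) / (q[2] - q[1])
}
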