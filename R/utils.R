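# Internal helpers shared across modules.

#' Gaussian smoothing of a regularly sampled series
#'
#' Discrete convolution with a truncated Gaussian kernel (+/- 4 sd), with the
#' kernel mass renormalised at the series edges so a constant series is left
#' unchanged everywhere.
#'
#' @param x numeric series.
#' @param sd_bins kernel standard deviation in units of bins. `sd_bins <= 0`
#'   returns `x` unchanged.
#' @return smoothed series, same length as `x`.
#' @keywords internal
#' @noRd
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  n <- length(x)
  xp <- c(rep(NA_real_, half), x, rep(NA_real_, half))
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + 2L * half)]
    ok <- !is.na(seg)
    out[i] <- sum(seg[ok] * k[ok]) / sum(k[ok])
  }
  out
}

# Causal (trailing half-Gaussian) smoothing: the value at i uses samples
# i, i-1, ..., weighted by a Gaussian in lag, renormalised at the start.
causal_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(0:half, sd = sd_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0:min(half, i - 1L)
    out[i] <- sum(x[i - lag] * k[lag + 1L]) / sum(k[lag + 1L])
  }
  out
}

# 90 degree counter-clockwise rotation of a matrix (square required for the
# lossless subfield rotation used by the colocalization null).
rot90_mat <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

#' Point-in-polygon with a deterministic half-open boundary rule
#'
#' Even-odd (crossing number) rule with half-open edges: rays are cast in +x
#' and each edge counts its lower vertex but not its upper one, so a point on
#' a boundary shared by two adjacent simple polygons is counted inside exactly
#' one of them. Points on a left boundary are inside, points on a right
#' boundary outside.
#'
#' @param px,py point coordinates.
#' @param poly data.frame or matrix with columns x, y (vertices in order,
#'   closed implicitly).
#' @return logical vector.
#' @keywords internal
#' @noRd
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly[, 1:2])
  nv <- nrow(poly)
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace polygon area (absolute value).
polygon_area <- function(poly) {
  poly <- as.matrix(poly[, 1:2])
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Paired / one-sample t-test p-value that degrades gracefully when the
# differences have zero variance (returns NA rather than erroring).
safe_t_p <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2L || stats::sd(d) == 0) return(NA_real_)
  stats::t.test(d)$p.value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
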