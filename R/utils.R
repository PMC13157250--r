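# Internal numerical utilities shared across modules.

#' Centered rolling mean with shrinking edge windows
#'
#' At position t the mean is taken over `[t - h, t + h]` intersected with the
#' series, where `h = floor(width / 2)`; near the edges the window shrinks
#' rather than padding, so the output has no startup artifacts and the same
#' length as the input.
#'
#' @param x numeric vector.
#' @param width window width in samples (coerced to an odd integer >= 1 by
#'   taking `h = floor(width / 2)`).
#' @param edges `"shrink"`: windows shrink to the available samples;
#'   `"extrapolate"`: the series is padded by the least-squares linear trend
#'   of its first/last window, keeping every window full width (unbiased
#'   against a steep monotone trend at the edges).
#' @return numeric vector, same length as `x`.
#' @keywords internal
rolling_mean <- function(x, width, edges = c("shrink", "extrapolate")) {
  edges <- match.arg(edges)
  n <- length(x)
  h <- max(0L, as.integer(floor(width / 2)))
  if (h == 0L) return(x)
  if (edges == "extrapolate") {
    k <- min(n, 2L * h + 1L)
    i1 <- seq_len(k)
    b1 <- stats::cov(i1, x[i1]) / stats::var(i1)
    a1 <- mean(x[i1]) - b1 * mean(i1)
    i2 <- (n - k + 1L):n
    b2 <- stats::cov(i2, x[i2]) / stats::var(i2)
    a2 <- mean(x[i2]) - b2 * mean(i2)
    xp <- c(a1 + b1 * ((1L - h):0L), x, a2 + b2 * ((n + 1L):(n + h)))
    cs <- c(0, cumsum(xp))
    lo <- seq_len(n)
    return((cs[lo + 2L * h + 1L] - cs[lo]) / (2L * h + 1L))
  }
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rolling mean along rows of a P x T matrix (each row a pixel time series),
# with per-row linear-trend extrapolation at the edges (vectorized).
rolling_mean_rows <- function(m, width) {
  n <- ncol(m)
  h <- max(0L, as.integer(floor(width / 2)))
  if (h == 0L) return(m)
  k <- min(n, 2L * h + 1L)
  lin_pad <- function(sub, idx, pos) {
    # least-squares line per row over columns idx, evaluated at pos
    ib <- idx - mean(idx)
    b <- (sub %*% ib) / sum(ib^2)
    a <- rowMeans(sub) - b * mean(idx)
    a %*% t(rep(1, length(pos))) + b %*% t(pos)
  }
  pre <- lin_pad(m[, seq_len(k), drop = FALSE], seq_len(k), (1L - h):0L)
  post <- lin_pad(m[, (n - k + 1L):n, drop = FALSE], (n - k + 1L):n,
                  (n + 1L):(n + h))
  mp <- cbind(pre, m, post)
  cs <- cbind(0, t(apply(mp, 1L, cumsum)))
  lo <- seq_len(n)
  (cs[, lo + 2L * h + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) / (2L * h + 1L)
}

#' Deterministic local maxima with a minimum-separation rule
#'
#' A sample is a candidate peak when it strictly exceeds its left neighbour
#' and is not exceeded by its right neighbour, so a flat plateau yields its
#' earliest frame. Candidates below `min_height` are dropped; the remainder
#' are accepted greedily in order of decreasing height (ties broken by the
#' earlier index), discarding any candidate within `min_distance` samples of
#' an already-accepted peak.
#'
#' @param x numeric vector.
#' @param min_height minimum value for a retained peak.
#' @param min_distance minimum separation between retained peaks, in samples.
#' @return integer vector of peak indices, increasing.
#' @keywords internal
local_maxima <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0L || min_distance <= 1L) return(cand)
  ord <- cand[order(-x[cand], cand)]
  keep <- integer(0)
  for (p in ord) {
    if (all(abs(keep - p) >= min_distance)) keep <- c(keep, p)
  }
  sort(keep)
}

# Sample skewness (biased, moment estimator); 0 for degenerate input.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Translate an image by a (possibly subpixel) offset
#'
#' The image content moves by `dy` rows (down when positive) and `dx` columns
#' (right when positive): `out[r, c] = img[r - dy, c - dx]` with bilinear
#' interpolation. Samples falling outside the input are set to `fill`.
#'
#' @param img numeric matrix.
#' @param dy,dx translation in pixels (float).
#' @param fill value for out-of-field pixels (default: median of `img`).
#' @return numeric matrix of the same dimensions.
#' @keywords internal
translate_bilinear <- function(img, dy, dx, fill = stats::median(img)) {
  h <- nrow(img); w <- ncol(img)
  if (dy == 0 && dx == 0) return(img)
  r_src <- seq_len(h) - dy
  c_src <- seq_len(w) - dx
  r0 <- floor(r_src); c0 <- floor(c_src)
  fr <- r_src - r0; fc <- c_src - c0
  # pad by one on each side so integer neighbours can be indexed uniformly
  pad <- matrix(fill, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  ri <- r0 + 1L; ci <- c0 + 1L  # index of floor sample in padded frame
  ri[r0 < 0L | r0 > h] <- NA; ci[c0 < 0L | c0 > w] <- NA
  ri_ok <- ifelse(is.na(ri), 1L, pmax(1L, pmin(h + 1L, ri)))
  ci_ok <- ifelse(is.na(ci), 1L, pmax(1L, pmin(w + 1L, ci)))
  a00 <- pad[ri_ok, ci_ok, drop = FALSE]
  a10 <- pad[ri_ok + 1L, ci_ok, drop = FALSE]
  a01 <- pad[ri_ok, ci_ok + 1L, drop = FALSE]
  a11 <- pad[ri_ok + 1L, ci_ok + 1L, drop = FALSE]
  wr <- matrix(fr, h, w); wc <- matrix(fc, h, w, byrow = TRUE)
  out <- a00 * (1 - wr) * (1 - wc) + a10 * wr * (1 - wc) +
    a01 * (1 - wr) * wc + a11 * wr * wc
  out[is.na(ri), ] <- fill
  out[, is.na(ci)] <- fill
  out
}

# Separable Gaussian blur with reflected borders (optics PSF emulation).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(m) {  # along rows of m
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - rev(seq_len(r)))
    padded <- m[pmax(1L, pmin(n, idx)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
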