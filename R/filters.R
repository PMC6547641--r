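# Pixel-level filters used by segmentation: Sobel gradient, adaptive
# (Wiener) denoising, unsharp masking and Otsu thresholding. All filters
# replicate the border pixel outward ("edge replication") so output extent
# equals input extent.

# Shift a matrix by (dy, dx) with replicate padding.
.shift_rep <- function(m, dy, dx) {
  ri <- pmin(pmax(seq_len(nrow(m)) - dy, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) - dx, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 3x3 correlation with replicate padding; k is the 3x3 kernel,
# k[2,2] over the center pixel.
.conv3x3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1)
    for (dx in -1:1) {
      w <- k[dy + 2L, dx + 2L]
      if (w != 0) out <- out + w * .shift_rep(m, -dy, -dx)
    }
  out
}

# Local mean over a size x size window (replicate padding), via an
# integral image on the padded matrix.
.box_mean <- function(m, size = 5L) {
  r <- (size - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  s <- rbind(0, cbind(0, s))                    # s[j+1, i+1] = sum p[1:i,1:j]
  i1 <- seq_len(nr); i2 <- i1 + 2L * r
  j1 <- seq_len(nc); j2 <- j1 + 2L * r
  tot <- t(s[j2 + 1L, i2 + 1L] - s[j1, i2 + 1L] - s[j2 + 1L, i1] + s[j1, i1])
  tot / size^2
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels in x and y and combines the two
#' responses as the Euclidean norm. Borders are handled by edge
#' replication, so a constant image yields an exactly zero gradient.
#'
#' @param channel 2-D intensity matrix, at least 3x3.
#' @return Non-negative gradient-magnitude matrix of the same extent.
#' @export
sobel_gradient <- function(channel) {
  if (!is.matrix(channel) || nrow(channel) < 3L || ncol(channel) < 3L)
    stop("sobel_gradient needs a matrix of extent >= 3x3")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  ky <- t(kx)
  gx <- .conv3x3(channel, kx)
  gy <- .conv3x3(channel, ky)
  sqrt(gx^2 + gy^2)
}

#' Automatic base threshold for Sobel edge maps
#'
#' The base threshold is the root-mean-square of the gradient magnitudes
#' multiplied by a fixed constant (default 4), a standard automatic Sobel
#' threshold heuristic. The effective threshold applied during segmentation
#' is `base * edge_threshold_multiplier`; the multiplier (default 0.5) is
#' the user's tuning knob — smaller values detect more candidate edges,
#' larger values are more stringent.
#'
#' @param gradient Non-negative gradient-magnitude matrix with at least one
#'   non-zero value.
#' @param constant Internal scale constant applied to the RMS.
#' @return Positive scalar base threshold.
#' @export
auto_edge_threshold <- function(gradient, constant = 4) {
  if (all(gradient == 0))
    stop("degenerate input: gradient is identically zero (no edges ",
         "detectable)")
  sqrt(mean(gradient^2)) * constant
}

#' Adaptive (Wiener) denoising
#'
#' Local-mean / local-variance adaptive filter with a 5x5 window: the local
#' variance is measured around every pixel and intensities are smoothed in
#' inverse relation to it, so flat (noisy) regions are averaged while
#' high-variance regions — edges — pass nearly unchanged. The noise power
#' is estimated as the mean of the local variances over the whole image.
#'
#' @param channel 2-D intensity matrix, at least 5x5.
#' @param size Window edge length (odd), default 5.
#' @return Denoised matrix of the same extent.
#' @export
wiener_denoise <- function(channel, size = 5L) {
  if (!is.matrix(channel) || nrow(channel) < size || ncol(channel) < size)
    stop("wiener_denoise needs a matrix of extent >= ", size, "x", size)
  mu <- .box_mean(channel, size)
  sig2 <- pmax(.box_mean(channel^2, size) - mu^2, 0)
  nu <- mean(sig2)
  gain <- ifelse(sig2 > nu, (sig2 - nu) / sig2, 0)
  mu + gain * (channel - mu)
}

# Separable Gaussian blur, replicate padding; kernel truncated at 3 sigma.
.gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (d in seq(-r, r)) out <- out + k[d + r + 1L] * .shift_rep(m, -d, 0L)
  res <- matrix(0, nrow(m), ncol(m))
  for (d in seq(-r, r)) res <- res + k[d + r + 1L] * .shift_rep(out, 0L, -d)
  res
}

#' Unsharp masking
#'
#' Sharpens by adding back the difference between the image and a
#' Gaussian-blurred copy: `out = x + amount * (x - blur(x))`, clipped to
#' the valid intensity range. Increases edge contrast, which helps the
#' Sobel step on faintly stained cells; the iteration count used during
#' segmentation is the user's knob, the amount and blur width are fixed
#' conventional defaults.
#'
#' @param channel 2-D intensity matrix.
#' @param amount Overshoot weight, default 1.
#' @param sigma Gaussian blur width in pixels, default 1.
#' @param max_value Upper clip bound (e.g. `2^bit_depth - 1`); default the
#'   input maximum.
#' @return Sharpened matrix of the same extent.
#' @export
unsharp_mask <- function(channel, amount = 1, sigma = 1,
                         max_value = max(channel)) {
  stopifnot(is.matrix(channel))
  out <- channel + amount * (channel - .gaussian_blur(channel, sigma))
  pmin(pmax(out, 0), max_value)
}

#' Otsu threshold
#'
#' Histogram-based binarization threshold chosen by exhaustive
#' maximization of the between-class variance over all observed integer
#' intensity levels. Foreground is `x > threshold`.
#'
#' @param channel 2-D matrix of non-negative integer intensities.
#' @return Scalar threshold (an observed intensity level).
#' @export
otsu_threshold <- function(channel) {
  v <- as.vector(channel)
  lev <- sort(unique(round(v)))
  if (length(lev) < 2L)
    stop("cannot threshold: image has fewer than two intensity levels")
  h <- tabulate(match(round(v), lev), nbins = length(lev))
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after level k (k < K)
  k <- seq_len(length(lev) - 1L)
  denom <- w0[k] * (1 - w0[k])
  bcv <- ifelse(denom > 0, (mu_t * w0[k] - mu[k])^2 / denom, -Inf)
  lev[which.max(bcv)]
}
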