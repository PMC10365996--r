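# Separable Gaussian / Gaussian-derivative filtering with reflect padding.
# These primitives back the multi-scale feature bank; EBImage's filter2 only
# offers circular/replicate borders and no derivative kernels, hence in-house.

#' Sampled Gaussian (derivative) kernel
#'
#' @param sigma kernel standard deviation in pixels (> 0).
#' @param order derivative order: 0 (smoothing), 1 (first derivative) or 2.
#' @param radius half-width in pixels; default `max(1, ceiling(3 * sigma))`.
#' @return numeric vector of length `2 * radius + 1`. Order 0 sums to 1;
#'   orders 1 and 2 have zero mean so constant images map to exactly zero.
#' @keywords internal
gauss_kernel <- function(sigma, order = 0L, radius = NULL) {
  stopifnot(sigma > 0, order %in% 0:2)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  k <- if (order == 1L) (-x / sigma^2) * g else (x^2 / sigma^4 - 1 / sigma^2) * g
  k - mean(k)
}

# Reflect (symmetric, edge repeated) padding on both axes.
pad_reflect <- function(m, pr, pc = pr) {
  nr <- nrow(m); nc <- ncol(m)
  if (pr >= nr || pc >= nc)
    stop("image too small (", nr, "x", nc, ") for padding radius ", max(pr, pc))
  ri <- c(rev(seq_len(pr)), seq_len(nr), nr + 1 - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(nc), nc + 1 - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

# Correlate each column (i.e. filter along rows dimension) of a padded matrix.
conv_cols <- function(p, k, n_out) {
  acc <- 0
  for (i in seq_along(k)) acc <- acc + k[i] * p[i:(i + n_out - 1L), , drop = FALSE]
  acc
}

#' Separable 2D correlation with reflect boundary
#'
#' Applies `k_row` along rows (vertical axis) and `k_col` along columns.
#' @keywords internal
sep_filter <- function(image, k_row, k_col = k_row) {
  pr <- (length(k_row) - 1L) %/% 2L
  pc <- (length(k_col) - 1L) %/% 2L
  p <- pad_reflect(image, pr, pc)
  p <- conv_cols(p, k_row, nrow(image))
  t(conv_cols(t(p), k_col, ncol(image)))
}

#' Gaussian smoothing of a 2D image (reflect boundary)
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` returns the input.
#' @return filtered matrix of identical dimensions.
#' @export
gaussian_smooth <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma >= 0)
  if (sigma == 0) return(image)
  sep_filter(image, gauss_kernel(sigma, 0L))
}

# Dense 2D correlation via FFT with zero padding ("same" output). Used by the
# Hough accumulator where wrap-around votes would fake circles at the border.
fft_filter_same <- function(image, kern) {
  nr <- nrow(image); nc <- ncol(image)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  a <- matrix(0, pr, pc); a[1:nr, 1:nc] <- image
  b <- matrix(0, pr, pc); b[1:kr, 1:kc] <- kern
  full <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), drop = FALSE]
}

# Binary morphology on masks via EBImage (disc brush).
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask + 0, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")) > 0
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::erode(mask + 0, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")) > 0
}
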