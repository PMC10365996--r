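# Multi-scale pixel feature bank for cell/background classification.
#
# Channel layout (37 channels with the default scales):
#   1-7    Gaussian smoothing at sigma = 0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0
#   then, for each sigma in {0.7, 1.0, 1.6, 3.5, 5.0, 10.0}, in this order:
#   laplacian_of_gaussian, gradient_magnitude, difference_of_gaussians,
#   structure_tensor_eig1, hessian_eig1
# Eigenvalue features report the largest eigenvalue, so each contributes one
# channel and the bank totals 7 + 5 * 6 = 37.

#' Multi-scale pixel features
#'
#' Computes per-pixel Gaussian, Laplacian-of-Gaussian, Gaussian gradient
#' magnitude, difference-of-Gaussians, structure-tensor and
#' Hessian-of-Gaussian eigenvalue features at several scales, with reflect
#' boundary handling. With the default scales every pixel gets a 37-vector.
#'
#' @param image 2D numeric matrix of intensities. Must be larger than the
#'   widest kernel: with the default scales (difference-of-Gaussians at
#'   scale 10 smooths at 16 px, radius 48) the image needs at least 49 px
#'   per side; smaller inputs raise an informative error.
#' @param scales_gaussian scales (pixels) for plain Gaussian smoothing.
#' @param scales_other scales for the five derivative-based features.
#' @return 3D array `nrow x ncol x n_channels`, class `feature_stack`, with
#'   channel names in `dimnames(...)[[3]]`.
#' @export
compute_pixel_features <- function(image,
                                   scales_gaussian = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0),
                                   scales_other = c(0.7, 1.0, 1.6, 3.5, 5.0, 10.0)) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2D numeric matrix")
  if (any(!is.finite(image))) stop("image must be finite-valued")
  nch <- length(scales_gaussian) + 5L * length(scales_other)
  out <- array(0, dim = c(nrow(image), ncol(image), nch))
  nm <- character(nch)
  i <- 0L
  for (s in scales_gaussian) {
    i <- i + 1L
    out[, , i] <- gaussian_smooth(image, s)
    nm[i] <- sprintf("gaussian_s%g", s)
  }
  for (s in scales_other) {
    g0 <- gauss_kernel(s, 0L)
    g1 <- gauss_kernel(s, 1L)
    g2 <- gauss_kernel(s, 2L)
    ixx <- sep_filter(image, g2, g0)   # d2/drow2
    iyy <- sep_filter(image, g0, g2)
    ixy <- sep_filter(image, g1, g1)
    ix  <- sep_filter(image, g1, g0)
    iy  <- sep_filter(image, g0, g1)
    # structure tensor: gradient outer products smoothed at the same scale
    jxx <- gaussian_smooth(ix * ix, s)
    jyy <- gaussian_smooth(iy * iy, s)
    jxy <- gaussian_smooth(ix * iy, s)
    st_eig <- 0.5 * ((jxx + jyy) + sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0)))
    h_eig <- 0.5 * ((ixx + iyy) + sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0)))
    dog <- gaussian_smooth(image, s) - gaussian_smooth(image, 1.6 * s)
    blocks <- list(laplacian_of_gaussian = ixx + iyy,
                   gradient_magnitude = sqrt(ix^2 + iy^2),
                   difference_of_gaussians = dog,
                   structure_tensor_eig1 = st_eig,
                   hessian_eig1 = h_eig)
    for (b in names(blocks)) {
      i <- i + 1L
      out[, , i] <- blocks[[b]]
      nm[i] <- sprintf("%s_s%g", b, s)
    }
  }
  dimnames(out) <- list(NULL, NULL, nm)
  class(out) <- c("feature_stack", class(out))
  out
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Feature stack: %d x %d px, %d channels\n", d[1L], d[2L], d[3L]))
  invisible(x)
}

feature_channels <- function(features) dimnames(features)[[3L]]

# Flatten a feature stack to a pixels x channels matrix.
features_as_matrix <- function(features) {
  d <- dim(features)
  m <- matrix(as.numeric(features), d[1L] * d[2L], d[3L])
  colnames(m) <- feature_channels(features)
  m
}
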