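# Circular Hough transform for microwell boundary detection.

#' Detect the microwell boundary circle
#'
#' Edge pixels (Gaussian gradient magnitude above its Otsu threshold) vote
#' for circle centers by correlation with one-pixel-wide ring kernels over a
#' radius range; the vote map uses zero padding so border wrap-around cannot
#' fake circles. Scores are votes normalised by ring circumference; ties are
#' broken by higher score, then smaller radius.
#'
#' @param image 2D intensity matrix (typically the first frame of a well
#'   crop).
#' @param radius_range integer vector of candidate radii in pixels.
#' @param score_threshold minimum fraction of the circumference supported by
#'   edges (default 0.25).
#' @param edge_sigma Gaussian-derivative scale for the edge map (pixels).
#' @return object of class `well_circle`: `center` (0-based row/col),
#'   `radius`, `score`.
#' @export
detect_well_circle <- function(image, radius_range, score_threshold = 0.25,
                               edge_sigma = 1.5) {
  stopifnot(is.matrix(image), all(radius_range >= 2))
  radii <- sort(unique(as.integer(round(radius_range))))
  if (max(radii) * 2L >= min(dim(image)))
    stop("radius range exceeds image size")
  g0 <- gauss_kernel(edge_sigma, 0L); g1 <- gauss_kernel(edge_sigma, 1L)
  gm <- sqrt(sep_filter(image, g1, g0)^2 + sep_filter(image, g0, g1)^2)
  if (diff(range(gm)) < .Machine$double.eps^0.5)
    stop("well circle detection failed: image has no edges")
  thr <- EBImage::otsu(gm / max(gm), range = c(0, 1), levels = 256L) * max(gm)
  edges <- (gm > thr) + 0
  best <- NULL
  for (r in radii) {
    k <- ring_kernel(r)
    votes <- fft_filter_same(edges, k)
    score <- votes / sum(k)
    j <- which.max(score)
    s <- score[j]
    if (is.null(best) || s > best$score + 1e-12) {
      rc <- arrayInd(j, dim(score))
      best <- list(center = c(rc[1L] - 1L, rc[2L] - 1L), radius = r, score = s)
    }
  }
  # chance level: a random edge field of this density supports any ring in
  # proportion to the density, so demand a clear margin above it
  floor_score <- max(score_threshold, 3 * mean(edges > 0))
  if (best$score < floor_score)
    stop(sprintf(paste0("well circle detection failed: best score %.3f < %.3f ",
                        "(radius %d at center %d,%d; %d edge px)"),
                 best$score, floor_score, best$radius,
                 best$center[1L], best$center[2L], sum(edges)))
  structure(best, class = "well_circle")
}

#' @export
print.well_circle <- function(x, ...) {
  cat(sprintf("Well circle: center (%d, %d), radius %d px, score %.3f\n",
              x$center[1L], x$center[2L], x$radius, x$score))
  invisible(x)
}

# One-pixel-wide ring of radius r as a (2r+3)^2 kernel.
ring_kernel <- function(r) {
  n <- 2L * r + 3L
  c0 <- r + 2L
  d <- sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+"))
  (abs(d - r) <= 0.5) + 0
}

#' Disc mask for a detected circle
#'
#' @param circle a `well_circle`.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param shrink erode the disc by this many pixels (default 0).
#' @return logical matrix, `TRUE` inside the (shrunk) circle.
#' @export
circle_mask <- function(circle, dim, shrink = 0) {
  r <- circle$radius - shrink
  dr <- outer((seq_len(dim[1L]) - 1 - circle$center[1L])^2,
              (seq_len(dim[2L]) - 1 - circle$center[2L])^2, "+")
  dr <= r^2
}
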