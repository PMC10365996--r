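# Difference imaging, reference-well drift correction, and assembly of the
# 4D spatiotemporal secretion maps.

#' Absolute difference stack
#'
#' Per-frame pixel-wise absolute difference from the first frame,
#' `dI(t) = |I(t) - I(1)|`, optionally Gaussian-smoothed (the smoothing is
#' applied to the difference images, not the raw frames).
#'
#' @param well a `well_stack` or [image_stack()] with at least two frames.
#' @param sigma Gaussian smoothing sd in pixels (default 1.5; 0 disables).
#' @return object of class `diff_stack`: `frames` (first identically zero),
#'   `times`, `sigma`.
#' @export
difference_stack <- function(well, sigma = 1.5) {
  stack <- if (inherits(well, "well_stack")) well$stack else well
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 2L) stop("difference imaging needs at least 2 frames")
  ref <- stack$frames[[1L]]
  frames <- lapply(stack$frames, function(f) {
    d <- abs(f - ref)
    if (sigma > 0) d <- gaussian_smooth(d, sigma)
    d
  })
  frames[[1L]] <- matrix(0, nrow(ref), ncol(ref))
  structure(list(frames = frames, times = stack$times, sigma = sigma),
            class = "diff_stack")
}

#' Reference-well background level series
#'
#' For each frame the background level is `mean + 3 * sd` of the reference
#' well's difference image over a fixed region of interest, propagated along
#' the time lapse.
#'
#' @param ref_diff a `diff_stack` from the reference well.
#' @param roi region of interest `c(row0, col0, height, width)` (0-based
#'   origin). Default: a 50x50 window centred in the frame (clipped to fit).
#' @return object of class `background_levels`: numeric `level` per frame,
#'   plus `times` and the `roi` used.
#' @export
reference_level <- function(ref_diff, roi = NULL) {
  stopifnot(inherits(ref_diff, "diff_stack"))
  d <- dim(ref_diff$frames[[1L]])
  if (is.null(roi)) {
    side <- min(50L, d[1L], d[2L])
    roi <- c((d[1L] - side) %/% 2L, (d[2L] - side) %/% 2L, side, side)
  }
  roi <- as.integer(roi)
  if (roi[1L] < 0L || roi[2L] < 0L || roi[1L] + roi[3L] > d[1L] ||
      roi[2L] + roi[4L] > d[2L]) stop("ROI exceeds frame bounds")
  if (roi[3L] * roi[4L] < 4L) stop("ROI must cover at least 4 pixels")
  ri <- (roi[1L] + 1L):(roi[1L] + roi[3L])
  ci <- (roi[2L] + 1L):(roi[2L] + roi[4L])
  level <- vapply(ref_diff$frames, function(f) {
    v <- f[ri, ci]
    mean(v) + 3 * stats::sd(v)
  }, numeric(1L))
  structure(list(level = level, times = ref_diff$times, roi = roi),
            class = "background_levels")
}

#' Subtract the reference background level
#'
#' Pixel-wise subtraction of the per-frame reference level from the sensing
#' difference stack; negative results are clamped to zero so the mean + 3 sd
#' level acts as a one-sided noise gate.
#'
#' @param sens_diff `diff_stack` of the sensing well.
#' @param levels [reference_level()] series with matching frame count.
#' @return corrected `diff_stack`.
#' @export
subtract_background <- function(sens_diff, levels) {
  stopifnot(inherits(sens_diff, "diff_stack"), inherits(levels, "background_levels"))
  if (length(levels$level) != length(sens_diff$frames))
    stop("frame count mismatch between sensing stack and background levels")
  frames <- mapply(function(f, l) pmax(f - l, 0), sens_diff$frames, levels$level,
                   SIMPLIFY = FALSE)
  structure(list(frames = frames, times = sens_diff$times, sigma = sens_diff$sigma),
            class = "diff_stack")
}

#' Prune small, distant intensity clusters
#'
#' K-means clustering of non-zero pixel coordinates; clusters that are both
#' smaller than `min_size` and farther than `max_dist` from the cell centroid
#' are zeroed, iterating until no cluster is removed.
#'
#' @param map_frame nonnegative 2D matrix (one secretion-map frame).
#' @param k number of clusters (default 4).
#' @param min_size minimum cluster size in pixels (default 20).
#' @param max_dist maximum allowed centroid distance in pixels.
#' @param cell_centroid cell centroid `c(row, col)`, 0-based pixels.
#' @param seed RNG seed for k-means initialisation (default 0).
#' @return pruned matrix.
#' @export
prune_clusters <- function(map_frame, k = 4L, min_size = 20L, max_dist,
                           cell_centroid, seed = 0L) {
  stopifnot(is.matrix(map_frame), all(map_frame >= 0), k >= 1L)
  out <- map_frame
  repeat {
    idx <- which(out > 0, arr.ind = TRUE)
    if (nrow(idx) <= k) return(out)
    km <- with_local_seed(seed,
      stats::kmeans(idx, centers = min(k, nrow(idx) - 1L), nstart = 5L,
                    iter.max = 50L))
    sizes <- tabulate(km$cluster, nbins = nrow(km$centers))
    cd <- sqrt((km$centers[, 1L] - 1 - cell_centroid[1L])^2 +
               (km$centers[, 2L] - 1 - cell_centroid[2L])^2)
    drop <- which(sizes < min_size & cd > max_dist)
    if (!length(drop)) return(out)
    kill <- idx[km$cluster %in% drop, , drop = FALSE]
    out[kill] <- 0
  }
}

#' Automated secretion region of interest
#'
#' Interactive analyses restrict secretion maps to a human-chosen ROI that
#' excludes well-edge artefacts; unattended runs here default to an annulus:
#' inside the well circle eroded by `margin`, outside the final cumulative
#' cell mask dilated by `cell_margin`.
#'
#' @param circle a `well_circle`.
#' @param final_mask final cumulative cell mask (logical matrix).
#' @param margin erosion of the well circle in pixels (default 5).
#' @param cell_margin dilation of the cell mask in pixels. Smoothing of the
#'   difference images spreads cell-motion artefacts by roughly 3 sigma, so
#'   callers should keep this above `3 * sigma` (default 7, matching the
#'   default `sigma = 1.5` plus safety).
#' @return logical matrix, `TRUE` where secretion is admissible.
#' @export
secretion_roi <- function(circle, final_mask, margin = 5L, cell_margin = 7L) {
  inner <- circle_mask(circle, dim(final_mask), shrink = margin)
  inner & !dilate_mask(final_mask, cell_margin)
}

#' Build the 4D spatiotemporal secretion map stack
#'
#' Full mapping pipeline for one sensing/reference well pair: difference
#' imaging, reference-level subtraction, restriction to the well circle and
#' secretion ROI, optional K-means cluster pruning, and exclusion of every
#' pixel ever occupied by the cell (complement of the cumulative mask).
#'
#' @param pair a `well_pair` from [pair_wells()], or a list with `sensing`
#'   and `reference` well stacks.
#' @param masks per-frame cell masks (list of logical matrices); the
#'   cumulative union is formed internally.
#' @param circle optional `well_circle`; auto-detected from the first
#'   sensing frame when `NULL`.
#' @param sigma Gaussian smoothing sd for difference images (default 1.5).
#' @param ref_roi reference-well ROI (see [reference_level()]).
#' @param roi optional logical matrix overriding the automated
#'   [secretion_roi()] annulus.
#' @param roi_margin,cell_margin annulus parameters (see [secretion_roi()]).
#' @param prune enable K-means cluster pruning (default `FALSE`).
#' @param prune_k,prune_min_size cluster pruning parameters; the distance
#'   cutoff defaults to half the well radius.
#' @param radius_range candidate radii for circle detection; default
#'   0.3-0.48 of the crop side.
#' @return object of class `secretion_maps`: `frames` (nonnegative, zero
#'   outside the ROI and inside the cumulative mask), `times`, `circle`,
#'   `roi`, `cumulative_masks` and a `provenance` list recording each step.
#' @export
build_secretion_maps <- function(pair, masks, circle = NULL, sigma = 1.5,
                                 ref_roi = NULL, roi = NULL, roi_margin = 5L,
                                 cell_margin = ceiling(3 * sigma) + 2L,
                                 prune = FALSE, prune_k = 4L,
                                 prune_min_size = 20L, radius_range = NULL) {
  sens <- pair$sensing; ref <- pair$reference
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("secretion mapping failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  sd_ <- stage("difference", difference_stack(sens, sigma = sigma))
  rd_ <- stage("difference", difference_stack(ref, sigma = sigma))
  lv <- stage("reference_level", reference_level(rd_, roi = ref_roi))
  corr <- stage("subtract_background", subtract_background(sd_, lv))
  d <- dim(corr$frames[[1L]])
  if (is.null(circle)) {
    if (is.null(radius_range))
      radius_range <- seq.int(max(2L, floor(0.30 * min(d))), floor(0.48 * min(d)))
    circle <- stage("detect_well_circle",
                    detect_well_circle(sens$stack$frames[[1L]], radius_range))
  }
  cum <- stage("accumulate_masks", accumulate_masks(masks))
  admissible <- if (is.null(roi)) {
    stage("secretion_roi",
          secretion_roi(circle, cum[[length(cum)]], roi_margin, cell_margin))
  } else roi & circle_mask(circle, d)
  max_dist <- circle$radius / 2
  frames <- vector("list", length(corr$frames))
  for (t in seq_along(frames)) {
    f <- corr$frames[[t]]
    f[!admissible] <- 0
    if (prune && any(f > 0)) {
      ct <- which(cum[[t]], arr.ind = TRUE)
      centroid <- if (nrow(ct)) c(mean(ct[, 1L]) - 1, mean(ct[, 2L]) - 1)
                  else (d - 1) / 2
      f <- prune_clusters(f, k = prune_k, min_size = prune_min_size,
                          max_dist = max_dist, cell_centroid = centroid)
    }
    f[cum[[t]]] <- 0
    frames[[t]] <- f
  }
  structure(
    list(frames = frames, times = corr$times, circle = circle,
         roi = admissible, cumulative_masks = cum,
         provenance = list(
           sensing_well = sens$well_id, reference_well = ref$well_id,
           sigma = sigma, ref_roi = lv$roi,
           circle = unclass(circle)[c("center", "radius", "score")],
           roi_margin = roi_margin, cell_margin = cell_margin,
           prune = prune,
           prune_params = if (prune) list(k = prune_k, min_size = prune_min_size,
                                          max_dist = max_dist) else NULL)),
    class = "secretion_maps")
}

#' @export
print.secretion_maps <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Secretion map stack: %d frames of %d x %d px\n",
              length(x$frames), d[1L], d[2L]))
  print(x$circle)
  invisible(x)
}

#' Export secretion maps as a 32-bit float TIFF plus JSON provenance sidecar
#'
#' @param maps a `secretion_maps` object.
#' @param path output TIFF path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly. Frames are scaled to `[0, 1]` by the global
#'   maximum, which the sidecar records as `intensity_scale`.
#' @export
write_secretion_maps <- function(maps, path) {
  mx <- max(1e-12, vapply(maps$frames, max, numeric(1L)))
  tiff::writeTIFF(lapply(maps$frames, function(f) f / mx), path,
                  bits.per.sample = 32L)
  side <- c(maps$provenance, list(intensity_scale = mx, times_min = maps$times))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
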