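# Random-forest pixel classification: training on sparse labels, probability
# maps, mean-filter + Otsu binarization, cumulative masks, track metrics.

#' Train a random-forest pixel classifier
#'
#' Trains a cell/background random forest (default 100 trees) on sparsely
#' labelled pixels. Labels follow the sparse-label-image convention:
#' 0 = unlabelled, 1 = cell, 2 = background.
#'
#' @param features a `feature_stack` (see [compute_pixel_features()]) or a
#'   list of them.
#' @param labels integer matrix matching each feature stack spatially
#'   (or a list of such matrices).
#' @param n_trees number of trees (default 100).
#' @param seed RNG seed for reproducible forests (default 0).
#' @param holdout fraction of labelled pixels held out to report accuracy
#'   (default 0.2; out-of-bag error is reported as well).
#' @return object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, labels, n_trees = 100L, seed = 0L,
                                   holdout = 0.2) {
  if (inherits(features, "feature_stack")) features <- list(features)
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(length(features) == length(labels))
  xs <- list(); ys <- list()
  for (i in seq_along(features)) {
    f <- features[[i]]; l <- labels[[i]]
    stopifnot(identical(dim(f)[1:2], dim(l)))
    sel <- which(l != 0L)
    if (length(sel)) {
      xs[[length(xs) + 1L]] <- features_as_matrix(f)[sel, , drop = FALSE]
      ys[[length(ys) + 1L]] <- ifelse(l[sel] == 1L, "cell", "background")
    }
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = c("cell", "background"))
  if (is.null(x) || length(unique(y)) < 2L)
    stop("training requires labelled pixels from both classes")
  res <- with_local_seed(seed, {
    n <- nrow(x)
    idx_test <- if (holdout > 0 && n >= 10L) sample.int(n, max(1L, round(holdout * n)))
                else integer(0)
    idx_train <- setdiff(seq_len(n), idx_test)
    rf <- randomForest::randomForest(x[idx_train, , drop = FALSE], y[idx_train],
                                     ntree = as.integer(n_trees))
    acc <- if (length(idx_test)) {
      pred <- stats::predict(rf, x[idx_test, , drop = FALSE])
      mean(pred == y[idx_test])
    } else NA_real_
    list(rf = rf, acc = acc)
  })
  structure(
    list(forest = res$rf,
         n_trees = as.integer(n_trees),
         channels = colnames(x),
         seed = as.integer(seed),
         training_summary = c(table(y)),
         holdout_accuracy = res$acc,
         oob_error = res$rf$err.rate[n_trees, "OOB"]),
    class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("Pixel classifier: %d trees, %d feature channels (seed %d)\n",
              x$n_trees, length(x$channels), x$seed))
  cat(sprintf("  labelled px: cell %d, background %d\n",
              x$training_summary[["cell"]], x$training_summary[["background"]]))
  cat(sprintf("  held-out accuracy %.3f, OOB error %.3f\n",
              x$holdout_accuracy, x$oob_error))
  invisible(x)
}

#' Predict a background-probability map
#'
#' Per-pixel probability of class background, from 0 (certainly cell) to 1
#' (certainly background).
#'
#' @param model a [train_pixel_classifier()] fit.
#' @param image 2D intensity matrix, or a precomputed `feature_stack`.
#' @return numeric matrix in `[0, 1]` with the image's dimensions.
#' @export
predict_probability_map <- function(model, image) {
  stopifnot(inherits(model, "pixel_classifier"))
  features <- if (inherits(image, "feature_stack")) image else
    compute_pixel_features(image)
  if (!identical(feature_channels(features), model$channels))
    stop("feature bank mismatch: model was trained on different channels")
  m <- features_as_matrix(features)
  p <- stats::predict(model$forest, m, type = "prob")[, "background"]
  matrix(p, dim(features)[1L], dim(features)[2L])
}

#' Binarize a probability map into a cell mask
#'
#' Smooths the background-probability map with an arithmetic mean filter,
#' then thresholds with Otsu's method; pixels below the threshold are cell.
#'
#' @param probmap matrix of background probabilities in `[0, 1]`.
#' @param filter_radius mean-filter radius in pixels (kernel side
#'   `2 * radius + 1`; default 1, i.e. 3x3).
#' @return logical matrix, `TRUE` = cell. A constant map yields an empty
#'   mask with a warning (no threshold exists).
#' @export
binarize_probability_map <- function(probmap, filter_radius = 1L) {
  stopifnot(is.matrix(probmap), all(probmap >= 0 & probmap <= 1))
  k <- rep(1, 2L * filter_radius + 1L)
  sm <- if (filter_radius > 0) sep_filter(probmap, k / length(k)) else probmap
  if (diff(range(sm)) < .Machine$double.eps^0.5) {
    warning("constant probability map: no Otsu threshold, returning empty mask")
    return(matrix(FALSE, nrow(probmap), ncol(probmap)))
  }
  thr <- EBImage::otsu(pmin(pmax(sm, 0), 1), range = c(0, 1), levels = 256L)
  sm < thr
}

#' Cumulative union of cell masks
#'
#' `cumulative[[t]]` flags every pixel occupied by the cell in any frame up
#' to and including `t`; monotone non-decreasing in `t`.
#'
#' @param masks list of logical matrices of equal dimensions.
#' @return list of logical matrices of the same length.
#' @export
accumulate_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1L]])
  out <- vector("list", length(masks))
  acc <- matrix(FALSE, d[1L], d[2L])
  for (t in seq_along(masks)) {
    if (!identical(dim(masks[[t]]), d)) stop("mask dimensions differ at frame ", t)
    acc <- acc | masks[[t]]
    out[[t]] <- acc
  }
  out
}

#' Per-frame cell morphology and motility metrics
#'
#' Keeps the largest connected component per frame (both components when two
#' are comparable, size ratio > 0.5, as during division) and reports centroid
#' and area in physical units plus the mean squared displacement
#' `MSD = mean_t |centroid(t) - centroid(0)|^2`, averaged over the frames
#' after the first (the zero self-displacement is not counted).
#'
#' @param masks list of per-frame logical cell masks.
#' @param meta an [acquisition_meta()], or a scalar pixel size in um/px.
#' @return object of class `cell_track`: data frame (`time_index`,
#'   `centroid_row_um`, `centroid_col_um`, `area_um2`, `n_components`) with
#'   attributes `msd_um2` and `boundaries` (per-frame contour polygon, px).
#' @export
track_metrics <- function(masks, meta) {
  px <- if (inherits(meta, "acquisition_meta")) object_pixel_size(meta) else meta
  stopifnot(px > 0)
  rows <- vector("list", length(masks))
  boundaries <- vector("list", length(masks))
  for (t in seq_along(masks)) {
    m <- masks[[t]]
    lab <- EBImage::bwlabel(m + 0)
    sizes <- tabulate(lab[lab > 0])
    if (!length(sizes)) {
      rows[[t]] <- data.frame(time_index = t - 1L, centroid_row_um = NA_real_,
                              centroid_col_um = NA_real_, area_um2 = 0,
                              n_components = 0L)
      next
    }
    keep <- which.max(sizes)
    # division: keep a second component of comparable size
    if (length(sizes) > 1L) {
      second <- order(sizes, decreasing = TRUE)[2L]
      if (sizes[second] / sizes[keep] > 0.5) keep <- c(keep, second)
    }
    sel <- lab %in% keep & m
    idx <- which(sel, arr.ind = TRUE)
    rows[[t]] <- data.frame(
      time_index = t - 1L,
      centroid_row_um = (mean(idx[, 1L]) - 1) * px,
      centroid_col_um = (mean(idx[, 2L]) - 1) * px,
      area_um2 = nrow(idx) * px^2,
      n_components = length(keep))
    oc <- EBImage::ocontour(EBImage::bwlabel(sel + 0))
    boundaries[[t]] <- if (length(oc)) oc[[1L]] else NULL
  }
  df <- do.call(rbind, rows)
  ok <- !is.na(df$centroid_row_um)
  msd <- if (sum(ok) > 1L) {
    first <- which(ok)[1L]
    later <- setdiff(which(ok), first)
    r0 <- df[first, c("centroid_row_um", "centroid_col_um")]
    mean((df$centroid_row_um[later] - r0[[1L]])^2 +
         (df$centroid_col_um[later] - r0[[2L]])^2)
  } else NA_real_
  structure(df, msd_um2 = msd, boundaries = boundaries, empty = !any(ok),
            class = c("cell_track", "data.frame"))
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("Cell track: %d frames, MSD %.3g um^2%s\n", nrow(x),
              attr(x, "msd_um2"),
              if (isTRUE(attr(x, "empty"))) " [no cell detected]" else ""))
  invisible(x)
}

# Evaluate expr under a temporary RNG state so library RNG use (forests,
# k-means) is reproducible without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
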