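# Image stacks, well crops, sensing/reference pairing, and TIFF I/O.
# Coordinates are 0-based (row, col) with origin top-left; crop windows are
# half-open [r0, r0 + side) x [c0, c0 + side).

#' Construct an image stack
#'
#' @param frames list of numeric matrices of identical dimensions
#'   (nonnegative grey levels).
#' @param times per-frame acquisition times in minutes, strictly increasing.
#' @return object of class `image_stack` with elements `frames` and `times`.
#' @export
image_stack <- function(frames, times) {
  stopifnot(is.list(frames), length(frames) >= 1L, length(times) == length(frames))
  d <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f)) stop("frames must be matrices")
    if (!identical(dim(f), d)) stop("all frames must share identical dimensions")
    if (any(!is.finite(f)) || any(f < 0)) stop("intensities must be finite and >= 0")
  }
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times)), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Image stack: %d frame(s) of %d x %d px, t = %g..%g min\n",
              length(x$frames), d[1L], d[2L], x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames)

#' Read a multi-page grayscale TIFF time lapse
#'
#' Frames are taken in page order; times default to `index * frame_interval`
#' (first frame at 0) unless per-page `DateTime`-free timestamps are supplied
#' via `times`.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param meta an [acquisition_meta()] giving the frame interval.
#' @param times optional explicit per-frame times (minutes), overriding
#'   `index * frame_interval`.
#' @return an [image_stack()] with integer grey levels.
#' @export
read_timelapse <- function(path, meta, times = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] > 1L) stop("color TIFF pages are not supported")
      p <- p[, , 1L]
    }
    storage.mode(p) <- "double"
    p
  })
  d <- dim(frames[[1L]])
  if (any(!vapply(frames, function(f) identical(dim(f), d), logical(1L))))
    stop("ragged TIFF: pages differ in size")
  if (is.null(times)) times <- (seq_along(frames) - 1L) * meta$frame_interval
  image_stack(frames, times)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer grey levels are stored bit-exactly at the given bit depth.
#'
#' @param stack an [image_stack()] or `well_stack`.
#' @param path output path.
#' @param bits bits per sample (8, 16, or 32 for float data).
#' @export
write_timelapse <- function(stack, path, bits = 16L) {
  if (inherits(stack, "well_stack")) stack <- stack$stack
  stopifnot(inherits(stack, "image_stack"))
  if (bits == 32L) {
    mx <- max(1, vapply(stack$frames, max, numeric(1L)))
    pages <- lapply(stack$frames, function(f) f / mx)
  } else {
    top <- 2^bits - 1
    if (any(vapply(stack$frames, max, numeric(1L)) > top))
      stop("grey levels exceed ", bits, "-bit range")
    pages <- lapply(stack$frames, function(f) f / top)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Crop a square well region from every frame
#'
#' @param stack an [image_stack()].
#' @param center `(row, col)` center in 0-based pixel coordinates.
#' @param side window side length in pixels (default 350).
#' @param well_id identifier for the crop.
#' @param role `"sensing"` or `"reference"`.
#' @return object of class `well_stack`: the cropped [image_stack()] plus
#'   `well_id`, `role` and `crop_origin` (0-based row/col of the top-left
#'   corner in the parent frame).
#' @export
crop_well_region <- function(stack, center, side = 350L, well_id = "well",
                             role = c("sensing", "reference")) {
  role <- match.arg(role)
  stopifnot(inherits(stack, "image_stack"), length(center) == 2L, side >= 1L)
  d <- dim(stack$frames[[1L]])
  r0 <- as.integer(round(center[1L])) - side %/% 2L
  c0 <- as.integer(round(center[2L])) - side %/% 2L
  if (r0 < 0L || c0 < 0L || r0 + side > d[1L] || c0 + side > d[2L])
    stop(sprintf("crop window [%d,%d)+%d exceeds %d x %d frame", r0, c0, side,
                 d[1L], d[2L]))
  frames <- lapply(stack$frames, function(f)
    f[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE])
  structure(
    list(stack = image_stack(frames, stack$times),
         well_id = well_id, role = role, crop_origin = c(r0, c0)),
    class = "well_stack")
}

#' @export
print.well_stack <- function(x, ...) {
  cat(sprintf("Well '%s' (%s), origin (%d,%d)\n", x$well_id, x$role,
              x$crop_origin[1L], x$crop_origin[2L]))
  print(x$stack)
  invisible(x)
}

#' Pair sensing wells with their reference wells
#'
#' @param wells list of `well_stack` objects (mixed roles), named or carrying
#'   `well_id`s.
#' @param layout named character vector or list mapping sensing well id to
#'   reference well id.
#' @return list of `well_pair` objects (`sensing`, `reference`).
#' @export
pair_wells <- function(wells, layout) {
  ids <- vapply(wells, function(w) w$well_id, character(1L))
  names(wells) <- ids
  layout <- unlist(layout)
  pairs <- lapply(names(layout), function(sid) {
    rid <- layout[[sid]]
    if (!sid %in% ids) stop("sensing well '", sid, "' not found")
    if (!rid %in% ids) stop("reference well '", rid, "' not found")
    s <- wells[[sid]]; r <- wells[[rid]]
    if (n_frames(s$stack) != n_frames(r$stack))
      stop("frame count mismatch between '", sid, "' and '", rid, "'")
    if (!isTRUE(all.equal(s$stack$times, r$stack$times)))
      stop("acquisition times differ between '", sid, "' and '", rid, "'")
    structure(list(sensing = s, reference = r), class = "well_pair")
  })
  names(pairs) <- names(layout)
  pairs
}
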