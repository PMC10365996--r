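#' Acquisition metadata
#'
#' Bundles the camera/objective parameters needed to convert between pixels
#' and physical units and to time-stamp frames.
#'
#' @param frame_interval time between frames, minutes (> 0).
#' @param camera_pixel_pitch sensor pixel size, micrometres (> 0). The sCMOS
#'   camera used for plasmonic intensity imaging has 4.25 um pixels.
#' @param magnification objective magnification (> 0), e.g. 20.
#' @param binning camera binning factor (integer >= 1).
#' @param bit_depth camera bit depth (e.g. 8 or 16).
#' @return object of class `acquisition_meta`.
#' @examples
#' meta <- acquisition_meta(frame_interval = 10)
#' object_pixel_size(meta)  # 0.2125 um/px
#' @export
acquisition_meta <- function(frame_interval = 10,
                             camera_pixel_pitch = 4.25,
                             magnification = 20,
                             binning = 1L,
                             bit_depth = 16L) {
  stopifnot(frame_interval > 0, camera_pixel_pitch > 0, magnification > 0)
  binning <- as.integer(binning)
  stopifnot(binning >= 1L)
  structure(
    list(frame_interval = frame_interval,
         camera_pixel_pitch = camera_pixel_pitch,
         magnification = magnification,
         binning = binning,
         bit_depth = as.integer(bit_depth)),
    class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("Acquisition metadata\n")
  cat(sprintf("  frame interval : %g min\n", x$frame_interval))
  cat(sprintf("  pixel pitch    : %g um (binning %d, x%g objective)\n",
              x$camera_pixel_pitch, x$binning, x$magnification))
  cat(sprintf("  object pixel   : %g um/px\n", object_pixel_size(x)))
  invisible(x)
}

#' Object-plane pixel size
#'
#' Physical size of one image pixel at the sample plane:
#' `camera_pixel_pitch * binning / magnification`.
#'
#' @param meta an [acquisition_meta()] object.
#' @return micrometres per pixel (scalar).
#' @export
object_pixel_size <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  meta$camera_pixel_pitch * meta$binning / meta$magnification
}

#' Field-of-view extent
#'
#' Physical width/height imaged by a sensor of `sensor_px` pixels.
#'
#' @param meta an [acquisition_meta()] object.
#' @param sensor_px number of sensor pixels along the axis (one or two values).
#' @return extent in millimetres, same length as `sensor_px`.
#' @examples
#' field_of_view(acquisition_meta(), c(5056, 2960))  # ~1.07 x 0.63 mm
#' @export
field_of_view <- function(meta, sensor_px) {
  stopifnot(all(sensor_px > 0))
  sensor_px * object_pixel_size(meta) / 1000
}

#' Microwell volume
#'
#' Volume of a cylindrical microwell in nanolitres.
#'
#' @param diameter_um well diameter, micrometres (default 200).
#' @param height_um well height, micrometres (default 50).
#' @return volume in nanolitres. The default 200 um x 50 um well holds
#'   ~1.57 nl.
#' @export
microwell_volume <- function(diameter_um = 200, height_um = 50) {
  stopifnot(diameter_um > 0, height_um > 0)
  pi * (diameter_um / 2)^2 * height_um * 1e-6  # um^3 -> nl
}
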