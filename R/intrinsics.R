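#' Pinhole camera intrinsics
#'
#' Bundle of pinhole parameters relating image pixels to metric rays in the
#' camera frame. Pixel coordinates are 0-based with the pixel-centre
#' convention: column `u` and row `v` index into the image, `(cx, cy)` is the
#' principal point in the same units. `depth_scale` converts raw stored depth
#' counts to metres (0.001 for millimetre 16-bit PNGs).
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels; must lie inside the frame.
#' @param width,height Frame size in pixels.
#' @param depth_scale Metres per stored depth unit (default 0.001).
#' @return An object of class `camera_intrinsics`.
#' @examples
#' intr <- camera_intrinsics(fx = 425, fy = 425, cx = 424, cy = 240,
#'                           width = 848, height = 480)
#' backproject_pixel(424, 240, 3000, intr)  # principal-point ray at 3 m
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height,
                              depth_scale = 0.001) {
  stopifnot(is.numeric(fx), is.numeric(fy), is.numeric(cx), is.numeric(cy))
  if (fx <= 0 || fy <= 0)
    stop("focal lengths fx, fy must be positive")
  if (width <= 0 || height <= 0 || width != round(width) || height != round(height))
    stop("width and height must be positive integers")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point (cx, cy) must lie inside the frame")
  if (depth_scale <= 0)
    stop("depth_scale must be positive")
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         cx = as.numeric(cx), cy = as.numeric(cy),
         width = as.integer(width), height = as.integer(height),
         depth_scale = as.numeric(depth_scale)),
    class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "<camera_intrinsics> %dx%d  fx=%.3f fy=%.3f cx=%.3f cy=%.3f depth_scale=%g\n",
    x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$depth_scale))
  invisible(x)
}

#' Default intrinsics for the overhead 848x480 depth camera
#'
#' Nominal pinhole model for an 848x480 RGB-D stream from a wide-FOV stereo
#' depth camera mounted ~3 m above the floor, with millimetre depth units.
#'
#' @return A [camera_intrinsics] object.
#' @export
default_intrinsics <- function() {
  camera_intrinsics(fx = 425, fy = 425, cx = 424, cy = 240,
                    width = 848, height = 480, depth_scale = 0.001)
}

#' Project camera-frame points to pixel coordinates
#'
#' Forward pinhole projection, the inverse of [backproject_pixel]. Used to
#' verify the back-projection round-trip.
#'
#' @param xyz Numeric n x 3 matrix of camera-frame points in metres (z > 0).
#' @param intr A [camera_intrinsics] object.
#' @return n x 2 matrix of (u, v) pixel coordinates (0-based, continuous).
#' @export
project_points <- function(xyz, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  xyz <- rbind(xyz)
  if (any(xyz[, 3] <= 0)) stop("points must have positive depth z")
  cbind(u = xyz[, 1] * intr$fx / xyz[, 3] + intr$cx,
        v = xyz[, 2] * intr$fy / xyz[, 3] + intr$cy)
}
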