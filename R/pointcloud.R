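#' Point cloud container
#'
#' An ordered set of 3D points in metres (camera frame, +z pointing away from
#' the camera along the optical axis), with optional per-point 8-bit RGB
#' colours.
#'
#' @param xyz Numeric n x 3 matrix (columns x, y, z, metres). May have 0 rows.
#' @param rgb Optional integer n x 3 matrix of colours in 0..255.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(xyz = matrix(numeric(0), 0, 3), rgb = NULL) {
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  storage.mode(xyz) <- "double"
  if (nrow(xyz) > 0 && !all(is.finite(xyz)))
    stop(sprintf("point cloud has %d non-finite coordinates",
                 sum(!is.finite(xyz))))
  colnames(xyz) <- c("x", "y", "z")
  if (!is.null(rgb)) {
    rgb <- rbind(rgb)
    if (nrow(rgb) != nrow(xyz))
      stop("rgb must have one row per point")
    if (ncol(rgb) != 3) stop("rgb must have 3 columns")
    if (nrow(rgb) > 0 && (min(rgb) < 0 || max(rgb) > 255))
      stop("colours must be in 0..255")
    storage.mode(rgb) <- "integer"
    colnames(rgb) <- c("r", "g", "b")
  }
  structure(list(xyz = xyz, rgb = rgb), class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud A [point_cloud].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s\n", n_points(x),
              if (is.null(x$rgb)) "" else ", coloured"))
  if (n_points(x) > 0) {
    rng <- apply(x$xyz, 2, range)
    cat(sprintf("  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud A [point_cloud].
#' @param transform A `rigid_transform` (see [rigid_transform]).
#' @return The transformed [point_cloud] (colours preserved).
#' @export
transform_cloud <- function(cloud, transform) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(transform, "rigid_transform"))
  xyz <- cloud$xyz %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, `+`)
  point_cloud(xyz, cloud$rgb)
}
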