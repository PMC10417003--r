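#' Back-project a pixel with depth to a 3D camera-frame point
#'
#' Standard pinhole back-projection: `z = d_raw * depth_scale`,
#' `x = (u - cx) * z / fx`, `y = (v - cy) * z / fy`. A raw depth of 0 encodes
#' "no sensor return" and is an error here — callers must skip such pixels
#' rather than emit a point at the origin.
#'
#' @param u Column pixel coordinate (0-based).
#' @param v Row pixel coordinate (0-based).
#' @param d_raw Raw depth count (> 0).
#' @param intr A [camera_intrinsics] object.
#' @return Numeric length-3 vector (x, y, z) in metres.
#' @export
backproject_pixel <- function(u, v, d_raw, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (u < 0 || u >= intr$width || v < 0 || v >= intr$height)
    stop("pixel (u, v) outside the frame")
  if (d_raw <= 0)
    stop("invalid depth: d_raw must be > 0 (0 encodes no sensor return)")
  z <- d_raw * intr$depth_scale
  c(x = (u - intr$cx) * z / intr$fx,
    y = (v - intr$cy) * z / intr$fy,
    z = z)
}

# Vectorised back-projection over parallel pixel/depth vectors (no validity
# checks; callers pre-filter zero depth).
backproject_pixels <- function(u, v, d_raw, intr) {
  z <- d_raw * intr$depth_scale
  cbind(x = (u - intr$cx) * z / intr$fx,
        y = (v - intr$cy) * z / intr$fy,
        z = z)
}

# Shared image shape checks. depth: integer matrix; rgb: h x w x 3 array.
check_frame_shapes <- function(rgb, depth, intr = NULL) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a height x width x 3 array")
  if (!is.matrix(depth))
    stop("depth must be a height x width matrix")
  if (!identical(dim(rgb)[1:2], dim(depth)))
    stop("registration error: rgb and depth shapes differ")
  if (any(depth < 0)) stop("depth counts must be non-negative")
  if (!is.null(intr) &&
      (dim(depth)[1] != intr$height || dim(depth)[2] != intr$width))
    stop("registration error: frame shape does not match intrinsics")
  invisible(TRUE)
}

#' Lift a full RGB-D frame to a coloured point cloud
#'
#' Back-projects every pixel with a valid (non-zero) depth return through the
#' intrinsics and colours it from the RGB frame. Pixels are emitted in
#' column-major raster order.
#'
#' @param rgb Integer height x width x 3 array, values 0..255.
#' @param depth Integer height x width matrix of raw depth counts; 0 = no
#'   return (skipped).
#' @param intr A [camera_intrinsics] matching the frame size.
#' @return A [point_cloud] with one point per valid-depth pixel.
#' @export
depth_to_cloud <- function(rgb, depth, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  check_frame_shapes(rgb, depth, intr)
  keep <- which(depth > 0)
  if (length(keep) == 0) return(point_cloud())
  h <- nrow(depth)
  v <- (keep - 1) %% h         # 0-based row
  u <- (keep - 1) %/% h        # 0-based column
  xyz <- backproject_pixels(u, v, depth[keep], intr)
  cols <- cbind(rgb[, , 1][keep], rgb[, , 2][keep], rgb[, , 3][keep])
  point_cloud(xyz, cols)
}

#' Per-instance flat-colour mask set
#'
#' A single mask image in which each instance is painted with one flat,
#' non-black colour on a black background, plus the ordered colour list
#' mapping colours to instances. Colour matching throughout the package is
#' exact (masks are stored as lossless PNG).
#'
#' @param mask_image Integer height x width x 3 array; black = background.
#' @param colour_list Integer n x 3 matrix of distinct non-black RGB triples,
#'   one row per instance, in instance order.
#' @param instance_ids Optional character/integer labels parallel to
#'   `colour_list` (defaults to 1..n).
#' @return An object of class `instance_mask_set`.
#' @export
instance_mask_set <- function(mask_image, colour_list,
                              instance_ids = seq_len(nrow(colour_list))) {
  if (!is.array(mask_image) || length(dim(mask_image)) != 3 ||
      dim(mask_image)[3] != 3)
    stop("mask_image must be a height x width x 3 array")
  colour_list <- rbind(colour_list)
  if (ncol(colour_list) != 3) stop("colour_list must have 3 columns")
  storage.mode(colour_list) <- "integer"
  if (nrow(colour_list) > 0) {
    if (any(rowSums(colour_list) == 0))
      stop("colour_list must not contain black")
    keys <- colour_key(colour_list)
    if (anyDuplicated(keys)) stop("colour_list colours must be distinct")
  }
  if (length(instance_ids) != nrow(colour_list))
    stop("instance_ids must parallel colour_list")
  obj <- structure(list(mask_image = mask_image, colour_list = colour_list,
                        instance_ids = instance_ids),
                   class = "instance_mask_set")
  extra <- setdiff(unique(mask_keys(obj)), c(0, colour_key(colour_list)))
  if (length(extra) > 0)
    stop(sprintf("annotation inconsistency: %d mask colour(s) absent from colour_list",
                 length(extra)))
  obj
}

# Encode RGB triples as single integers for exact matching.
colour_key <- function(cols) {
  cols <- rbind(cols)
  as.numeric(cols[, 1]) * 65536 + as.numeric(cols[, 2]) * 256 + as.numeric(cols[, 3])
}

mask_keys <- function(masks) {
  m <- masks$mask_image
  as.numeric(m[, , 1]) * 65536 + as.numeric(m[, , 2]) * 256 + as.numeric(m[, , 3])
}

#' @export
print.instance_mask_set <- function(x, ...) {
  cat(sprintf("<instance_mask_set> %dx%d, %d instance(s)\n",
              dim(x$mask_image)[1], dim(x$mask_image)[2], nrow(x$colour_list)))
  invisible(x)
}

#' Build per-instance masks from detection boxes and a semantic mask
#'
#' Instance masks are formed by intersecting each detection box with the
#' binary semantic foreground mask: pixel p belongs to instance i iff it is
#' foreground and lies inside box i. A pixel inside several boxes goes to the
#' highest-scoring box; score ties break to the lower instance index. Each
#' instance is painted with its colour from `colour_list`.
#'
#' @param boxes A data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based pixel coordinates, half-open), `score` in `[0,1]`, and
#'   optionally `instance_id`.
#' @param semantic_mask Logical (or 0/1) height x width matrix.
#' @param colour_list Integer matrix of distinct non-black RGB rows, at least
#'   `nrow(boxes)` of them.
#' @return An [instance_mask_set] with one entry per box (boxes whose region
#'   contains no foreground keep their colour with zero pixels).
#' @export
build_instance_masks <- function(boxes, semantic_mask, colour_list) {
  semantic_mask <- semantic_mask > 0
  h <- nrow(semantic_mask); w <- ncol(semantic_mask)
  nb <- nrow(boxes)
  colour_list <- rbind(colour_list)
  if (nrow(colour_list) < nb)
    stop("colour_list must provide at least one colour per box")
  colour_list <- colour_list[seq_len(nb), , drop = FALSE]
  if (nb > 0) {
    bad <- boxes$x_min >= boxes$x_max | boxes$y_min >= boxes$y_max
    if (any(bad)) stop("degenerate box (x_min >= x_max or y_min >= y_max)")
    if (any(boxes$x_min < 0 | boxes$y_min < 0 |
            boxes$x_max > w | boxes$y_max > h))
      stop("boxes must be clipped to the frame")
  }
  owner <- matrix(0L, h, w)
  # claim pixels from the strongest box down; ties keep the earlier index
  ord <- order(-boxes$score, seq_len(nb))
  for (i in ord) {
    rows <- (floor(boxes$y_min[i]) + 1):ceiling(boxes$y_max[i])
    cols <- (floor(boxes$x_min[i]) + 1):ceiling(boxes$x_max[i])
    sub <- owner[rows, cols, drop = FALSE]
    sel <- sub == 0L & semantic_mask[rows, cols, drop = FALSE]
    sub[sel] <- i
    owner[rows, cols] <- sub
  }
  mask_image <- array(0L, c(h, w, 3))
  for (i in seq_len(nb)) {
    sel <- owner == i
    if (any(sel)) for (ch in 1:3) {
      plane <- mask_image[, , ch]
      plane[sel] <- colour_list[i, ch]
      mask_image[, , ch] <- plane
    }
  }
  ids <- if (!is.null(boxes$instance_id)) boxes$instance_id else seq_len(nb)
  instance_mask_set(mask_image, colour_list, ids)
}

#' Split an RGB-D frame into per-instance point clouds
#'
#' For each colour in the mask set's colour list (in order), back-projects
#' exactly the pixels whose mask colour matches exactly and whose depth is
#' valid. Points are coloured from the RGB frame, never from the mask.
#'
#' @param rgb Integer height x width x 3 array.
#' @param depth Integer height x width matrix of raw depth counts.
#' @param masks An [instance_mask_set] of the same shape.
#' @param intr A [camera_intrinsics] matching the frame.
#' @return List of [point_cloud] objects, one per listed colour, named by
#'   `instance_ids`.
#' @export
extract_object_clouds <- function(rgb, depth, masks, intr) {
  stopifnot(inherits(masks, "instance_mask_set"), inherits(intr, "camera_intrinsics"))
  check_frame_shapes(rgb, depth, intr)
  if (!identical(dim(masks$mask_image)[1:2], dim(depth)))
    stop("registration error: mask shape does not match frame")
  keys <- mask_keys(masks)
  wanted <- colour_key(masks$colour_list)
  extra <- setdiff(unique(keys), c(0, wanted))
  if (length(extra) > 0)
    stop("annotation inconsistency: mask contains colours absent from colour_list")
  h <- nrow(depth)
  out <- vector("list", length(wanted))
  for (i in seq_along(wanted)) {
    keep <- which(keys == wanted[i] & depth > 0)
    if (length(keep) == 0) { out[[i]] <- point_cloud(); next }
    v <- (keep - 1) %% h
    u <- (keep - 1) %/% h
    xyz <- backproject_pixels(u, v, depth[keep], intr)
    cols <- cbind(rgb[, , 1][keep], rgb[, , 2][keep], rgb[, , 3][keep])
    out[[i]] <- point_cloud(xyz, cols)
  }
  names(out) <- as.character(masks$instance_ids)
  out
}
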