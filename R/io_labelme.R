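#' Rasterise a polygon to a binary mask (pixel-centre even-odd fill)
#'
#' A pixel belongs to the polygon iff its centre `(col + 0.5, row + 0.5)` in
#' 0-based pixel coordinates lies inside under the even-odd rule. The square
#' `(0,0)(0,10)(10,10)(10,0)` therefore covers exactly the 100 pixels whose
#' centres fall in `(0,10) x (0,10)`. Annotation pixel counts depend on this
#' rule, so it is fixed and tested.
#'
#' @param points Numeric n x 2 matrix of polygon vertices `(x, y)` in pixels.
#' @param height,width Mask shape.
#' @return Logical height x width matrix.
#' @export
rasterise_polygon <- function(points, height, width) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("polygon needs at least 3 vertices")
  px <- rep(0:(width - 1), each = height) + 0.5
  py <- rep(0:(height - 1), times = width) + 0.5
  inside <- rep(FALSE, height * width)
  n <- nrow(points)
  j <- n
  for (i in seq_len(n)) {
    xi <- points[i, 1]; yi <- points[i, 2]
    xj <- points[j, 1]; yj <- points[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, height, width)
}

#' Read a Labelme-style polygon annotation file as a ground-truth set
#'
#' Accepts the JSON layout written by polygon annotation tools: a `shapes`
#' list whose entries carry `label`, `points` (list of `(x, y)` pairs) and
#' optionally `shape_type` (`"polygon"`, the default, or `"rectangle"` as
#' two corner points). Polygons are rasterised with the pixel-centre
#' even-odd rule; tight boxes are derived from the mask. Malformed shapes
#' produce a per-shape warning and are skipped; the file errors only when no
#' valid shape remains out of a non-empty list.
#'
#' @param path Path to the JSON file.
#' @param height,width Frame shape; defaults to the file's `imageHeight` /
#'   `imageWidth` fields.
#' @return Data.frame with `label`, box columns, and a `mask` list-column
#'   (zero rows for an empty shapes list). Duplicate labels stay distinct
#'   instances.
#' @export
read_labelme_json <- function(path, height = NULL, width = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  height <- height %||% doc$imageHeight
  width <- width %||% doc$imageWidth
  if (is.null(height) || is.null(width))
    stop("frame shape unknown: pass height/width or include imageHeight/imageWidth")
  shapes <- doc$shapes %||% list()
  out <- list()
  for (s in shapes) {
    pts <- tryCatch(
      matrix(unlist(s$points), ncol = 2, byrow = TRUE),
      error = function(e) NULL)
    type <- s$shape_type %||% "polygon"
    if (is.null(pts) || nrow(pts) < 2 || (type == "polygon" && nrow(pts) < 3)) {
      warning(sprintf("skipping malformed shape '%s'", s$label %||% "?"))
      next
    }
    if (type == "rectangle")
      pts <- rbind(c(pts[1, 1], pts[1, 2]), c(pts[2, 1], pts[1, 2]),
                   c(pts[2, 1], pts[2, 2]), c(pts[1, 1], pts[2, 2]))
    mask <- rasterise_polygon(pts, height, width)
    if (!any(mask)) {
      warning(sprintf("shape '%s' rasterises to zero pixels; skipped",
                      s$label %||% "?"))
      next
    }
    rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
    out[[length(out) + 1]] <- data.frame(
      label = s$label %||% "object",
      x_min = min(cols) - 1, y_min = min(rows) - 1,
      x_max = max(cols), y_max = max(rows))
    out[[length(out)]]$mask <- list(mask)
  }
  if (length(shapes) > 0 && length(out) == 0)
    stop("no valid shape in annotation file")
  if (length(out) == 0)
    return(data.frame(label = character(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0)))
  do.call(rbind, out)
}

#' Write annotations as a Labelme-style JSON file
#'
#' Boxes are written as `rectangle` shapes in the same layout
#' [read_labelme_json] consumes.
#'
#' @param anns Data.frame with `label` (optional) and box columns.
#' @param path Output path.
#' @param height,width Frame shape recorded in the file.
#' @return `path`, invisibly.
#' @export
write_labelme_json <- function(anns, path, height, width) {
  shapes <- lapply(seq_len(nrow(anns)), function(i) list(
    label = as.character(if (!is.null(anns$label)) anns$label[i] else "object"),
    points = list(list(anns$x_min[i], anns$y_min[i]),
                  list(anns$x_max[i], anns$y_max[i])),
    shape_type = "rectangle"))
  jsonlite::write_json(
    list(imageHeight = height, imageWidth = width, shapes = shapes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
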