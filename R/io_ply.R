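#' Write a point cloud as ASCII PLY
#'
#' Emits `x`, `y`, `z` as floats (6 decimal places, i.e. micron precision at
#' metre scale) and, when present, `red`, `green`, `blue` as uchar. ASCII is
#' the default on purpose: fixtures stay diff-able.
#'
#' @param cloud A [point_cloud] with finite coordinates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  bad <- sum(!is.finite(cloud$xyz))
  if (bad > 0)
    stop(sprintf("refusing to write PLY: %d non-finite coordinate(s)", bad))
  n <- n_points(cloud)
  has_col <- !is.null(cloud$rgb)
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              "end_header")
  lines <- if (n == 0) character(0) else if (has_col)
    sprintf("%.6f %.6f %.6f %d %d %d",
            cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3],
            cloud$rgb[, 1], cloud$rgb[, 2], cloud$rgb[, 3])
  else
    sprintf("%.6f %.6f %.6f", cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3])
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Parses the vertex element; `x`, `y`, `z` are required, `red`, `green`,
#' `blue` picked up when present, any extra vertex properties are ignored.
#' Only ASCII PLY is supported.
#'
#' @param path Path to an ASCII PLY file.
#' @return A [point_cloud].
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("format error: not a PLY file")
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("format error: PLY header not terminated")
  header <- trimws(lines[seq_len(endh)])
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) == 0 || !grepl("ascii", fmt[1]))
    stop("format error: only ASCII PLY is supported")
  # vertex element and its property order
  el <- grep("^element ", header)
  vline <- el[grepl("^element vertex ", header[el])]
  if (length(vline) == 0) stop("format error: no vertex element")
  nvert <- as.integer(sub("^element vertex ", "", header[vline[1]]))
  next_el <- el[el > vline[1]]
  pstop <- if (length(next_el)) next_el[1] else endh
  props <- header[(vline[1] + 1):(pstop - 1)]
  props <- props[grepl("^property ", props)]
  pnames <- vapply(strsplit(props, "\\s+"), function(x) x[length(x)], "")
  need <- match(c("x", "y", "z"), pnames)
  if (any(is.na(need))) stop("format error: vertex element lacks x/y/z")
  if (nvert == 0) return(point_cloud())
  body <- lines[(endh + 1):(endh + nvert)]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                 nrow = nvert, byrow = TRUE)
  if (ncol(vals) < length(pnames))
    stop("format error: vertex rows shorter than the property list")
  xyz <- vals[, need, drop = FALSE]
  cidx <- match(c("red", "green", "blue"), pnames)
  rgb <- if (!any(is.na(cidx))) vals[, cidx, drop = FALSE] else NULL
  point_cloud(xyz, rgb)
}
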