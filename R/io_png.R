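# -- 16-bit grayscale PNG ----------------------------------------------------
# Depth frames are stored as single-channel 16-bit PNGs in raw depth counts
# (millimetres by convention). Reading goes through png::readPNG, which
# decodes 16-bit samples exactly; writing is done here chunk by chunk
# (IHDR / IDAT / IEND, zlib stream via memCompress, CRC32 in C) because no
# installed writer emits 16-bit samples.

be_bytes <- function(x, n) {
  as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(be_bytes(length(data), 4), body, be_bytes(.crc32_cpp(body), 4))
}

#' Write a depth image as a 16-bit grayscale PNG
#'
#' Lossless storage of raw depth counts (0 = no return). Round-trips
#' bit-exactly with [read_depth_png].
#'
#' @param depth Integer matrix of counts in `[0, 65535]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  if (!is.matrix(depth)) stop("depth must be a matrix")
  if (any(depth < 0) || any(depth > 65535) || any(depth != round(depth)))
    stop("depth counts must be integers in [0, 65535]")
  h <- nrow(depth); w <- ncol(depth)
  vals <- as.integer(t(depth))                    # row-major scanlines
  hi <- vals %/% 256L; lo <- vals %% 256L
  pix <- as.raw(as.vector(rbind(hi, lo)))         # big-endian 16-bit samples
  scan <- matrix(pix, nrow = 2 * w)               # one column per scanline
  raw_rows <- rbind(as.raw(0L), scan)             # filter byte 0 per scanline
  idat <- memCompress(as.raw(raw_rows), type = "gzip")
  ihdr <- c(be_bytes(w, 4), be_bytes(h, 4),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))       # 16-bit, grayscale
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  writeBin(c(sig, png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0))), path)
  invisible(path)
}

#' Read a 16-bit grayscale depth PNG
#'
#' @param path Path to a single-channel 16-bit PNG.
#' @return Integer matrix of raw depth counts.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16)
    stop(sprintf(
      "format error: %s is %d-bit; depth frames must be 16-bit grayscale PNG (re-export the depth stream at 16 bits)",
      path, info$bit.depth))
  if (length(dim(img)) == 3)
    stop(sprintf(
      "format error: %s has %d channels; depth frames must be single-channel (grayscale) PNG",
      path, dim(img)[3]))
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

# -- 8-bit RGB PNG -----------------------------------------------------------

#' Write an 8-bit RGB PNG
#' @param rgb Integer height x width x 3 array in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be a height x width x 3 array")
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Read an 8-bit RGB PNG as an integer array
#' @param path Path to an RGB (or RGBA; alpha dropped) PNG.
#' @return Integer height x width x 3 array in 0..255.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  a <- round(img * 255)
  storage.mode(a) <- "integer"
  a
}
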