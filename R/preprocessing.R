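# Luma conversion (Rec. 601 weights) from an integer h x w x 3 array.
rgb_to_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Exact area-average resize of a numeric matrix to h_out x w_out: each output
# pixel is the mean over its (fractional) source footprint. Implemented as a
# pair of interval-overlap weight matrices, so it is fully deterministic.
resize_area <- function(g, h_out, w_out) {
  wmat <- function(n_in, n_out) {
    W <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (o in seq_len(n_out)) {
      lo <- (o - 1) * scale; hi <- o * scale
      i0 <- floor(lo) + 1; i1 <- ceiling(hi)
      for (i in i0:min(i1, n_in))
        W[o, i] <- min(hi, i) - max(lo, i - 1)
    }
    W / scale
  }
  wmat(nrow(g), h_out) %*% g %*% t(wmat(ncol(g), w_out))
}

#' Double perceptual hash of a frame (aHash + dHash)
#'
#' Two 64-bit signatures of the grayscale thumbnail used for near-duplicate
#' frame detection. aHash thresholds each pixel of the `hash_size` x
#' `hash_size` thumbnail against the thumbnail mean (strict >); dHash
#' compares horizontal neighbours on a `hash_size` x `(hash_size + 1)`
#' thumbnail (strict >), making it invariant to uniform brightness scaling.
#' A constant image yields the documented all-zero bit strings.
#'
#' @param img Integer height x width x 3 RGB array (or grayscale matrix).
#' @param hash_size Thumbnail edge in pixels (default 8, i.e. 64-bit hashes).
#' @return A `frame_hash`: list with logical bit vectors `ahash_bits`,
#'   `dhash_bits` and `hash_size`.
#' @export
frame_hashes <- function(img, hash_size = 8) {
  if (hash_size < 2) stop("hash_size must be >= 2")
  g <- if (is.matrix(img)) img else rgb_to_gray(img)
  # strict > with a 1e-9 guard so resize round-off on flat regions never
  # sets bits (constant image => all-zero hashes, as documented)
  a_thumb <- resize_area(g, hash_size, hash_size)
  ahash <- as.vector(a_thumb - mean(a_thumb) > 1e-9)
  d_thumb <- resize_area(g, hash_size, hash_size + 1)
  dhash <- as.vector(d_thumb[, -1] - d_thumb[, -ncol(d_thumb)] > 1e-9)
  structure(list(ahash_bits = ahash, dhash_bits = dhash,
                 hash_size = hash_size),
            class = "frame_hash")
}

#' @export
print.frame_hash <- function(x, ...) {
  b2h <- function(b) paste(sprintf("%x", colSums(
    matrix(as.integer(b), 4) * c(8, 4, 2, 1))), collapse = "")
  cat(sprintf("<frame_hash> a=%s d=%s\n", b2h(x$ahash_bits), b2h(x$dhash_bits)))
  invisible(x)
}

#' Hamming distance between two frame hashes
#'
#' @param h1,h2 `frame_hash` objects of equal `hash_size`.
#' @return Named integer vector with components `ahash` and `dhash`.
#' @export
hash_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "frame_hash"), inherits(h2, "frame_hash"),
            h1$hash_size == h2$hash_size)
  c(ahash = sum(h1$ahash_bits != h2$ahash_bits),
    dhash = sum(h1$dhash_bits != h2$dhash_bits))
}

#' Deduplicate an ordered frame stream by double perceptual hashing
#'
#' A frame is dropped iff BOTH its aHash and dHash Hamming distances to some
#' already-kept frame are within the thresholds (conjunctive rule: agreement
#' of the two hashes is required to call a frame a duplicate). The first
#' frame is always kept and output order is preserved.
#'
#' @param frames List of RGB arrays (or grayscale matrices), in stream order.
#' @param threshold_a,threshold_d Maximum Hamming distances (bits, in
#'   `[0, hash_size^2]`) under which a frame counts as a duplicate
#'   (default 5 each).
#' @param hash_size Thumbnail edge (default 8).
#' @return Integer vector of kept frame indices (increasing).
#' @export
dedup_frames <- function(frames, threshold_a = 5, threshold_d = 5,
                         hash_size = 8) {
  nbits <- hash_size * hash_size
  if (threshold_a < 0 || threshold_a > nbits ||
      threshold_d < 0 || threshold_d > nbits)
    stop("thresholds must lie in [0, hash_size^2]")
  if (length(frames) == 0) return(integer(0))
  hashes <- lapply(frames, frame_hashes, hash_size = hash_size)
  kept <- integer(0)
  for (i in seq_along(frames)) {
    dup <- FALSE
    for (k in kept) {
      d <- hash_distance(hashes[[i]], hashes[[k]])
      if (d["ahash"] <= threshold_a && d["dhash"] <= threshold_d) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  kept
}

#' Mosaic augmentation: stitch four images into one training canvas
#'
#' Draws a stitch centre uniformly from the central region of the canvas
#' (under `seed`), fills each quadrant with the top-left crop of the
#' corresponding input, translates each input's box annotations by its
#' quadrant origin, clips them to the quadrant, and drops annotations whose
#' clipped area falls below `min_visible` of the original.
#'
#' @param imgs List of exactly 4 integer RGB arrays.
#' @param anns List of 4 annotation data.frames with columns `x_min`,
#'   `y_min`, `x_max`, `y_max` (0-based half-open pixels) and optionally
#'   `label`.
#' @param canvas Output size `c(width, height)` in pixels.
#' @param seed Integer seed controlling the centre jitter (required for
#'   reproducibility).
#' @param centre Optional fixed stitch centre `c(x, y)`; overrides the draw.
#' @param jitter_frac Fraction of the canvas within which the centre is
#'   drawn, centred (default 0.5, i.e. the central 50%).
#' @param min_visible Minimum surviving annotation area as a fraction of the
#'   original box area (default 0.01).
#' @return A `mosaic_sample`: `image`, `annotations` (kept, with
#'   `source_quadrant`), `dropped` (count per quadrant), `centre`, `seed`.
#' @export
mosaic <- function(imgs, anns, canvas = c(640, 640), seed = 1,
                   centre = NULL, jitter_frac = 0.5, min_visible = 0.01) {
  if (length(imgs) != 4 || length(anns) != 4)
    stop("mosaic requires exactly 4 images and 4 annotation sets")
  W <- canvas[1]; H <- canvas[2]
  if (is.null(centre)) {
    centre <- with_seed(seed, c(
      round(runif(1, W * (0.5 - jitter_frac / 2), W * (0.5 + jitter_frac / 2))),
      round(runif(1, H * (0.5 - jitter_frac / 2), H * (0.5 + jitter_frac / 2)))))
  }
  cx <- centre[1]; cy <- centre[2]
  # quadrant rectangles (0-based half-open): TL, TR, BL, BR
  quads <- list(c(0, 0, cx, cy), c(cx, 0, W, cy),
                c(0, cy, cx, H), c(cx, cy, W, H))
  out <- array(0L, c(H, W, 3))
  kept <- list(); dropped <- integer(4)
  for (q in 1:4) {
    qr <- quads[[q]]
    qw <- qr[3] - qr[1]; qh <- qr[4] - qr[2]
    if (qw <= 0 || qh <= 0) { dropped[q] <- nrow(anns[[q]]); next }
    img <- imgs[[q]]
    ch <- min(qh, dim(img)[1]); cw <- min(qw, dim(img)[2])
    out[(qr[2] + 1):(qr[2] + ch), (qr[1] + 1):(qr[1] + cw), ] <-
      img[1:ch, 1:cw, ]
    an <- anns[[q]]
    if (is.null(an) || nrow(an) == 0) next
    for (j in seq_len(nrow(an))) {
      orig_area <- (an$x_max[j] - an$x_min[j]) * (an$y_max[j] - an$y_min[j])
      # translate by the quadrant origin, then clip to the quadrant
      x0 <- max(an$x_min[j] + qr[1], qr[1]); x1 <- min(an$x_max[j] + qr[1], qr[3])
      y0 <- max(an$y_min[j] + qr[2], qr[2]); y1 <- min(an$y_max[j] + qr[2], qr[4])
      area <- max(0, x1 - x0) * max(0, y1 - y0)
      if (area >= min_visible * orig_area && area > 0) {
        kept[[length(kept) + 1]] <- data.frame(
          x_min = x0, y_min = y0, x_max = x1, y_max = y1,
          label = if (!is.null(an$label)) an$label[j] else NA,
          source_quadrant = q)
      } else dropped[q] <- dropped[q] + 1L
    }
  }
  annotations <- if (length(kept)) do.call(rbind, kept) else
    data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0), label = character(0),
               source_quadrant = integer(0))
  structure(list(image = out, annotations = annotations, dropped = dropped,
                 centre = c(cx, cy), seed = seed),
            class = "mosaic_sample")
}
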