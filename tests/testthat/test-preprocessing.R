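test_that("frame hashes are deterministic and brightness-aware where expected", {
  img <- gradient_frame(seed = 1)
  h1 <- frame_hashes(img)
  h2 <- frame_hashes(img)
  expect_equal(length(h1$ahash_bits), 64)
  expect_equal(length(h1$dhash_bits), 64)
  expect_identical(h1, h2)
  expect_equal(unname(hash_distance(h1, h2)), c(0, 0))
  # dhash is invariant to uniform brightness scaling (order-preserving)
  dim_img <- img
  dim_img[] <- as.integer(round(img * 0.6))
  expect_equal(unname(hash_distance(h1, frame_hashes(dim_img))["dhash"]), 0)
  # constant image: documented all-zero hashes under the strict > rule
  flat <- array(37L, c(32, 32, 3))
  hf <- frame_hashes(flat)
  expect_true(all(!hf$ahash_bits))
  expect_true(all(!hf$dhash_bits))
  # 1-pixel shift of a smooth frame stays below the dedup threshold
  shifted <- img[, c(2:64, 64), ]
  d <- hash_distance(h1, frame_hashes(shifted))
  expect_lte(d[["ahash"]], 5)
  expect_lte(d[["dhash"]], 5)
  # structurally different noise frame lands above the threshold
  set.seed(9)
  noise <- array(as.integer(sample(0:255, 48 * 64 * 3, TRUE)), c(48, 64, 3))
  dn <- hash_distance(h1, frame_hashes(noise))
  expect_true(dn[["ahash"]] > 5 || dn[["dhash"]] > 5)
})

test_that("dedup keeps one frame per near-duplicate run", {
  base1 <- gradient_frame(seed = 1)
  base2 <- base1[, 64:1, , drop = FALSE]   # mirrored: structurally distinct
  set.seed(21)
  base3 <- array(as.integer(sample(0:255, 48 * 64 * 3, TRUE)), c(48, 64, 3))
  jitter <- function(img, seed) {
    set.seed(seed)
    out <- img + as.integer(round(rnorm(length(img), 0, 2)))
    out[] <- pmin(255L, pmax(0L, out))
    out
  }
  # 3 runs of near-duplicates: 8 + 7 + 5 = 20 frames
  frames <- c(lapply(1:8, function(s) jitter(base1, s)),
              lapply(1:7, function(s) jitter(base2, 100 + s)),
              lapply(1:5, function(s) jitter(base3, 200 + s)))
  kept <- dedup_frames(frames, threshold_a = 5, threshold_d = 5)
  # oracle: exhaustive pairwise distances confirm run structure
  hashes <- lapply(frames, frame_hashes)
  runs <- rep(1:3, c(8, 7, 5))
  for (i in seq_along(frames)) for (j in seq_len(i - 1)) {
    d <- hash_distance(hashes[[i]], hashes[[j]])
    if (runs[i] == runs[j]) {
      expect_true(d[["ahash"]] <= 5 && d[["dhash"]] <= 5)
    } else {
      expect_true(d[["ahash"]] > 5 || d[["dhash"]] > 5)
    }
  }
  expect_equal(kept, c(1, 9, 16))   # first frame of each run
  # k copies of one frame -> 1 kept; first frame always kept
  expect_equal(dedup_frames(rep(list(base1), 6)), 1)
  # threshold 0 with all-distinct frames -> all kept
  distinct <- lapply(1:5, function(s) gradient_frame(seed = s, noise = 80))
  expect_equal(dedup_frames(distinct, 0, 0), 1:5)
  expect_equal(dedup_frames(list()), integer(0))
})

test_that("mosaic stitches quadrants deterministically and conserves annotations", {
  set.seed(31)
  imgs <- lapply(1:4, function(s) gradient_frame(h = 40, w = 40, seed = s,
                                                 noise = 30))
  anns <- list(
    data.frame(x_min = 2, y_min = 2, x_max = 10, y_max = 10, label = "a"),
    data.frame(x_min = c(1, 30), y_min = c(1, 30), x_max = c(8, 39),
               y_max = c(8, 39), label = c("b1", "b2")),
    data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0), label = character(0)),
    data.frame(x_min = 5, y_min = 5, x_max = 15, y_max = 15, label = "d"))
  # centre fixed at the canvas midpoint, canvas-sized inputs:
  # each quadrant equals that input's top-left 20x20 region pixelwise
  ms <- mosaic(imgs, anns, canvas = c(40, 40), seed = 1, centre = c(20, 20))
  expect_equal(ms$image[1:20, 1:20, ], imgs[[1]][1:20, 1:20, ])
  expect_equal(ms$image[1:20, 21:40, ], imgs[[2]][1:20, 1:20, ])
  expect_equal(ms$image[21:40, 1:20, ], imgs[[3]][1:20, 1:20, ])
  expect_equal(ms$image[21:40, 21:40, ], imgs[[4]][1:20, 1:20, ])
  # a box fully inside its quadrant is translated by exactly the quadrant offset
  a4 <- ms$annotations[ms$annotations$source_quadrant == 4, ]
  expect_equal(unlist(a4[, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 25, y_min = 25, x_max = 35, y_max = 35))
  # conservation per quadrant: kept + dropped = input total
  for (q in 1:4)
    expect_equal(sum(ms$annotations$source_quadrant == q) + ms$dropped[q],
                 nrow(anns[[q]]))
  # the out-of-crop box in quadrant 2 is dropped, the in-crop one kept
  expect_equal(sum(ms$annotations$source_quadrant == 2), 1)
  expect_equal(ms$dropped[2], 1)
  # determinism: same seed -> bit-identical image and annotations
  m1 <- mosaic(imgs, anns, canvas = c(40, 40), seed = 77)
  m2 <- mosaic(imgs, anns, canvas = c(40, 40), seed = 77)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$annotations, m2$annotations)
  expect_error(mosaic(imgs[1:3], anns[1:3]), "exactly 4")
})
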