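test_that("back-projection follows the pinhole model and round-trips", {
  intr <- camera_intrinsics(fx = 425, fy = 425, cx = 424, cy = 240,
                            width = 848, height = 480)
  # principal-point ray and unit-tangent ray
  expect_equal(unname(backproject_pixel(intr$cx, intr$cy, 1000, intr)),
               c(0, 0, 1))
  wide <- camera_intrinsics(fx = 200, fy = 200, cx = 100, cy = 240,
                            width = 848, height = 480)
  expect_equal(unname(backproject_pixel(wide$cx + wide$fx, wide$cy, 2000, wide)),
               c(2, 0, 2))
  # z always equals d_raw * depth_scale exactly
  expect_identical(backproject_pixel(10, 20, 1234, intr)[["z"]],
                   1234 * intr$depth_scale)
  # round-trip through an independent forward projection, 100 random pixels
  set.seed(42)
  u <- sample(0:847, 100, replace = TRUE)
  v <- sample(0:479, 100, replace = TRUE)
  d <- sample(500:4000, 100, replace = TRUE)
  for (i in 1:100) {
    p <- backproject_pixel(u[i], v[i], d[i], intr)
    u_back <- p[["x"]] * intr$fx / p[["z"]] + intr$cx
    v_back <- p[["y"]] * intr$fy / p[["z"]] + intr$cy
    expect_lt(abs(u_back - u[i]), 1e-9)
    expect_lt(abs(v_back - v[i]), 1e-9)
  }
  # invalid inputs
  expect_error(backproject_pixel(10, 10, 0, intr), "invalid depth")
  expect_error(backproject_pixel(-1, 10, 100, intr), "outside")
})

test_that("depth_to_cloud emits one point per valid pixel, coloured from rgb", {
  intr <- camera_intrinsics(fx = 10, fy = 10, cx = 4, cy = 4,
                            width = 8, height = 8)
  rgb <- array(as.integer(sample(0:255, 8 * 8 * 3, TRUE)), c(8, 8, 3))
  # all-zero depth -> empty cloud
  expect_equal(n_points(depth_to_cloud(rgb, matrix(0L, 8, 8), intr)), 0)
  # constant 3000 mm over the full frame -> 64 points, all z = 3
  cl <- depth_to_cloud(rgb, matrix(3000L, 8, 8), intr)
  expect_equal(n_points(cl), 64)
  expect_true(all(cl$xyz[, "z"] == 3))
  # mixed validity: brute-force per-pixel oracle
  set.seed(7)
  depth <- matrix(sample(c(0L, 0L, 800L, 1500L, 2500L), 64, TRUE), 8, 8)
  cl <- depth_to_cloud(rgb, depth, intr)
  expect_equal(n_points(cl), sum(depth > 0))
  want <- NULL; cols <- NULL
  for (col in 1:8) for (row in 1:8) {    # column-major pixel order
    if (depth[row, col] > 0) {
      want <- rbind(want, backproject_pixel(col - 1, row - 1, depth[row, col], intr))
      cols <- rbind(cols, rgb[row, col, ])
    }
  }
  expect_equal(unname(cl$xyz), unname(want))
  expect_equal(unname(cl$rgb), unname(cols))
  # shape mismatch signals a registration error
  expect_error(depth_to_cloud(rgb, matrix(0L, 8, 9), intr), "registration")
})

test_that("instance masks form from box-semantic intersection with score tie-breaks", {
  sem <- matrix(FALSE, 20, 20)
  sem[5:8, 5:8] <- TRUE    # 16-pixel blob
  pal <- mask_palette(3)
  # one box covering part of the blob
  b1 <- data.frame(x_min = 4, y_min = 4, x_max = 8, y_max = 8, score = 0.9)
  ms <- build_instance_masks(b1, sem, pal)
  expect_equal(sum(mask_keys(ms) == colour_key(pal[1, ])), 16)
  # blob fully outside all boxes -> all-black mask
  b2 <- data.frame(x_min = 12, y_min = 12, x_max = 18, y_max = 18, score = 0.9)
  ms2 <- build_instance_masks(b2, sem, pal)
  expect_true(all(ms2$mask_image == 0))
  # overlapping boxes: higher score claims the contested pixels
  sem3 <- matrix(TRUE, 20, 20)
  boxes <- data.frame(x_min = c(0, 4), y_min = c(0, 0),
                      x_max = c(6, 10), y_max = c(2, 2),
                      score = c(0.95, 0.90))
  ms3 <- build_instance_masks(boxes, sem3, pal)
  keys <- matrix(mask_keys(ms3), 20, 20)
  # the 2x2-column overlap region (cols 5:6, rows 1:2) belongs to box 1
  expect_true(all(keys[1:2, 5:6] == colour_key(pal[1, ])))
  expect_true(all(keys[1:2, 7:10] == colour_key(pal[2, ])))
  # equal scores: lower index wins, deterministically
  boxes$score <- c(0.9, 0.9)
  ms4 <- build_instance_masks(boxes, sem3, pal)
  keys4 <- matrix(mask_keys(ms4), 20, 20)
  expect_true(all(keys4[1:2, 5:6] == colour_key(pal[1, ])))
})

test_that("extract_object_clouds matches brute-force mask x depth counting", {
  fx <- generate_scene(small_scene_config(n_animals = 2, seed = 11,
                                          noise_sigma_mm = 40))
  intr <- fx$config$intrinsics
  clouds <- extract_object_clouds(fx$rgb, fx$depth, fx$masks, intr)
  expect_length(clouds, 2)
  keys <- matrix(mask_keys(fx$masks), nrow(fx$depth), ncol(fx$depth))
  for (i in 1:2) {
    want <- sum(keys == colour_key(fx$masks$colour_list[i, ]) & fx$depth > 0)
    expect_equal(n_points(clouds[[i]]), want)
  }
  # union of object clouds is contained in the full-frame cloud, pointwise
  full <- depth_to_cloud(fx$rgb, fx$depth, intr)
  full_keys <- paste(full$xyz[, 1], full$xyz[, 2], full$xyz[, 3])
  for (i in 1:2)
    expect_true(all(paste(clouds[[i]]$xyz[, 1], clouds[[i]]$xyz[, 2],
                          clouds[[i]]$xyz[, 3]) %in% full_keys))
  # empty mask -> one empty cloud per listed colour
  blank <- instance_mask_set(array(0L, c(nrow(fx$depth), ncol(fx$depth), 3)),
                             fx$masks$colour_list)
  empty <- extract_object_clouds(fx$rgb, fx$depth, blank, intr)
  expect_true(all(vapply(empty, n_points, 1L) == 0))
  # unknown mask colour signals annotation inconsistency
  bad <- fx$masks$mask_image
  bad[1, 1, ] <- c(1L, 2L, 3L)
  expect_error(
    extract_object_clouds(fx$rgb, fx$depth,
                          structure(list(mask_image = bad,
                                         colour_list = fx$masks$colour_list,
                                         instance_ids = fx$masks$instance_ids),
                                    class = "instance_mask_set"), intr),
    "annotation inconsistency")
})

test_that("geometry invariants: zero-depth exclusion, depth-scale rescaling, partition", {
  fx <- generate_scene(small_scene_config(n_animals = 3, seed = 5,
                                          noise_sigma_mm = 60))
  intr <- fx$config$intrinsics
  clouds <- extract_object_clouds(fx$rgb, fx$depth, fx$masks, intr)
  for (cl in clouds) if (n_points(cl) > 0) expect_true(all(cl$xyz[, "z"] > 0))
  # point counts are invariant to RGB content
  rgb2 <- fx$rgb; rgb2[] <- 17L
  clouds2 <- extract_object_clouds(rgb2, fx$depth, fx$masks, intr)
  expect_equal(vapply(clouds2, n_points, 1L), vapply(clouds, n_points, 1L))
  # scaling depth counts by k and depth_scale by 1/k leaves clouds unchanged
  k <- 4
  intr_k <- camera_intrinsics(intr$fx, intr$fy, intr$cx, intr$cy,
                              intr$width, intr$height, intr$depth_scale / k)
  clouds_k <- extract_object_clouds(fx$rgb, fx$depth * k, fx$masks, intr_k)
  for (i in seq_along(clouds))
    expect_equal(clouds_k[[i]]$xyz, clouds[[i]]$xyz)
  # partition: with non-overlapping masks the union of object clouds equals
  # the masked subset of the full-frame cloud exactly
  full <- depth_to_cloud(fx$rgb, fx$depth, intr)
  keys <- mask_keys(fx$masks)
  masked_px <- which(keys != 0 & fx$depth > 0)
  union_xyz <- do.call(rbind, lapply(clouds, function(cl) cl$xyz))
  expect_equal(nrow(union_xyz), length(masked_px))
  full_px <- which(fx$depth > 0)
  sub <- full$xyz[match(masked_px, full_px), , drop = FALSE]
  expect_setequal(paste(union_xyz[, 1], union_xyz[, 2], union_xyz[, 3]),
                  paste(sub[, 1], sub[, 2], sub[, 3]))
})
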