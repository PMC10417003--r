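test_that("generated scenes honour their configuration exactly", {
  # n_animals = 0: uniform floor, no masks, no clouds
  cfg0 <- small_scene_config(n_animals = 0, seed = 3)
  fx0 <- generate_scene(cfg0)
  expect_true(all(fx0$depth == round(cfg0$floor_depth_m * 1000)))
  expect_equal(nrow(fx0$boxes), 0)
  expect_length(fx0$gt_clouds, 0)
  expect_true(all(fx0$masks$mask_image == 0))
  # single animal, no noise: every mask pixel rises above the floor
  cfg1 <- small_scene_config(n_animals = 1, seed = 4)
  fx1 <- generate_scene(cfg1)
  keys <- matrix(mask_keys(fx1$masks), nrow(fx1$depth))
  on_animal <- keys == colour_key(fx1$masks$colour_list[1, ])
  expect_true(all(fx1$depth[on_animal] < round(cfg1$floor_depth_m * 1000)))
  expect_true(all(fx1$depth[!on_animal] == round(cfg1$floor_depth_m * 1000)))
  # gt cloud z-range stays within floor minus the configured height range
  z <- fx1$gt_clouds[[1]]$xyz[, "z"]
  expect_gte(min(z), cfg1$floor_depth_m - cfg1$animal_height_m[2] - 1e-3)
  expect_lt(max(z), cfg1$floor_depth_m)
  # boxes are the tight bounding boxes of the masks
  px <- which(on_animal, arr.ind = TRUE)
  expect_equal(fx1$boxes$x_min, min(px[, 2]) - 1)
  expect_equal(fx1$boxes$x_max, max(px[, 2]))
  expect_equal(fx1$boxes$y_min, min(px[, 1]) - 1)
  expect_equal(fx1$boxes$y_max, max(px[, 1]))
  # determinism: same seed -> bit-identical fixture
  fx1b <- generate_scene(cfg1)
  expect_identical(fx1$rgb, fx1b$rgb)
  expect_identical(fx1$depth, fx1b$depth)
  expect_identical(fx1$masks$mask_image, fx1b$masks$mask_image)
})

test_that("gt clouds are exactly the back-projection of valid mask pixels", {
  fx <- generate_scene(small_scene_config(n_animals = 3, seed = 6,
                                          noise_sigma_mm = 30))
  clouds <- extract_object_clouds(fx$rgb, fx$depth, fx$masks,
                                  fx$config$intrinsics)
  for (i in seq_along(clouds)) {
    expect_identical(clouds[[i]]$xyz, fx$gt_clouds[[i]]$xyz)
    expect_identical(clouds[[i]]$rgb, fx$gt_clouds[[i]]$rgb)
  }
})

test_that("depth noise can invalidate pixels, exercising the zero-depth path", {
  cfg <- small_scene_config(n_animals = 2, seed = 8, noise_sigma_mm = 1500)
  fx <- generate_scene(cfg)
  expect_gt(sum(fx$depth == 0), 0)   # heavy noise clips some counts to zero
  keys <- matrix(mask_keys(fx$masks), nrow(fx$depth))
  for (i in 1:2) {
    valid <- sum(keys == colour_key(fx$masks$colour_list[i, ]) & fx$depth > 0)
    expect_equal(n_points(fx$gt_clouds[[i]]), valid)
  }
})

test_that("overlap mode creates adhesion while normal mode keeps blobs apart", {
  fx <- generate_scene(small_scene_config(n_animals = 3, seed = 12))
  # non-overlap: instance pixel sets are disjoint by construction
  keys <- mask_keys(fx$masks)
  counts <- table(keys[keys != 0])
  expect_equal(sum(counts), sum(keys != 0))
  ov <- generate_scene(small_scene_config(n_animals = 2, seed = 42,
                                          overlap_mode = TRUE))
  expect_equal(nrow(ov$boxes), 2)
})

test_that("perturb_detections yields the constructed TP/FP composition", {
  fx <- generate_scene(small_scene_config(n_animals = 3, seed = 14))
  gt <- scene_ground_truth(fx)
  # clean detections: mAP 1.0 through the evaluation module
  clean <- perturb_detections(fx, seed = 1)
  r <- map_over_range(clean, gt)
  expect_equal(r$map5095, 1)
  expect_equal(map_over_range(clean, gt, mode = "mask")$map5095, 1)
  # fp_rate 0.25 on 3 TPs -> exactly 1 FP -> precision 3/4
  dets <- perturb_detections(fx, fp_rate = 0.25, seed = 2)
  expect_equal(sum(is.na(dets$instance_id)), 1)
  m <- match_and_ap(dets, gt, 0.5)
  expect_equal(precision(m$counts), 0.75)
  # drop_rate 1 -> no true detections, AP 0
  none <- perturb_detections(fx, drop_rate = 1, fp_rate = 0, seed = 3)
  expect_equal(nrow(none), 0)
  expect_equal(match_and_ap(none, gt, 0.5)$ap, 0)
  # determinism under a fixed seed
  expect_identical(perturb_detections(fx, jitter_px = 3, fp_rate = 0.25, seed = 9),
                   perturb_detections(fx, jitter_px = 3, fp_rate = 0.25, seed = 9))
})

test_that("illumination scales RGB only, never depth or geometry", {
  bright <- generate_scene(small_scene_config(n_animals = 2, seed = 10,
                                              illumination = 1.4))
  dark <- generate_scene(small_scene_config(n_animals = 2, seed = 10,
                                            illumination = 0.5))
  expect_identical(bright$depth, dark$depth)
  expect_identical(bright$masks$mask_image, dark$masks$mask_image)
  expect_false(identical(bright$rgb, dark$rgb))
  for (i in 1:2)
    expect_identical(bright$gt_clouds[[i]]$xyz, dark$gt_clouds[[i]]$xyz)
})
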