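#' Configuration for a synthetic overhead RGB-D scene
#'
#' Describes a fixed overhead camera above a flat floor with several convex
#' animal-shaped blobs (half-ellipsoids) lying on it — the acquisition
#' geometry of a depth camera mounted on a 3 m post over a pen, streaming
#' 848x480 frames with millimetre depth.
#'
#' @param n_animals Number of animal blobs (>= 0).
#' @param floor_depth_m Camera-to-floor distance in metres (default 3.0).
#' @param animal_height_m Range (min, max) of blob apex heights above the
#'   floor in metres (default c(0.25, 0.45), a lying adult pig seen from
#'   above).
#' @param axes_a_px,axes_b_px Ranges for the ellipse semi-axes in pixels
#'   (major/minor; defaults sized so a blob spans roughly 0.6-1.3 m on the
#'   floor at 3 m range with the default intrinsics).
#' @param intrinsics A [camera_intrinsics] (default [default_intrinsics]).
#' @param illumination Gamma-style brightness factor applied to the RGB
#'   channels only (default 1.0 = neutral; < 1 darkens as at night, > 1
#'   brightens; nonlinear, like a sensor gamma response, so thumbnail
#'   hashes see it). Depth is never touched by illumination.
#' @param noise_sigma_mm Gaussian depth-noise s.d. in millimetres
#'   (default 0). Noisy counts are clipped at 0, and 0 means "no return",
#'   so noise can invalidate pixels.
#' @param overlap_mode If `TRUE`, allow blobs to overlap (adhesion stress
#'   mode); later blobs occlude earlier ones in the mask and depth.
#' @param max_place_tries Placement retries before giving up.
#' @param seed Integer seed making the scene deterministic.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_animals = 5, floor_depth_m = 3.0,
                         animal_height_m = c(0.25, 0.45),
                         axes_a_px = c(55, 95), axes_b_px = c(28, 50),
                         intrinsics = default_intrinsics(),
                         illumination = 1.0, noise_sigma_mm = 0,
                         overlap_mode = FALSE, max_place_tries = 200,
                         seed = 1) {
  stopifnot(n_animals >= 0, floor_depth_m > 0, noise_sigma_mm >= 0,
            illumination > 0, inherits(intrinsics, "camera_intrinsics"),
            animal_height_m[1] > 0, animal_height_m[2] >= animal_height_m[1],
            animal_height_m[2] < floor_depth_m)
  structure(list(n_animals = n_animals, floor_depth_m = floor_depth_m,
                 animal_height_m = animal_height_m, axes_a_px = axes_a_px,
                 axes_b_px = axes_b_px, intrinsics = intrinsics,
                 illumination = illumination, noise_sigma_mm = noise_sigma_mm,
                 overlap_mode = overlap_mode,
                 max_place_tries = max_place_tries, seed = seed),
            class = "scene_config")
}

# Maximally distinct instance palette (bright, non-black, deterministic).
mask_palette <- function(n) {
  if (n == 0) return(matrix(integer(0), 0, 3))
  cols <- t(grDevices::col2rgb(grDevices::hsv(seq(0, 1 - 1 / n, length.out = n),
                                              s = 1, v = 1)))
  storage.mode(cols) <- "integer"
  colnames(cols) <- NULL
  cols
}

#' Generate a synthetic overhead RGB-D scene with exact ground truth
#'
#' Renders the floor at the configured depth, places the requested number of
#' half-ellipsoid blobs (fully inside the frame, non-overlapping unless
#' `overlap_mode`), and emits the RGB frame, the raw depth counts
#' (millimetres), the per-instance flat-colour mask set, tight bounding
#' boxes, and per-instance ground-truth clouds obtained by back-projecting
#' each instance's valid-depth mask pixels — exactly what the lifting
#' pipeline must reproduce.
#'
#' @param cfg A [scene_config].
#' @return A `scene_fixture`: `rgb`, `depth`, `masks` ([instance_mask_set]),
#'   `boxes` (data.frame with scores 1.0), `gt_clouds` (list of
#'   [point_cloud]), `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    intr <- cfg$intrinsics
    h <- intr$height; w <- intr$width
    floor_mm <- round(cfg$floor_depth_m * 1000)
    # elevation of the surface above the floor, in metres (0 = floor)
    elev <- matrix(0, h, w)
    owner <- matrix(0L, h, w)
    px_u <- matrix(rep(0:(w - 1), each = h), h, w)   # 0-based column
    px_v <- matrix(rep(0:(h - 1), times = w), h, w)  # 0-based row
    placed <- list()
    for (i in seq_len(cfg$n_animals)) {
      ok <- FALSE
      for (try in seq_len(cfg$max_place_tries)) {
        a <- runif(1, cfg$axes_a_px[1], cfg$axes_a_px[2])
        b <- runif(1, cfg$axes_b_px[1], cfg$axes_b_px[2])
        theta <- runif(1, 0, pi)
        cu <- runif(1, a, w - 1 - a)
        cv <- runif(1, a, h - 1 - a)
        hmax <- runif(1, cfg$animal_height_m[1], cfg$animal_height_m[2])
        if (!cfg$overlap_mode && length(placed) > 0) {
          clash <- vapply(placed, function(p)
            sqrt((p$cu - cu)^2 + (p$cv - cv)^2) < (p$a + a), logical(1))
          if (any(clash)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("placement failure: could not place all animals")
      du <- px_u - cu; dv <- px_v - cv
      xr <- (du * cos(theta) + dv * sin(theta)) / a
      yr <- (-du * sin(theta) + dv * cos(theta)) / b
      q <- xr^2 + yr^2
      # cut the ellipsoid slightly above its rim so every mask pixel is
      # elevated by at least 0.1*hmax and strictly above the floor in mm
      inside <- q < 0.99
      elev[inside] <- hmax * sqrt(1 - q[inside])
      owner[inside] <- i
      placed[[i]] <- list(cu = cu, cv = cv, a = a, b = b, theta = theta,
                          hmax = hmax)
    }
    depth <- floor_mm - round(elev * 1000)
    if (cfg$noise_sigma_mm > 0)
      depth <- depth + round(rnorm(h * w, 0, cfg$noise_sigma_mm))
    depth[depth < 0] <- 0L
    storage.mode(depth) <- "integer"
    dim(depth) <- c(h, w)

    # RGB: textured grey floor, per-animal pinkish shade, then illumination
    rgb <- array(0L, c(h, w, 3))
    base <- c(120, 110, 100)
    tex <- matrix(round(rnorm(h * w, 0, 8)), h, w)
    shades <- if (cfg$n_animals > 0)
      matrix(round(runif(cfg$n_animals * 3, -25, 25)), cfg$n_animals, 3)
    for (ch in 1:3) {
      plane <- base[ch] + tex
      for (i in seq_len(cfg$n_animals)) {
        sel <- owner == i
        plane[sel] <- c(210, 170, 160)[ch] + shades[i, ch] + tex[sel]
      }
      plane <- pmin(255, pmax(0, plane))
      # gamma-style brightness: nonlinear in intensity, RGB path only
      rgb[, , ch] <- as.integer(round(255 * (plane / 255)^(1 / cfg$illumination)))
    }

    colour_list <- mask_palette(cfg$n_animals)
    mask_image <- array(0L, c(h, w, 3))
    boxes <- NULL
    gt_clouds <- vector("list", cfg$n_animals)
    for (i in seq_len(cfg$n_animals)) {
      sel <- owner == i
      if (!any(sel))
        stop("placement failure: instance fully occluded in overlap mode")
      for (ch in 1:3) {
        plane <- mask_image[, , ch]
        plane[sel] <- colour_list[i, ch]
        mask_image[, , ch] <- plane
      }
      us <- px_u[sel]; vs <- px_v[sel]
      boxes <- rbind(boxes, data.frame(
        x_min = min(us), y_min = min(vs), x_max = max(us) + 1,
        y_max = max(vs) + 1, score = 1.0, instance_id = i))
      keep <- which(sel & depth > 0)
      vv <- (keep - 1) %% h; uu <- (keep - 1) %/% h
      xyz <- backproject_pixels(uu, vv, depth[keep], intr)
      cols <- cbind(rgb[, , 1][keep], rgb[, , 2][keep], rgb[, , 3][keep])
      gt_clouds[[i]] <- point_cloud(xyz, cols)
    }
    if (is.null(boxes))
      boxes <- data.frame(x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0),
                          score = numeric(0), instance_id = integer(0))
    structure(list(rgb = rgb, depth = depth,
                   masks = instance_mask_set(mask_image, colour_list,
                                             seq_len(cfg$n_animals)),
                   boxes = boxes, gt_clouds = gt_clouds, config = cfg),
              class = "scene_fixture")
  })
}

#' @export
print.scene_fixture <- function(x, ...) {
  cat(sprintf("<scene_fixture> %dx%d, %d instance(s), %d valid-depth pixel(s)\n",
              dim(x$depth)[1], dim(x$depth)[2], nrow(x$boxes), sum(x$depth > 0)))
  invisible(x)
}

#' Perturb a scene's ground truth into a detection set with known composition
#'
#' Produces detections whose true/false composition is known by
#' construction, so expected precision and AP can be computed analytically:
#' each ground-truth box is dropped with probability `drop_rate`, surviving
#' boxes are jittered by up to `jitter_px` per edge, and false positives are
#' added so that the FP fraction of all detections equals `fp_rate`
#' (`n_fp = round(n_kept * fp_rate / (1 - fp_rate))`). True detections score
#' in (0.85, 0.99]; false positives in (0.30, 0.70), placed to overlap no
#' ground truth.
#'
#' @param fixture A `scene_fixture` from [generate_scene].
#' @param drop_rate Probability of dropping each true box, in `[0, 1]`.
#' @param jitter_px Maximum absolute per-edge jitter in pixels.
#' @param fp_rate Target false-positive fraction among detections, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return Detection data.frame (columns `x_min`,`y_min`,`x_max`,`y_max`,
#'   `score`, `instance_id` — `NA` for false positives — and `mask`
#'   list-column of logical matrices).
#' @export
perturb_detections <- function(fixture, drop_rate = 0, jitter_px = 0,
                               fp_rate = 0, seed = 1) {
  stopifnot(inherits(fixture, "scene_fixture"),
            drop_rate >= 0, drop_rate <= 1, fp_rate >= 0, fp_rate < 1)
  with_seed(seed, {
    h <- nrow(fixture$depth); w <- ncol(fixture$depth)
    keys <- mask_keys(fixture$masks)
    ckeys <- colour_key(fixture$masks$colour_list)
    rows <- list()
    masks <- list()
    gt <- fixture$boxes
    for (i in seq_len(nrow(gt))) {
      if (drop_rate > 0 && runif(1) < drop_rate) next
      j <- if (jitter_px > 0) round(runif(4, -jitter_px, jitter_px)) else rep(0, 4)
      x0 <- max(0, min(gt$x_min[i] + j[1], w - 2))
      y0 <- max(0, min(gt$y_min[i] + j[2], h - 2))
      x1 <- min(w, max(gt$x_max[i] + j[3], x0 + 1))
      y1 <- min(h, max(gt$y_max[i] + j[4], y0 + 1))
      rows[[length(rows) + 1]] <- data.frame(
        x_min = x0, y_min = y0, x_max = x1, y_max = y1,
        score = runif(1, 0.85, 0.99), instance_id = gt$instance_id[i])
      masks[[length(rows)]] <- matrix(keys == ckeys[i], h, w)
    }
    n_tp <- length(rows)
    n_fp <- if (fp_rate > 0) round(n_tp * fp_rate / (1 - fp_rate)) else 0
    for (k in seq_len(n_fp)) {
      for (try in 1:200) {
        bw <- round(runif(1, 30, 80)); bh <- round(runif(1, 30, 80))
        x0 <- round(runif(1, 0, w - bw)); y0 <- round(runif(1, 0, h - bh))
        box <- c(x0, y0, x0 + bw, y0 + bh)
        clash <- FALSE
        for (i in seq_len(nrow(gt)))
          if (iou(box, unlist(gt[i, c("x_min", "y_min", "x_max", "y_max")])) > 0.05) {
            clash <- TRUE; break
          }
        if (!clash) break
      }
      rows[[length(rows) + 1]] <- data.frame(
        x_min = box[1], y_min = box[2], x_max = box[3], y_max = box[4],
        score = runif(1, 0.30, 0.70), instance_id = NA_integer_)
      fp_mask <- matrix(FALSE, h, w)
      fp_mask[(box[2] + 1):box[4], (box[1] + 1):box[3]] <- TRUE
      masks[[length(rows)]] <- fp_mask
    }
    if (length(rows) == 0)
      return(data.frame(x_min = numeric(0), y_min = numeric(0),
                        x_max = numeric(0), y_max = numeric(0),
                        score = numeric(0), instance_id = integer(0)))
    dets <- do.call(rbind, rows)
    dets$mask <- masks
    dets
  })
}

#' Ground-truth data.frame of a scene (boxes + instance masks)
#'
#' Convenience accessor turning a `scene_fixture`'s ground truth into the
#' data.frame layout consumed by [match_and_ap] / [map_over_range].
#'
#' @param fixture A `scene_fixture`.
#' @return Data.frame with box columns and a `mask` list-column.
#' @export
scene_ground_truth <- function(fixture) {
  stopifnot(inherits(fixture, "scene_fixture"))
  gt <- fixture$boxes[, c("x_min", "y_min", "x_max", "y_max", "instance_id")]
  if (nrow(gt) > 0) {
    keys <- mask_keys(fixture$masks)
    ckeys <- colour_key(fixture$masks$colour_list)
    h <- nrow(fixture$depth); w <- ncol(fixture$depth)
    gt$mask <- lapply(seq_len(nrow(gt)), function(i) matrix(keys == ckeys[i], h, w))
  }
  gt
}
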