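# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use naive brute-force formulations (nested loops,
# prefix re-matching) so they stay independent of the vectorised package
# implementations they check.

# Small-frame configuration: same scene model as the full 848x480 default,
# scaled to keep unit tests fast.
small_scene_config <- function(n_animals = 3, seed = 1, noise_sigma_mm = 0,
                               illumination = 1.0, overlap_mode = FALSE) {
  scene_config(
    n_animals = n_animals,
    axes_a_px = c(9, 16), axes_b_px = c(5, 8),
    intrinsics = camera_intrinsics(fx = 90, fy = 90, cx = 60, cy = 45,
                                   width = 120, height = 90),
    noise_sigma_mm = noise_sigma_mm, illumination = illumination,
    overlap_mode = overlap_mode, seed = seed)
}

# Rigid perturbation about the cloud centroid: angle_deg about a random-ish
# axis plus a translation, expressed as a single rigid_transform.
centroid_perturbation <- function(cloud, axis, angle_deg, translation) {
  ctr <- colMeans(cloud$xyz)
  R <- axis_angle_transform(axis, angle_deg)$rotation
  rigid_transform(R, as.numeric(ctr - R %*% ctr) + translation)
}

# --- independent AP oracle --------------------------------------------------
# Greedy matching recomputed from scratch for every score-ordered prefix,
# then all-point interpolated AP via an explicit O(n^2) envelope maximum.
oracle_box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2]); ab <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (aa + ab - inter)
}

oracle_match_prefix <- function(dets, gts, k, thr) {
  matched <- rep(FALSE, nrow(gts))
  tp <- 0
  for (d in seq_len(k)) {
    best <- 0; bi <- 0
    for (g in seq_len(nrow(gts))) {
      if (matched[g]) next
      v <- oracle_box_iou(
        as.numeric(dets[d, c("x_min", "y_min", "x_max", "y_max")]),
        as.numeric(gts[g, c("x_min", "y_min", "x_max", "y_max")]))
      if (v >= thr && v > best) { best <- v; bi <- g }
    }
    if (bi > 0) { matched[bi] <- TRUE; tp <- tp + 1 }
  }
  tp
}

oracle_ap <- function(dets, gts, thr) {
  ng <- nrow(gts); nd <- nrow(dets)
  if (nd == 0 || ng == 0) return(0)
  dets <- dets[order(-dets$score, seq_len(nd)), , drop = FALSE]
  prec <- rec <- numeric(nd)
  for (k in seq_len(nd)) {
    tp <- oracle_match_prefix(dets, gts, k, thr)
    prec[k] <- tp / k
    rec[k] <- tp / ng
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_len(nd)) {
    p_env <- 0
    for (j in i:nd) p_env <- max(p_env, prec[j])  # envelope by explicit scan
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

# Random toy detection scene for oracle comparisons: boxes on a 100x100
# frame, some matching ground truth, some spurious.
random_toy_scene <- function(seed) {
  set.seed(seed)
  ng <- sample(1:5, 1)
  gts <- data.frame(
    x_min = runif(ng, 0, 60), y_min = runif(ng, 0, 60))
  gts$x_max <- gts$x_min + runif(ng, 10, 35)
  gts$y_max <- gts$y_min + runif(ng, 10, 35)
  nd <- sample(1:10, 1)
  src <- sample(seq_len(ng), nd, replace = TRUE)
  dets <- data.frame(
    x_min = gts$x_min[src] + runif(nd, -12, 12),
    y_min = gts$y_min[src] + runif(nd, -12, 12))
  dets$x_max <- dets$x_min + runif(nd, 8, 40)
  dets$y_max <- dets$y_min + runif(nd, 8, 40)
  dets$score <- round(runif(nd), 3)   # rounding forces occasional score ties
  list(dets = dets, gts = gts)
}

# --- independent convolution oracle ----------------------------------------
# Plain quadruple-loop 3x3 cross-correlation with zero padding.
oracle_conv3x3 <- function(x, k) {
  ci <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]; co <- dim(k)[1]
  out <- array(0, c(co, h, w))
  for (o in seq_len(co)) for (y in seq_len(h)) for (xx in seq_len(w)) {
    acc <- 0
    for (i in seq_len(ci)) for (dy in 1:3) for (dx in 1:3) {
      sy <- y + dy - 2; sx <- xx + dx - 2
      if (sy >= 1 && sy <= h && sx >= 1 && sx <= w)
        acc <- acc + k[o, i, dy, dx] * x[i, sy, sx]
    }
    out[o, y, xx] <- acc
  }
  out
}

oracle_res2net <- function(x, spec) {
  w <- spec$width
  hmap <- array(spec$in_proj %*% matrix(x, dim(x)[1]), dim(x))
  X <- lapply(1:4, function(i) hmap[((i - 1) * w + 1):(i * w), , , drop = FALSE])
  Y <- list(X[[1]],
            oracle_conv3x3(X[[2]], spec$k2), NULL, NULL)
  Y[[3]] <- oracle_conv3x3(X[[3]] + Y[[2]], spec$k3)
  Y[[4]] <- oracle_conv3x3(X[[4]] + Y[[3]], spec$k4)
  cat_y <- array(0, dim(x))
  for (i in 1:4) cat_y[((i - 1) * w + 1):(i * w), , ] <- Y[[i]]
  array(spec$out_proj %*% matrix(cat_y, dim(x)[1]), dim(x)) + x
}

random_res2net_spec <- function(channels, seed) {
  set.seed(seed)
  w <- channels / 4
  rk <- function() array(rnorm(w * w * 9, sd = 0.3), c(w, w, 3, 3))
  res2net_block_spec(channels, rk(), rk(), rk(),
                     in_proj = matrix(rnorm(channels^2, sd = 0.2), channels),
                     out_proj = matrix(rnorm(channels^2, sd = 0.2), channels))
}

# Frame with smooth gradient content plus seeded noise, for hashing tests.
gradient_frame <- function(h = 48, w = 64, seed = 1, noise = 0) {
  set.seed(seed)
  g <- outer(seq(0, 120, length.out = h), seq(0, 120, length.out = w), `+`)
  arr <- array(0L, c(h, w, 3))
  for (ch in 1:3)
    arr[, , ch] <- pmin(255L, pmax(0L, as.integer(round(
      g + ch * 5 + if (noise > 0) rnorm(h * w, 0, noise) else 0))))
  arr
}
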