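#' Confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integer counts (TN defaults to 0; a
#'   detector has no explicit true negatives).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0, FP = 0, FN = 0, TN = 0) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(lapply(v, as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Detection precision TP / (TP + FP)
#'
#' The fraction of positive predictions that are correct.
#'
#' @param counts A [confusion_counts] object (or list with TP and FP).
#' @return Precision in `[0, 1]`.
#' @export
precision <- function(counts) {
  if (counts$TP + counts$FP == 0)
    stop("undefined precision: no positive predictions (TP + FP = 0)")
  counts$TP / (counts$TP + counts$FP)
}

#' Intersection over union of two boxes or two binary masks
#'
#' Boxes are numeric vectors `(x_min, y_min, x_max, y_max)` in 0-based
#' half-open pixel coordinates; masks are logical matrices of equal shape.
#'
#' @param a,b Two boxes or two masks (same kind).
#' @return IoU in `[0, 1]`; 0 when disjoint, 1 when identical.
#' @export
iou <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    a <- a > 0; b <- b > 0
    if (!identical(dim(a), dim(b))) stop("masks must share a shape")
    u <- sum(a | b)
    if (u == 0) stop("undefined IoU: both masks empty")
    return(sum(a & b) / u)
  }
  if (length(a) != 4 || length(b) != 4)
    stop("boxes must be (x_min, y_min, x_max, y_max)")
  area <- function(bx) max(0, bx[3] - bx[1]) * max(0, bx[4] - bx[2])
  if (area(a) == 0 && area(b) == 0) stop("undefined IoU: both boxes empty")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / (area(a) + area(b) - inter)
}

# IoU matrix between detection and ground-truth sets for one image.
# dets/gts: data.frames with box columns; masks optionally in list-columns.
iou_matrix <- function(dets, gts, mode) {
  nd <- nrow(dets); ng <- nrow(gts)
  M <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    M[i, j] <- if (mode == "mask")
      iou(dets$mask[[i]], gts$mask[[j]])
    else
      iou(unlist(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
          unlist(gts[j, c("x_min", "y_min", "x_max", "y_max")]))
  }
  M
}

#' Greedy score-ordered matching and average precision at one IoU threshold
#'
#' Detections are sorted by descending score (ties keep input order); each
#' detection matches at most one still-unmatched ground truth of the same
#' image with IoU >= `iou_threshold`, taking the best-IoU candidate (ties to
#' the lower ground-truth index) — the standard PASCAL/COCO rule. AP is the
#' area under the interpolated precision-recall curve.
#'
#' @param dets Data.frame of detections: box columns `x_min`,`y_min`,
#'   `x_max`,`y_max`, a `score` column, optionally `image_id` and a `mask`
#'   list-column of logical matrices.
#' @param gts Data.frame of ground truths (same columns, no score).
#' @param iou_threshold IoU threshold in (0, 1).
#' @param mode `"box"` (rectangle IoU) or `"mask"` (pixel-set IoU).
#' @param interpolation `"all"` for all-point (continuous) interpolation
#'   (default) or `"coco101"` for COCO-style 101-point sampling.
#' @return List: `ap`, `counts` ([confusion_counts]; FN = unmatched ground
#'   truths), `tp` (logical flags in score order), `precision_curve`,
#'   `recall_curve`.
#' @export
match_and_ap <- function(dets, gts, iou_threshold, mode = c("box", "mask"),
                         interpolation = c("all", "coco101")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  nd <- if (is.null(dets)) 0 else nrow(dets)
  ng <- if (is.null(gts)) 0 else nrow(gts)
  if (nd == 0)
    return(list(ap = 0, counts = confusion_counts(0, 0, ng),
                tp = logical(0), precision_curve = numeric(0),
                recall_curve = numeric(0)))
  if (is.null(dets$image_id)) dets$image_id <- 1L
  if (ng > 0 && is.null(gts$image_id)) gts$image_id <- 1L
  ord <- order(-dets$score, seq_len(nd))
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nd)
  if (ng > 0) {
    matched <- logical(ng)
    gt_idx <- seq_len(ng)
    for (img in unique(dets$image_id)) {
      di <- which(dets$image_id == img)
      gi <- gt_idx[gts$image_id == img]
      if (length(gi) == 0) next
      M <- iou_matrix(dets[di, , drop = FALSE], gts[gi, , drop = FALSE], mode)
      for (k in seq_along(di)) {
        cand <- which(!matched[gi] & M[k, ] >= iou_threshold)
        if (length(cand) == 0) next
        best <- cand[which.max(M[k, cand])]   # which.max ties -> lower index
        matched[gi[best]] <- TRUE
        tp[di[k]] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_len(nd)
  rec <- if (ng > 0) cum_tp / ng else rep(0, nd)
  ap <- if (ng == 0) 0 else interpolate_ap(prec, rec, interpolation)
  list(ap = ap,
       counts = confusion_counts(sum(tp), sum(!tp), if (ng > 0) ng - sum(tp) else 0),
       tp = tp, precision_curve = prec, recall_curve = rec)
}

# Area under the PR curve from cumulative precision/recall vectors.
interpolate_ap <- function(prec, rec, interpolation = "all") {
  if (length(prec) == 0) return(0)
  env <- rev(cummax(rev(prec)))   # precision envelope, monotone from the right
  if (interpolation == "coco101") {
    r_grid <- seq(0, 1, by = 0.01)
    p_at <- vapply(r_grid, function(r) {
      i <- which(rec >= r)
      if (length(i) == 0) 0 else env[i[1]]
    }, numeric(1))
    return(mean(p_at))
  }
  dr <- diff(c(0, rec))
  sum(dr * env)
}

#' mAP over the IoU threshold range 0.50:0.05:0.95
#'
#' Computes AP at each of the ten IoU thresholds 0.50, 0.55, ..., 0.95 and
#' their unweighted mean (mAP@0.5:0.95), plus mAP@0.5.
#'
#' @inheritParams match_and_ap
#' @return An `ap_result`: `ap_per_threshold` (named numeric length 10),
#'   `map50`, `map5095`.
#' @export
map_over_range <- function(dets, gts, mode = c("box", "mask"),
                           interpolation = c("all", "coco101")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  thr <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thr, function(t)
    match_and_ap(dets, gts, t, mode, interpolation)$ap, numeric(1))
  names(aps) <- sprintf("%.2f", thr)
  structure(list(ap_per_threshold = aps, map50 = aps[["0.50"]],
                 map5095 = mean(aps)),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> mAP@0.5 = %.4f  mAP@0.5:0.95 = %.4f\n",
              x$map50, x$map5095))
  invisible(x)
}

#' Filter detections by a confidence threshold
#'
#' Mirrors a deployment rule in which only predictions above a fixed
#' confidence (0.9 by default) count as accepted detections. Applied before
#' confusion counting, never inside the AP sweep.
#'
#' @param dets Detection data.frame with a `score` column.
#' @param conf_thres Minimum accepted score (default 0.9, exclusive below).
#' @return The filtered data.frame.
#' @export
filter_detections <- function(dets, conf_thres = 0.9) {
  dets[dets$score > conf_thres, , drop = FALSE]
}

#' Pixel confusion matrix between label images
#'
#' @param truth,pred Integer matrices of class labels (same shape); labels
#'   are indexed 0..(n-1) or 1..n.
#' @param n Number of classes.
#' @return A `seg_confusion` n x n matrix, entry (i, j) = pixels of true
#'   class i predicted as class j.
#' @export
seg_confusion <- function(truth, pred, n) {
  if (!identical(dim(truth), dim(pred))) stop("label images must share a shape")
  lv <- sort(unique(c(as.vector(truth), as.vector(pred))))
  if (length(lv) > n) stop("more labels than classes")
  t0 <- match(as.vector(truth), lv)
  p0 <- match(as.vector(pred), lv)
  m <- matrix(0, n, n)
  tab <- table(factor(t0, levels = seq_len(n)), factor(p0, levels = seq_len(n)))
  m[] <- as.numeric(tab)
  structure(m, class = c("seg_confusion", "matrix"))
}

#' Global pixel accuracy from a segmentation confusion matrix
#'
#' The proportion of correctly predicted pixels: trace of the pixel
#' confusion matrix over its total.
#'
#' @param m Square numeric matrix of pixel counts, entry (i, j) = pixels of
#'   true class i predicted as class j.
#' @return Fraction in `[0, 1]`.
#' @export
global_accuracy <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix entries must be non-negative")
  tot <- sum(m)
  if (tot == 0) stop("undefined accuracy: empty confusion matrix")
  sum(diag(m)) / tot
}
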