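#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector in metres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) m\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Compose: apply a first, then b (b o a).
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Rotation angle of a 3x3 rotation matrix, in degrees
#' @param R A 3x3 rotation matrix.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Least-squares rigid fit between corresponded point sets (Kabsch)
#'
#' Closed-form SVD solution of the transform minimising
#' sum ||R s_i + t - d_i||^2 over given correspondence pairs.
#'
#' @param src,dst [point_cloud] objects.
#' @param correspondences Integer n x 2 matrix of (src index, dst index)
#'   pairs; default pairs points positionally (clouds of equal size).
#' @return A [rigid_transform].
#' @export
kabsch_align <- function(src, dst, correspondences = NULL) {
  stopifnot(inherits(src, "point_cloud"), inherits(dst, "point_cloud"))
  if (is.null(correspondences)) {
    if (n_points(src) != n_points(dst))
      stop("clouds differ in size; explicit correspondences required")
    correspondences <- cbind(seq_len(n_points(src)), seq_len(n_points(dst)))
  }
  S <- src$xyz[correspondences[, 1], , drop = FALSE]
  D <- dst$xyz[correspondences[, 2], , drop = FALSE]
  if (nrow(S) < 3)
    stop("rank deficiency: at least 3 correspondence pairs required")
  sc <- colMeans(S); dc <- colMeans(D)
  Sc <- sweep(S, 2, sc); Dc <- sweep(D, 2, dc)
  # collinear source points leave the rotation about their axis unconstrained
  sv_s <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_s[2] < 1e-12 * max(sv_s[1], 1e-300))
    stop("rank deficiency: correspondence points are collinear")
  H <- crossprod(Sc, Dc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, as.numeric(dc - R %*% sc))
}

#' Point-to-point iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence (within `max_corr_dist`) and
#' a Kabsch update until the correspondence RMSD stops improving by more
#' than `tol` or `max_iterations` is reached. The RMSD sequence is
#' non-increasing while the correspondence set is stable; the per-iteration
#' history is returned for inspection.
#'
#' @param src,dst Non-empty [point_cloud] objects in the same metric frame.
#' @param max_iterations Maximum ICP iterations (default 50).
#' @param tol Convergence threshold on RMSD improvement, metres
#'   (default 1e-6).
#' @param max_corr_dist Correspondence rejection radius, metres
#'   (default 0.05, suited to animal-scale geometry at ~3 m range).
#' @param tau Inlier radius for the post-alignment similarity score, metres
#'   (default 0.01).
#' @param init `"none"` (default) starts from the identity — appropriate for
#'   clouds that already share a camera frame, and preserves the convention
#'   that far-apart clouds simply fail to match. `"centroid"` first
#'   translates `src` so the centroids coincide, the standard initialisation
#'   when an unknown rigid offset is expected.
#' @return An `alignment_report`: `transform` ([rigid_transform] mapping src
#'   onto dst), `rmsd` (metres, over the final correspondences), `iterations`,
#'   `converged`, `similarity` (directed inlier fraction at `tau`), and
#'   `rmsd_history`.
#' @export
icp <- function(src, dst, max_iterations = 50, tol = 1e-6,
                max_corr_dist = 0.05, tau = 0.01,
                init = c("none", "centroid")) {
  stopifnot(inherits(src, "point_cloud"), inherits(dst, "point_cloud"))
  init <- match.arg(init)
  if (n_points(src) == 0 || n_points(dst) == 0)
    stop("empty input: both clouds must be non-empty")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  total <- if (init == "centroid")
    rigid_transform(diag(3), colMeans(dst$xyz) - colMeans(src$xyz))
  else rigid_transform()
  cur <- sweep(src$xyz, 2, total$translation, `+`)
  prev_rmsd <- Inf
  history <- numeric(0)
  converged <- FALSE
  it <- 0
  rmsd <- NA_real_
  while (it < max_iterations) {
    it <- it + 1
    nn <- .nn1_cpp(cur, dst$xyz, max_corr_dist)
    m <- nn$idx > 0
    if (sum(m) < 3) {
      report <- structure(
        list(transform = total, rmsd = NA_real_, iterations = it,
             converged = FALSE, similarity = 0, rmsd_history = history),
        class = "alignment_report")
      return(report)
    }
    step <- kabsch_align(point_cloud(cur[m, , drop = FALSE]),
                         point_cloud(dst$xyz[nn$idx[m], , drop = FALSE]))
    cur <- sweep(cur %*% t(step$rotation), 2, step$translation, `+`)
    total <- compose_transforms(step, total)
    resid <- cur[m, , drop = FALSE] - dst$xyz[nn$idx[m], , drop = FALSE]
    rmsd <- sqrt(mean(rowSums(resid^2)))
    history <- c(history, rmsd)
    if (rmsd <= tol || (prev_rmsd - rmsd) < tol) { converged <- TRUE; break }
    prev_rmsd <- rmsd
  }
  sim <- cloud_similarity(point_cloud(cur, src$rgb), dst, tau = tau)
  structure(
    list(transform = total, rmsd = rmsd, iterations = it,
         converged = converged, similarity = sim$directed,
         rmsd_history = history),
    class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> iterations=%d converged=%s rmsd=%.3g m similarity=%.4f\n",
              x$iterations, x$converged, x$rmsd, x$similarity))
  invisible(x)
}

#' Cloud similarity as post-alignment inlier fraction
#'
#' Fraction of `src` points whose nearest neighbour in `dst` lies within
#' `tau` metres, intended to be called on clouds already aligned (e.g. after
#' [icp]). Reported in both the directed (src to dst) and symmetric (mean of
#' both directions) forms. The score lies in `[0, 1]` and equals 1 for
#' identical clouds.
#'
#' @param src,dst Non-empty [point_cloud] objects, already aligned.
#' @param tau Inlier radius in metres (> 0), default 0.01.
#' @return List with `directed` and `symmetric` fractions.
#' @export
cloud_similarity <- function(src, dst, tau = 0.01) {
  stopifnot(inherits(src, "point_cloud"), inherits(dst, "point_cloud"))
  if (tau <= 0) stop("invalid threshold: tau must be positive")
  if (n_points(src) == 0 || n_points(dst) == 0)
    stop("empty input: both clouds must be non-empty")
  fwd <- mean(.nn1_cpp(src$xyz, dst$xyz, Inf)$dist <= tau)
  bwd <- mean(.nn1_cpp(dst$xyz, src$xyz, Inf)$dist <= tau)
  list(directed = fwd, symmetric = (fwd + bwd) / 2)
}

#' Build a rigid transform from axis-angle and translation
#'
#' Convenience constructor used in tests and simulations: rotation of
#' `angle_deg` degrees about `axis`, then translation.
#'
#' @param axis Length-3 rotation axis (normalised internally).
#' @param angle_deg Rotation angle in degrees.
#' @param translation Length-3 translation in metres.
#' @return A [rigid_transform].
#' @export
axis_angle_transform <- function(axis = c(0, 0, 1), angle_deg = 0,
                                 translation = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}
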