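#' Res2Net bottleneck specification
#'
#' Weight bundle for the pure-numeric forward pass of a Res2Net-style
#' bottleneck: a 1x1 input projection, a split of the channels into four
#' equal groups (X1..X4), hierarchical 3x3 convolutions K2, K3, K4 over
#' groups 2-4 (Y1 = X1 passes through; Y2 = K2(X2); Yi = Ki(Xi + Y(i-1))),
#' concatenation, a 1x1 output projection, and the residual sum with the
#' block input. Activation/normalisation layers are omitted by default (the
#' structure, not the training recipe, is what this models); an optional
#' elementwise `activation` hook can be supplied.
#'
#' @param channels Channel count, divisible by 4.
#' @param k2,k3,k4 3x3 group convolution weights: arrays of shape
#'   `(w, w, 3, 3)` with `w = channels / 4` (out, in, ky, kx).
#' @param in_proj,out_proj 1x1 projection weights: `channels x channels`
#'   matrices (out x in).
#' @param k1 Optional 3x3 convolution for the first group (`NULL`, the
#'   default, means X1 passes through unconvolved).
#' @param activation Optional elementwise function applied to each group
#'   output and to the final sum (default `NULL` = identity, the linear test
#'   mode).
#' @return An object of class `res2net_block_spec`.
#' @export
res2net_block_spec <- function(channels, k2, k3, k4,
                               in_proj = diag(channels),
                               out_proj = diag(channels),
                               k1 = NULL, activation = NULL) {
  if (channels %% 4 != 0)
    stop("invalid spec: channels must be divisible by 4")
  w <- channels / 4
  chk <- function(k, nm) {
    if (!is.array(k) || !identical(dim(k), as.integer(c(w, w, 3, 3))))
      stop(sprintf("invalid spec: %s must be a (%d, %d, 3, 3) array", nm, w, w))
  }
  chk(k2, "k2"); chk(k3, "k3"); chk(k4, "k4")
  if (!is.null(k1)) chk(k1, "k1")
  stopifnot(identical(dim(in_proj), as.integer(c(channels, channels))),
            identical(dim(out_proj), as.integer(c(channels, channels))))
  structure(list(channels = channels, width = w, k1 = k1, k2 = k2, k3 = k3,
                 k4 = k4, in_proj = in_proj, out_proj = out_proj,
                 activation = activation),
            class = "res2net_block_spec")
}

#' All-zero Res2Net spec (the identity map through the residual path)
#' @param channels Channel count, divisible by 4.
#' @return A [res2net_block_spec] whose every learned weight is zero.
#' @export
res2net_zero_spec <- function(channels) {
  w <- channels / 4
  z <- array(0, c(w, w, 3, 3))
  res2net_block_spec(channels, z, z, z,
                     in_proj = matrix(0, channels, channels),
                     out_proj = matrix(0, channels, channels))
}

#' Identity-kernel Res2Net spec (centre-one 3x3 kernels, identity projections)
#' @param channels Channel count, divisible by 4.
#' @return A [res2net_block_spec] in which each group convolution maps each
#'   channel to itself (discrete delta kernel).
#' @export
res2net_identity_spec <- function(channels) {
  w <- channels / 4
  k <- array(0, c(w, w, 3, 3))
  for (i in seq_len(w)) k[i, i, 2, 2] <- 1
  res2net_block_spec(channels, k, k, k)
}

# 3x3 same-padding convolution of a (C_in, H, W) array with a
# (C_out, C_in, 3, 3) kernel; stride 1, zero padding 1.
conv3x3 <- function(x, k) {
  ci <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  co <- dim(k)[1]
  xp <- array(0, c(ci, h + 2, w + 2))
  xp[, 2:(h + 1), 2:(w + 1)] <- x
  out <- array(0, c(co, h, w))
  for (dy in 1:3) for (dx in 1:3) {
    # window of the padded input aligned with kernel tap (dy, dx)
    win <- xp[, dy:(dy + h - 1), dx:(dx + w - 1), drop = FALSE]
    wm <- matrix(win, ci, h * w)
    km <- matrix(k[, , dy, dx], co, ci)
    out <- out + array(km %*% wm, c(co, h, w))
  }
  out
}

conv1x1 <- function(x, p) {
  d <- dim(x)
  array(p %*% matrix(x, d[1], d[2] * d[3]), c(nrow(p), d[2], d[3]))
}

#' Res2Net bottleneck forward pass
#'
#' Applies the hierarchical multiscale structure: project in (1x1), split
#' into four groups, cascade Y1 = X1, Y2 = K2(X2), Y3 = K3(X3 + Y2),
#' Y4 = K4(X4 + Y3), concatenate, project out (1x1), and add the block input
#' (residual). Spatial size is preserved (3x3 kernels, padding 1, stride 1).
#'
#' @param x Numeric array `(channels, height, width)`.
#' @param spec A [res2net_block_spec] with matching `channels`.
#' @param return_hierarchy If `TRUE`, also return the internal group inputs
#'   X1..X4 and outputs Y1..Y4.
#' @return The output feature map (same shape as `x`), or when
#'   `return_hierarchy = TRUE` a list with `output`, `X`, `Y`.
#' @export
res2net_forward <- function(x, spec, return_hierarchy = FALSE) {
  stopifnot(inherits(spec, "res2net_block_spec"))
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[1] != spec$channels)
    stop("input channels must equal spec$channels")
  act <- if (is.null(spec$activation)) identity else spec$activation
  w <- spec$width
  h <- conv1x1(x, spec$in_proj)
  grp <- function(i) h[((i - 1) * w + 1):(i * w), , , drop = FALSE]
  X <- lapply(1:4, grp)
  Y <- vector("list", 4)
  Y[[1]] <- if (is.null(spec$k1)) X[[1]] else act(conv3x3(X[[1]], spec$k1))
  Y[[2]] <- act(conv3x3(X[[2]], spec$k2))
  Y[[3]] <- act(conv3x3(X[[3]] + Y[[2]], spec$k3))
  Y[[4]] <- act(conv3x3(X[[4]] + Y[[3]], spec$k4))
  cat_y <- array(0, dim(x))
  for (i in 1:4) cat_y[((i - 1) * w + 1):(i * w), , ] <- Y[[i]]
  out <- act(conv1x1(cat_y, spec$out_proj) + x)
  if (return_hierarchy) list(output = out, X = X, Y = Y) else out
}
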