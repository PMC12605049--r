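#' @title CPRSCA attention operations
#' @description
#' Functional building blocks of the channel-partitioned resolution
#' spatial-channel attention mechanism. All operations act on a single
#' feature map: a 3-D array with dim `(C, H, W)` — channels, height
#' (electrode rows for EEG windows), width (time samples). The trainable
#' network wraps the same computations with cached backward passes; these
#' functions are the reference surface and are convenient for inspection
#' and testing.
#' @name attention_ops
NULL

#' Partition a feature map into contiguous channel subsets
#'
#' Splits the `C` channels of `x` into `n` mutually exclusive contiguous
#' blocks of `C / n` channels each, in index order. Concatenating the
#' subsets in order reconstructs `x` exactly.
#'
#' @param x 3-D array `(C, H, W)`.
#' @param n number of subsets; `C` must be divisible by `n`.
#' @return list of `n` arrays, each `(C/n, H, W)`.
#' @export
partition_channels <- function(x, n) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a 3-D (C,H,W) array")
  n <- as.integer(n)
  if (d[1] %% n != 0L)
    stop(sprintf("channel count %d not divisible by n = %d subsets", d[1], n))
  ci <- d[1] %/% n
  lapply(seq_len(n), function(i) {
    x[((i - 1L) * ci + 1L):(i * ci), , , drop = FALSE]
  })
}

conv2d_raw <- function(x, w, sh = 1L, sw = 1L, ph = 0L, pw = 0L, groups = 1L) {
  conv2d_fwd_cpp(as_batch(x), w, as.integer(sh), as.integer(sw),
                 as.integer(ph), as.integer(pw), as.integer(groups))
}

#' 2-D depthwise separable convolution
#'
#' A per-channel `k x k` spatial convolution (one filter per channel)
#' followed by a 1x1 pointwise mixing over the channels, both bias-free
#' and with zero same-padding so the output shape equals the input shape.
#' No nonlinearity is applied. For `ci > 1` channels and `k > 1` this
#' factorization uses `ci * k^2 + ci^2` weights versus `ci^2 * k^2` for a
#' standard convolution.
#'
#' @param xi 3-D array `(ci, H, W)`.
#' @param k odd kernel size.
#' @param weights list with `depthwise` (dim `(ci, 1, k, k)`) and
#'   `pointwise` (dim `(ci, ci, 1, 1)`), e.g. from [make_dsc_weights()].
#' @return array of the same shape as `xi`.
#' @export
dsc2d <- function(xi, k, weights) {
  d <- dim(xi)
  if (length(d) != 3L) stop("xi must be a 3-D (C,H,W) array")
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop(sprintf("kernel size must be odd, got %d", k))
  dw <- weights$depthwise; pw <- weights$pointwise
  if (!identical(dim(dw), c(d[1], 1L, k, k)))
    stop("depthwise weight shape mismatch: expected (", d[1], ",1,", k, ",", k, ")")
  if (!identical(dim(pw), c(d[1], d[1], 1L, 1L)))
    stop("pointwise weight shape mismatch: expected (", d[1], ",", d[1], ",1,1)")
  p <- same_pad(k)
  y <- conv2d_raw(xi, dw, ph = p, pw = p, groups = d[1])
  y <- conv2d_raw(y, pw)
  drop_batch(y)
}

#' Group normalization
#'
#' Normalizes each contiguous channel group of a feature map to zero mean
#' and unit (population) variance over the group's channels and all spatial
#' positions, then applies the learnable per-channel affine transform.
#' Statistics are computed per sample, independent of batch composition.
#'
#' @param x 3-D array `(C, H, W)`.
#' @param gn parameters from [make_gn_params()].
#' @return array of the same shape.
#' @export
group_normalize <- function(x, gn) {
  drop_batch(gn_forward(as_batch(x), gn)$out)
}

gn_forward <- function(x, gn) {
  groupnorm_fwd_cpp(x, gn$gamma, gn$beta, gn$num_groups, gn$eps)
}

gn_backward <- function(cache, gn, dout) {
  groupnorm_bwd_cpp(cache$xhat, cache$inv_sd, gn$gamma, dout, gn$num_groups)
}

#' Softmax over channels
#'
#' At every spatial position, maps the channel vector through a softmax,
#' so the output lies in (0, 1) and sums to 1 over channels. Computed with
#' per-position max subtraction for overflow safety; shift-invariant in the
#' channel direction.
#'
#' @param x 3-D array `(C, H, W)` with finite entries.
#' @return array of the same shape.
#' @export
channel_softmax <- function(x) {
  check_finite(x, "channel_softmax input")
  drop_batch(softmax_channels(as_batch(x)))
}

#' Channel-partitioned resolution module (CPRM)
#'
#' The multi-scale descriptor at the heart of the mechanism: partition the
#' input channels into `n_subsets` contiguous blocks, filter each block with
#' a depthwise separable convolution at that subset's kernel size (3, 5, 7,
#' 9 under the defaults), concatenate back to `C` channels, group-normalize,
#' and apply a softmax over channels. The result is a channel-distribution
#' map: positive entries summing to 1 over channels at every position.
#'
#' @param x 3-D array `(C, H, W)`; `C` divisible by `cfg$n_subsets` and
#'   `cfg$groupnorm_groups`.
#' @param cfg a [cprsca_config()].
#' @param gn group-norm parameters from [make_gn_params()].
#' @param weights list of depthwise-separable weight pairs, one per subset
#'   (e.g. the `dsc` element of [make_cprsca_params()]).
#' @return array of the same shape as `x`.
#' @export
cprm <- function(x, cfg, gn, weights) {
  parts <- partition_channels(x, cfg$n_subsets)
  ks <- kernel_sizes(cfg)
  conv <- lapply(seq_along(parts), function(i) dsc2d(parts[[i]], ks[i], weights[[i]]))
  xp <- x
  ci <- dim(x)[1] %/% cfg$n_subsets
  for (i in seq_along(conv))
    xp[((i - 1L) * ci + 1L):(i * ci), , ] <- conv[[i]]
  channel_softmax(group_normalize(xp, gn))
}

#' Directional average pooling for coordinate attention
#'
#' Pools a feature map along each spatial axis separately: `zh[c, h]` is the
#' mean over width of channel `c` at height `h`, and `zw[c, w]` the mean
#' over height at width `w`, preserving positional information in the
#' un-pooled direction.
#'
#' @param y 3-D array `(C, H, W)`.
#' @return list with `zh` (`C x H` matrix) and `zw` (`C x W` matrix).
#' @export
ca_pool <- function(y) {
  yb <- as_batch(y)
  d <- dim(yb)
  list(zh = matrix(reduce_mean_w(yb), d[1], d[2]),
       zw = matrix(reduce_mean_h(yb), d[1], d[3]))
}

#' Coordinate attention gate generation
#'
#' Concatenates the directional descriptors along the spatial axis, applies
#' the shared bottleneck transform followed by ReLU, splits back into the
#' height and width parts, and maps each through its own expansion transform
#' and a sigmoid, yielding per-axis gates in `[0, 1]`.
#'
#' @param zh `C x H` matrix of height-direction descriptors.
#' @param zw `C x W` matrix of width-direction descriptors.
#' @param p parameters from [make_ca_params()].
#' @return list with `gh` (`C x H`) and `gw` (`C x W`), entries in `[0, 1]`.
#' @export
ca_gates <- function(zh, zw, p) {
  C <- nrow(zh)
  if (nrow(zw) != C) stop("zh and zw disagree on channel count")
  if (ncol(p$w1) != C || nrow(p$wh) != C || nrow(p$ww) != C)
    stop(sprintf("CA parameters sized for %d channels, input has %d", ncol(p$w1), C))
  H <- ncol(zh); W <- ncol(zw)
  f <- pmax(p$w1 %*% cbind(zh, zw), 0)           # shared transform + ReLU
  gh <- sigmoid(p$wh %*% f[, seq_len(H), drop = FALSE])
  gw <- sigmoid(p$ww %*% f[, H + seq_len(W), drop = FALSE])
  list(gh = gh, gw = gw)
}

#' Apply coordinate attention gates
#'
#' Rescales `x[c, h, w]` by `gh[c, h] * gw[c, w]` (broadcast product).
#' Because gates lie in `[0, 1]`, the output never exceeds the input in
#' absolute value.
#'
#' @param x 3-D array `(C, H, W)`.
#' @param gh,gw gate matrices from [ca_gates()].
#' @return array of the same shape as `x`.
#' @export
ca_apply <- function(x, gh, gw) {
  d <- dim(x)
  if (!identical(dim(gh), c(d[1], d[2])) || !identical(dim(gw), c(d[1], d[3])))
    stop("gate shapes inconsistent with x")
  xb <- as_batch(x)
  out <- xb * expand_along_w(array(gh, c(d[1], d[2], 1L)), d[3]) *
    expand_along_h(array(gw, c(d[1], d[3], 1L)), d[2])
  drop_batch(out)
}

#' Squeeze: global average pooling per channel
#'
#' @param y 3-D array `(C, H, W)`.
#' @return numeric vector of length `C` of per-channel spatial means.
#' @export
se_squeeze <- function(y) {
  yb <- as_batch(y)
  as.numeric(reduce_mean_hw(yb))
}

#' Excitation: channel weights from the squeeze descriptor
#'
#' Passes the channel descriptor through a bottleneck fully connected layer
#' with ReLU, expands back to `C` channels, and applies a sigmoid, producing
#' channel weights in `[0, 1]`.
#'
#' @param z numeric vector of length `C`.
#' @param p parameters from [make_se_params()].
#' @return numeric vector of length `C`, entries in `[0, 1]`.
#' @export
se_excite <- function(z, p) {
  if (length(z) != ncol(p$w1))
    stop(sprintf("SE parameters sized for %d channels, input has %d", ncol(p$w1), length(z)))
  a <- pmax(as.numeric(p$w1 %*% z) + p$b1, 0)
  as.numeric(sigmoid(as.numeric(p$w2 %*% a) + p$b2))
}

#' Apply excitation weights channel-wise
#'
#' @param y 3-D array `(C, H, W)`.
#' @param s numeric vector of length `C`.
#' @return array of the same shape as `y`.
#' @export
se_apply <- function(y, s) {
  d <- dim(y)
  if (length(s) != d[1]) stop("excitation vector length must equal channel count")
  y * array(s, d)  # channel is the fastest-varying dim, so this broadcasts per channel
}

#' Full CPRSCA block (functional form)
#'
#' The canonical composition: the CPRM descriptor `M = cprm(x)` is pooled
#' directionally and turned into coordinate-attention gates, which modulate
#' the block input `x`; squeeze-and-excitation then recalibrates the
#' channels of the gated map. With `cfg$use_ca = FALSE` the CPRM map itself
#' (rescaled by `C`) modulates `x`; with `cfg$use_se = FALSE` the SE stage
#' is skipped.
#'
#' @param x 3-D array `(C, H, W)`.
#' @param cfg a [cprsca_config()].
#' @param params parameter set from [make_cprsca_params()].
#' @return array of the same shape as `x`.
#' @export
cprsca <- function(x, cfg, params) {
  M <- cprm(x, cfg, params$gn, params$dsc)
  if (cfg$use_ca) {
    zp <- ca_pool(M)
    g <- ca_gates(zp$zh, zp$zw, params$ca)
    A <- ca_apply(x, g$gh, g$gw)
  } else {
    A <- x * (dim(x)[1] * M)
  }
  if (cfg$use_se) {
    s <- se_excite(se_squeeze(A), params$se)
    se_apply(A, s)
  } else {
    A
  }
}
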