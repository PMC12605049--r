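# Internal helpers over batched activation tensors.
#
# Convention: a batched feature map is a 4-D array with dim (C, H, W, N) —
# channel fastest, sample slowest — so channel-wise reductions reshape to a
# C x (H*W*N) matrix and use colSums/rowSums at C speed. A single FeatureMap
# is a 3-D (C, H, W) array; as_batch()/drop_batch() move between the two.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected a 3-D (C,H,W) or 4-D (C,H,W,N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

# mean over the W axis: (C,H,W,N) -> (C,H,N)
reduce_mean_w <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  out <- rowSums(matrix(xp, d[1] * d[2] * d[4], d[3])) / d[3]
  array(out, c(d[1], d[2], d[4]))
}

# mean over the H axis: (C,H,W,N) -> (C,W,N)
reduce_mean_h <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 3L, 4L, 2L))
  out <- rowSums(matrix(xp, d[1] * d[3] * d[4], d[2])) / d[2]
  array(out, c(d[1], d[3], d[4]))
}

# mean over both spatial axes: (C,H,W,N) -> (C,N)
reduce_mean_hw <- function(x) {
  z <- spatial_mean_cpp(x)
  array(z, dim(z))
}

# broadcast (C,H,N) along W -> (C,H,W,N)
expand_along_w <- function(g, W) {
  d <- dim(g)
  aperm(array(g, c(d[1], d[2], d[3], W)), c(1L, 2L, 4L, 3L))
}

# broadcast (C,W,N) along H -> (C,H,W,N)
expand_along_h <- function(g, H) {
  d <- dim(g)
  aperm(array(g, c(d[1], d[2], d[3], H)), c(1L, 4L, 2L, 3L))
}

# broadcast (C,N) over (H,W) -> (C,H,W,N)
expand_channelwise <- function(s, H, W) {
  d <- dim(s)
  aperm(array(s, c(d[1], d[2], H, W)), c(1L, 3L, 4L, 2L))
}

# softmax over channels at each (h, w, n); max-subtracted for overflow safety
softmax_channels <- function(x) softmax_channels_cpp(x)

# backward of softmax over channels: dx = s * (dy - sum_c(dy * s))
softmax_channels_bwd <- function(s, dy) softmax_channels_bwd_cpp(s, dy)

sigmoid <- function(x) 1 / (1 + exp(-x))

same_pad <- function(k) (k - 1L) %/% 2L

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}
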