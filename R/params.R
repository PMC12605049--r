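# Parameter constructors and initialization for the attention operations.
# Weights are drawn from a fan-in-scaled zero-mean normal (He-style), the
# standard choice ahead of ReLU; convolutions carry no bias because a
# normalization layer follows them.

init_weight <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / max(1, fan_in))), dims)
}

#' Depthwise separable convolution weights
#'
#' Builds the weight pair of a 2-D depthwise separable convolution over
#' `ci` channels with a square `k x k` spatial kernel: a depthwise stage
#' (one `k x k` filter per channel, array of dim `(ci, 1, k, k)`) and a
#' pointwise 1x1 mixing stage (dim `(ci, ci, 1, 1)`).
#'
#' @param ci channel count of the subset the convolution operates on.
#' @param k odd spatial kernel size.
#' @param init `"random"` for fan-in-scaled normal weights, `"identity"`
#'   for a centered delta depthwise kernel and identity pointwise mixing
#'   (useful for testing: the convolution is then the identity map).
#' @return list with elements `depthwise` and `pointwise`.
#' @export
make_dsc_weights <- function(ci, k, init = c("random", "identity")) {
  init <- match.arg(init)
  ci <- as.integer(ci); k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop("kernel size must be odd and >= 1")
  if (init == "identity") {
    dw <- array(0, c(ci, 1L, k, k))
    ctr <- (k + 1L) %/% 2L
    dw[, 1L, ctr, ctr] <- 1
    pw <- array(0, c(ci, ci, 1L, 1L))
    for (c in seq_len(ci)) pw[c, c, 1L, 1L] <- 1
  } else {
    dw <- init_weight(c(ci, 1L, k, k), k * k)
    pw <- init_weight(c(ci, ci, 1L, 1L), ci)
  }
  list(depthwise = dw, pointwise = pw)
}

#' Group normalization parameters
#'
#' @param C channel count; must be divisible by `num_groups`.
#' @param num_groups group count.
#' @param eps variance stabilizer (must be > 0).
#' @param gamma,beta optional per-channel scale/shift (default 1 and 0).
#' @return list with `gamma`, `beta`, `num_groups`, `eps`.
#' @export
make_gn_params <- function(C, num_groups, eps = 1e-5,
                           gamma = rep(1, C), beta = rep(0, C)) {
  C <- as.integer(C); num_groups <- as.integer(num_groups)
  if (C %% num_groups != 0L)
    stop(sprintf("channel count %d not divisible by %d groups", C, num_groups))
  if (eps <= 0) stop("eps must be positive")
  stopifnot(length(gamma) == C, length(beta) == C)
  list(gamma = as.numeric(gamma), beta = as.numeric(beta),
       num_groups = num_groups, eps = eps)
}

bottleneck_width <- function(C, r) max(1L, as.integer(ceiling(C / r)))

#' Coordinate attention parameters
#'
#' The shared 1x1 transform `w1` maps `C` channels to the bottleneck width
#' `ceiling(C / r)`; `wh` and `ww` map the bottleneck back to `C` channels
#' for the height- and width-direction gates. All stages are bias-free,
#' matching the published formulation.
#'
#' @param C channel count of the feature map the gates act on.
#' @param r reduction ratio (>= 1).
#' @return list with `w1`, `wh`, `ww`, `r`.
#' @export
make_ca_params <- function(C, r = 16L) {
  C <- as.integer(C); r <- as.integer(r)
  if (r < 1L) stop("reduction ratio must be >= 1")
  mid <- bottleneck_width(C, r)
  list(w1 = init_weight(c(mid, C), C),
       wh = init_weight(c(C, mid), mid),
       ww = init_weight(c(C, mid), mid),
       r = r)
}

#' Squeeze-and-excitation parameters
#'
#' Two fully connected layers with biases: `w1` (`ceiling(C/r) x C`) with
#' `b1`, then `w2` (`C x ceiling(C/r)`) with `b2`.
#'
#' @inheritParams make_ca_params
#' @return list with `w1`, `b1`, `w2`, `b2`, `r`.
#' @export
make_se_params <- function(C, r = 16L) {
  C <- as.integer(C); r <- as.integer(r)
  if (r < 1L) stop("reduction ratio must be >= 1")
  mid <- bottleneck_width(C, r)
  list(w1 = init_weight(c(mid, C), C), b1 = rep(0, mid),
       w2 = init_weight(c(C, mid), mid), b2 = rep(0, C),
       r = r)
}

#' Full CPRSCA parameter set for a given channel count
#'
#' @param C channel count; must be divisible by `cfg$n_subsets` and by
#'   `cfg$groupnorm_groups`.
#' @param cfg a [cprsca_config()].
#' @param init weight initialization passed to [make_dsc_weights()].
#' @return list with `dsc` (one weight pair per subset), `gn`, `ca`, `se`.
#' @export
make_cprsca_params <- function(C, cfg = cprsca_config(),
                               init = c("random", "identity")) {
  init <- match.arg(init)
  C <- as.integer(C)
  if (C %% cfg$n_subsets != 0L)
    stop(sprintf("channel count %d not divisible by n_subsets %d", C, cfg$n_subsets))
  ci <- C %/% cfg$n_subsets
  ks <- kernel_sizes(cfg)
  list(
    dsc = lapply(seq_len(cfg$n_subsets),
                 function(i) make_dsc_weights(ci, ks[i], init)),
    gn = make_gn_params(C, cfg$groupnorm_groups),
    ca = make_ca_params(C, cfg$reduction_ratio),
    se = make_se_params(C, cfg$reduction_ratio)
  )
}
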