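#' CPRSCA mechanism configuration
#'
#' Bundles the hyperparameters of the channel-partitioned resolution
#' spatial-channel attention block: how many mutually exclusive channel
#' subsets the input feature map is split into, which (odd, square) kernel
#' size each subset's depthwise separable convolution uses, the group count
#' of the group normalization that follows the multi-scale concat, and the
#' bottleneck reduction ratio shared by the coordinate-attention and
#' squeeze-and-excitation branches.
#'
#' The default kernel rule assigns subset `i` a kernel of size `2 * i + 1`,
#' i.e. sizes 3, 5, 7 and 9 under the default four-way partition, so early
#' subsets capture local detail and later subsets broader context.
#'
#' @param n_subsets number of channel subsets (default 4).
#' @param kernel_rule function mapping subset index (1-based) to an odd
#'   kernel size; default `2 * i + 1`.
#' @param groupnorm_groups group count for group normalization; defaults to
#'   `n_subsets` so normalization groups align with the resolution subsets.
#' @param reduction_ratio bottleneck reduction ratio `r` for the attention
#'   branches (default 16); the bottleneck width is `ceiling(C / r)` with a
#'   floor of 1.
#' @param use_ca,use_se logical ablation switches for the coordinate
#'   attention and squeeze-and-excitation stages. With `use_ca = FALSE` the
#'   CPRM softmax map (rescaled by C so its mean is 1) modulates the block
#'   input directly; with both `FALSE` the block is the CPRM-only variant.
#' @return an object of class `cprsca_config`.
#' @export
#' @examples
#' cfg <- cprsca_config()
#' kernel_sizes(cfg)  # 3 5 7 9
cprsca_config <- function(n_subsets = 4L,
                          kernel_rule = function(i) 2L * i + 1L,
                          groupnorm_groups = n_subsets,
                          reduction_ratio = 16L,
                          use_ca = TRUE,
                          use_se = TRUE) {
  n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L) stop("n_subsets must be >= 1")
  groupnorm_groups <- as.integer(groupnorm_groups)
  if (groupnorm_groups < 1L) stop("groupnorm_groups must be >= 1")
  reduction_ratio <- as.integer(reduction_ratio)
  if (reduction_ratio < 1L) stop("reduction_ratio must be >= 1")
  cfg <- structure(list(
    n_subsets = n_subsets,
    kernel_rule = kernel_rule,
    groupnorm_groups = groupnorm_groups,
    reduction_ratio = reduction_ratio,
    use_ca = isTRUE(use_ca),
    use_se = isTRUE(use_se)
  ), class = "cprsca_config")
  ks <- kernel_sizes(cfg)
  if (any(ks < 1L) || any(ks %% 2L == 0L))
    stop("kernel_rule must yield odd kernel sizes >= 1")
  cfg
}

#' Kernel sizes assigned to each channel subset
#'
#' Evaluates the configuration's kernel-size rule for every subset index.
#'
#' @param cfg a [cprsca_config()].
#' @return integer vector of length `n_subsets`.
#' @export
kernel_sizes <- function(cfg) {
  stopifnot(inherits(cfg, "cprsca_config"))
  vapply(seq_len(cfg$n_subsets), function(i) as.integer(cfg$kernel_rule(i)), integer(1))
}

#' @export
print.cprsca_config <- function(x, ...) {
  cat("CPRSCA config: N =", x$n_subsets,
      "| kernels =", paste(kernel_sizes(x), collapse = "/"),
      "| GN groups =", x$groupnorm_groups,
      "| r =", x$reduction_ratio,
      "| CA =", x$use_ca, "| SE =", x$use_se, "\n")
  invisible(x)
}
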