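#' CPRSCA-ResNet model configuration
#'
#' Describes a ResNet-34-style residual classifier over single-plane
#' (1 x electrodes x time) EEG windows. The stem convolution uses kernel
#' (1, 5) with stride (1, 2) followed by (1, 3)/(1, 2) max pooling; four
#' residual stages of basic blocks follow, each block carrying two (1, 3)
#' convolutions with group normalization and, unless attention is disabled,
#' one CPRSCA block on the second convolution's output before the skip
#' addition. Only the time axis is downsampled; the electrode axis is
#' preserved until global average pooling feeds a 2-class head.
#'
#' @param stage_depths integer vector of 4 block counts (default 3,4,6,3,
#'   the ResNet-34 layout).
#' @param stage_widths integer vector of 4 channel widths (default
#'   64,128,256,512); every width must be divisible by the attention
#'   config's `n_subsets` and `groupnorm_groups`.
#' @param input_channels electrode-row count of the input windows.
#' @param num_classes number of output logits (default 2: interictal/ictal).
#' @param attention a [cprsca_config()], or `NULL` for the plain-ResNet
#'   baseline with no attention blocks.
#' @return object of class `model_config`.
#' @export
model_config <- function(stage_depths = c(3L, 4L, 6L, 3L),
                         stage_widths = c(64L, 128L, 256L, 512L),
                         input_channels = 18L,
                         num_classes = 2L,
                         attention = cprsca_config()) {
  stage_depths <- as.integer(stage_depths)
  stage_widths <- as.integer(stage_widths)
  if (length(stage_depths) != 4L || length(stage_widths) != 4L)
    stop("stage_depths and stage_widths must each have length 4")
  if (any(stage_depths < 1L)) stop("stage depths must be >= 1")
  if (!is.null(attention)) {
    stopifnot(inherits(attention, "cprsca_config"))
    bad <- stage_widths %% attention$n_subsets != 0L |
      stage_widths %% attention$groupnorm_groups != 0L
    if (any(bad))
      stop("every stage width must be divisible by the attention n_subsets and groupnorm_groups")
  }
  structure(list(
    stage_depths = stage_depths,
    stage_widths = stage_widths,
    stem_kernel = c(1L, 5L),
    stem_stride = c(1L, 2L),
    input_channels = as.integer(input_channels),
    num_classes = as.integer(num_classes),
    attention = attention
  ), class = "model_config")
}

#' Small CPRSCA-ResNet configuration for desk-scale experiments
#'
#' One basic block per stage with widths 8/16/32/64 and reduction ratio 4,
#' used throughout the package's synthetic-cohort experiments and tests.
#'
#' @inheritParams model_config
#' @param use_ca,use_se ablation switches forwarded to [cprsca_config()].
#' @export
tiny_model_config <- function(input_channels = 12L, use_ca = TRUE, use_se = TRUE) {
  model_config(stage_depths = c(1L, 1L, 1L, 1L),
               stage_widths = c(8L, 16L, 32L, 64L),
               input_channels = input_channels,
               attention = cprsca_config(reduction_ratio = 4L,
                                         use_ca = use_ca, use_se = use_se))
}

new_basic_block <- function(cin, cout, stride_w, att_cfg, gn_groups, name) {
  self <- new_module()
  self$name <- name
  self$conv1 <- new_conv_layer(cin, cout, 1L, 3L, 1L, stride_w,
                               pad = c(0L, 1L), name = paste0(name, ".conv1"))
  self$gn1 <- new_gn_layer(cout, gn_groups, name = paste0(name, ".gn1"))
  self$relu1 <- new_relu_layer()
  self$conv2 <- new_conv_layer(cout, cout, 1L, 3L, 1L, 1L,
                               pad = c(0L, 1L), name = paste0(name, ".conv2"))
  self$gn2 <- new_gn_layer(cout, gn_groups, name = paste0(name, ".gn2"))
  self$att <- if (!is.null(att_cfg)) new_cprsca_layer(cout, att_cfg,
                                                      name = paste0(name, ".att"))
  self$proj <- NULL
  if (cin != cout || stride_w != 1L) {
    self$proj <- new_conv_layer(cin, cout, 1L, 1L, 1L, stride_w,
                                pad = c(0L, 0L), name = paste0(name, ".proj"))
    self$gnp <- new_gn_layer(cout, gn_groups, name = paste0(name, ".gnp"))
  }
  self$relu_out <- new_relu_layer()
  self$children <- Filter(Negate(is.null),
                          list(self$conv1, self$gn1, self$conv2, self$gn2,
                               self$att, self$proj, self$gnp))

  self$forward <- function(x) {
    h <- self$relu1$forward(self$gn1$forward(self$conv1$forward(x)))
    h <- self$gn2$forward(self$conv2$forward(h))
    if (!is.null(self$att)) h <- self$att$forward(h)
    skip <- if (!is.null(self$proj)) self$gnp$forward(self$proj$forward(x)) else x
    self$relu_out$forward(h + skip)
  }
  self$backward <- function(dout) {
    dsum <- self$relu_out$backward(dout)
    dh <- dsum
    if (!is.null(self$att)) dh <- self$att$backward(dh)
    dh <- self$conv2$backward(self$gn2$backward(dh))
    dh <- self$conv1$backward(self$gn1$backward(self$relu1$backward(dh)))
    dskip <- if (!is.null(self$proj)) self$proj$backward(self$gnp$backward(dsum)) else dsum
    dh + dskip
  }
  self
}

#' Build a CPRSCA-ResNet model
#'
#' Constructs the network deterministically from the configuration and the
#' seed: two builds with equal arguments have identical parameter arrays.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `cprsca_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(as.integer(seed))
  att <- cfg$attention
  gn_groups <- if (!is.null(att)) att$groupnorm_groups else 4L
  w <- cfg$stage_widths

  self <- new_module()
  self$config <- cfg
  self$seed <- as.integer(seed)
  self$stem_conv <- new_conv_layer(1L, w[1], cfg$stem_kernel[1], cfg$stem_kernel[2],
                                   cfg$stem_stride[1], cfg$stem_stride[2],
                                   pad = c(0L, same_pad(cfg$stem_kernel[2])),
                                   name = "stem.conv")
  self$stem_gn <- new_gn_layer(w[1], min(gn_groups, w[1]), name = "stem.gn")
  self$stem_relu <- new_relu_layer()
  self$stem_pool <- new_maxpool_layer(1L, 3L, 1L, 2L, pad = c(0L, 1L))
  self$blocks <- list()
  cin <- w[1]
  for (s in 1:4) {
    for (b in seq_len(cfg$stage_depths[s])) {
      stride_w <- if (s > 1L && b == 1L) 2L else 1L
      blk <- new_basic_block(cin, w[s], stride_w, att, gn_groups,
                             name = sprintf("stage%d.block%d", s, b))
      self$blocks <- c(self$blocks, list(blk))
      cin <- w[s]
    }
  }
  self$gap <- new_gap_layer()
  self$head <- new_dense_layer(w[4], cfg$num_classes, bias = TRUE, name = "head")
  self$children <- c(list(self$stem_conv, self$stem_gn), self$blocks,
                     list(self$head))

  # forward over a batched (1, E, S, n) tensor -> logits (num_classes x n)
  self$forward_tensor <- function(x) {
    h <- self$stem_pool$forward(
      self$stem_relu$forward(self$stem_gn$forward(self$stem_conv$forward(x))))
    for (blk in self$blocks) h <- blk$forward(h)
    self$head$forward(self$gap$forward(h))
  }
  self$backward_tensor <- function(dlogits) {
    dh <- self$gap$backward(self$head$backward(dlogits))
    for (blk in rev(self$blocks)) dh <- blk$backward(dh)
    self$stem_conv$backward(self$stem_gn$backward(
      self$stem_relu$backward(self$stem_pool$backward(dh))))
  }
  class(self) <- c("cprsca_model", class(self))
  self
}

#' Run the model on a batch of windows
#'
#' @param model a model from [build_model()].
#' @param x batch of windows as an array of dim `(n, 1, electrodes, samples)`
#'   (or `(n, electrodes, samples)`, which is unsqueezed automatically).
#' @return `n x num_classes` matrix of logits.
#' @export
model_forward <- function(model, x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d[1], 1L, d[2], d[3]); d <- dim(x) }
  if (length(d) != 4L || d[2] != 1L)
    stop("expected windows of shape (n, 1, electrodes, samples)")
  if (d[3] != model$config$input_channels)
    stop(sprintf("model expects %d electrode rows, input has %d",
                 model$config$input_channels, d[3]))
  xt <- aperm(x, c(2L, 3L, 4L, 1L))  # -> (1, E, S, n)
  t(model$forward_tensor(xt))
}

#' Per-layer parameter manifest
#'
#' @param model a model from [build_model()].
#' @return data.frame with one row per parameter array: layer name,
#'   parameter name, shape and element count.
#' @export
parameter_manifest <- function(model) {
  mods <- collect_modules(model)
  rows <- lapply(mods, function(m) {
    data.frame(layer = m$name %||% "module",
               param = m$params,
               shape = vapply(m$params, function(p)
                 paste(dim(m[[p]]) %||% length(m[[p]]), collapse = "x"), ""),
               count = vapply(m$params, function(p)
                 as.numeric(length(m[[p]])), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total trainable parameter count
#' @param model a model from [build_model()].
#' @return numeric scalar.
#' @export
num_parameters <- function(model) sum(parameter_manifest(model)$count)

serializable_config <- function(cfg) {
  att <- cfg$attention
  list(stage_depths = cfg$stage_depths,
       stage_widths = cfg$stage_widths,
       input_channels = cfg$input_channels,
       num_classes = cfg$num_classes,
       attention = if (!is.null(att))
         list(n_subsets = att$n_subsets,
              kernels = kernel_sizes(att),
              groupnorm_groups = att$groupnorm_groups,
              reduction_ratio = att$reduction_ratio,
              use_ca = att$use_ca, use_se = att$use_se))
}

config_from_serializable <- function(sc) {
  att <- if (!is.null(sc$attention)) {
    kern <- sc$attention$kernels
    cprsca_config(n_subsets = sc$attention$n_subsets,
                  kernel_rule = function(i) kern[i],
                  groupnorm_groups = sc$attention$groupnorm_groups,
                  reduction_ratio = sc$attention$reduction_ratio,
                  use_ca = sc$attention$use_ca,
                  use_se = sc$attention$use_se)
  }
  model_config(stage_depths = sc$stage_depths,
               stage_widths = sc$stage_widths,
               input_channels = sc$input_channels,
               num_classes = sc$num_classes,
               attention = att)
}

config_hash <- function(sc) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(sc, tf, version = 2L)
  unname(tools::md5sum(tf))
}

#' Save a model checkpoint
#'
#' Writes a single-file container holding every parameter array, the
#' serializable configuration, its hash, the build seed and a format
#' version. Doubles round-trip bit-exactly.
#'
#' @param model a model from [build_model()].
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  mods <- collect_modules(model)
  params <- list()
  for (m in mods)
    for (p in m$params)
      params[[paste(m$name, p, sep = "/")]] <- m[[p]]
  sc <- serializable_config(model$config)
  saveRDS(list(format_version = 1L,
               config = sc,
               config_hash = config_hash(sc),
               seed = model$seed,
               params = params),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from the embedded configuration and seed and
#' restores every parameter bit-exactly.
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param input_channels optional expected electrode-row count; an explicit
#'   incompatibility error is raised if the checkpoint disagrees.
#' @return a `cprsca_model`.
#' @export
load_checkpoint <- function(path, input_channels = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, 1L))
    stop("incompatible checkpoint format version")
  if (!identical(config_hash(ck$config), ck$config_hash))
    stop("checkpoint config hash mismatch: file corrupted or altered")
  if (!is.null(input_channels) &&
      ck$config$input_channels != as.integer(input_channels))
    stop(sprintf("checkpoint was built for %d electrode rows, expected %d",
                 ck$config$input_channels, as.integer(input_channels)))
  model <- build_model(config_from_serializable(ck$config), seed = ck$seed)
  mods <- collect_modules(model)
  for (m in mods)
    for (p in m$params) {
      key <- paste(m$name, p, sep = "/")
      v <- ck$params[[key]]
      if (is.null(v)) stop("checkpoint missing parameter ", key)
      cur <- m[[p]]
      if (!identical(dim(v) %||% length(v), dim(cur) %||% length(cur)))
        stop("checkpoint parameter shape mismatch for ", key)
      m[[p]] <- v
    }
  model
}

#' @export
print.cprsca_model <- function(x, ...) {
  cfg <- x$config
  cat("CPRSCA-ResNet:",
      paste(cfg$stage_depths, collapse = ","), "blocks x",
      paste(cfg$stage_widths, collapse = ","), "channels;",
      cfg$input_channels, "electrode rows;",
      format(num_parameters(x), big.mark = ","), "parameters\n")
  if (is.null(cfg$attention)) cat("attention: disabled (baseline)\n")
  else print(cfg$attention)
  invisible(x)
}
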