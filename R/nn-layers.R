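# Trainable layers: each layer is an environment holding its parameter
# arrays, matching gradient accumulators named "g_<param>", a forward()
# that caches what backward() needs, and a backward() that returns the
# gradient w.r.t. its input. Containers expose $children so the optimizer
# can walk the tree. Every gradient here is checked against finite
# differences in the test suite.

new_module <- function(param_names = character()) {
  self <- new.env(parent = emptyenv())
  self$params <- param_names
  self$children <- list()
  self
}

zero_grads <- function(layers) {
  for (l in layers)
    for (p in l$params)
      l[[paste0("g_", p)]] <- array(0, dim = dim(l[[p]]) %||% length(l[[p]]))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a module tree into the list of param-bearing leaves, in order.
collect_modules <- function(mod) {
  out <- list()
  if (length(mod$params) > 0) out <- list(mod)
  for (ch in mod$children) out <- c(out, collect_modules(ch))
  out
}

new_conv_layer <- function(cin, cout, kh, kw, sh = 1L, sw = 1L,
                           groups = 1L, pad = c(same_pad(kh), same_pad(kw)),
                           name = "conv") {
  self <- new_module("w")
  self$name <- name
  self$kh <- as.integer(kh); self$kw <- as.integer(kw)
  self$sh <- as.integer(sh); self$sw <- as.integer(sw)
  self$ph <- as.integer(pad[1]); self$pw <- as.integer(pad[2])
  self$groups <- as.integer(groups)
  cg <- as.integer(cin) %/% self$groups
  self$w <- init_weight(c(as.integer(cout), cg, self$kh, self$kw), cg * kh * kw)
  self$g_w <- array(0, dim(self$w))
  self$forward <- function(x) {
    self$x <- x
    conv2d_fwd_cpp(x, self$w, self$sh, self$sw, self$ph, self$pw, self$groups)
  }
  self$backward <- function(dout) {
    r <- conv2d_bwd_cpp(self$x, self$w, dout, self$sh, self$sw,
                        self$ph, self$pw, self$groups)
    self$g_w <- self$g_w + r$dw
    r$dx
  }
  self
}

new_gn_layer <- function(C, num_groups, eps = 1e-5, name = "gn") {
  self <- new_module(c("gamma", "beta"))
  self$name <- name
  self$C <- as.integer(C)
  if (self$C %% num_groups != 0L)
    stop(sprintf("group norm: %d channels not divisible by %d groups", C, num_groups))
  self$num_groups <- as.integer(num_groups)
  self$eps <- eps
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  self$g_gamma <- rep(0, C); self$g_beta <- rep(0, C)
  self$forward <- function(x) {
    gn <- list(gamma = self$gamma, beta = self$beta,
               num_groups = self$num_groups, eps = self$eps)
    r <- gn_forward(x, gn)
    self$cache <- r
    r$out
  }
  self$backward <- function(dout) {
    gn <- list(gamma = self$gamma, beta = self$beta,
               num_groups = self$num_groups, eps = self$eps)
    r <- gn_backward(self$cache, gn, dout)
    self$g_gamma <- self$g_gamma + r$dgamma
    self$g_beta <- self$g_beta + r$dbeta
    r$dx
  }
  self
}

new_relu_layer <- function(name = "relu") {
  self <- new_module()
  self$name <- name
  self$forward <- function(x) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(dout) dout * self$mask
  self
}

new_maxpool_layer <- function(kh, kw, sh, sw,
                              pad = c(same_pad(kh), same_pad(kw)),
                              name = "maxpool") {
  self <- new_module()
  self$name <- name
  self$forward <- function(x) {
    self$in_dim <- dim(x)
    r <- maxpool2d_fwd_cpp(x, as.integer(kh), as.integer(kw),
                           as.integer(sh), as.integer(sw),
                           as.integer(pad[1]), as.integer(pad[2]))
    self$argmax <- r$argmax
    r$out
  }
  self$backward <- function(dout) {
    maxpool2d_bwd_cpp(dout, self$argmax, self$in_dim)
  }
  self
}

# global average pool: (C,H,W,N) -> C x N matrix
new_gap_layer <- function(name = "gap") {
  self <- new_module()
  self$name <- name
  self$forward <- function(x) {
    self$in_dim <- dim(x)
    spatial_mean_cpp(x)
  }
  self$backward <- function(dout) {
    d <- self$in_dim
    channel_broadcast_cpp(as.matrix(dout), d[2], d[3], 1 / (d[2] * d[3]))
  }
  self
}

# fully connected over C x N column-sample matrices
new_dense_layer <- function(cin, cout, bias = TRUE, name = "fc") {
  self <- new_module(if (bias) c("w", "b") else "w")
  self$name <- name
  self$w <- init_weight(c(as.integer(cout), as.integer(cin)), cin)
  self$g_w <- array(0, dim(self$w))
  if (bias) { self$b <- rep(0, cout); self$g_b <- rep(0, cout) }
  self$forward <- function(x) {
    self$x <- x
    out <- self$w %*% x
    if (!is.null(self$b)) out <- out + self$b
    out
  }
  self$backward <- function(dout) {
    self$g_w <- self$g_w + dout %*% t(self$x)
    if (!is.null(self$b)) self$g_b <- self$g_b + rowSums(dout)
    t(self$w) %*% dout
  }
  self
}
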