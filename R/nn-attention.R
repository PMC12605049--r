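# Trainable CPRSCA block over batched tensors (C,H,W,N), with a manually
# derived backward pass. The forward computation mirrors the functional
# composition in attention-ops.R: a CPRM descriptor gates the block input
# through coordinate attention, and squeeze-and-excitation recalibrates
# the gated map's channels. The backward pass is verified against finite
# differences and the functional ops in the test suite.

new_cprsca_layer <- function(C, cfg, name = "cprsca") {
  C <- as.integer(C)
  if (C %% cfg$n_subsets != 0L)
    stop(sprintf("CPRSCA: %d channels not divisible by %d subsets", C, cfg$n_subsets))
  if (C %% cfg$groupnorm_groups != 0L)
    stop(sprintf("CPRSCA: %d channels not divisible by %d normalization groups",
                 C, cfg$groupnorm_groups))
  N <- cfg$n_subsets
  ci <- C %/% N
  ks <- kernel_sizes(cfg)
  mid <- bottleneck_width(C, cfg$reduction_ratio)

  pnames <- c(paste0("dw", seq_len(N)), paste0("pw", seq_len(N)), "gamma", "beta")
  if (cfg$use_ca) pnames <- c(pnames, "ca_w1", "ca_wh", "ca_ww")
  if (cfg$use_se) pnames <- c(pnames, "se_w1", "se_b1", "se_w2", "se_b2")
  self <- new_module(pnames)
  self$name <- name
  self$C <- C; self$cfg <- cfg; self$ci <- ci; self$ks <- ks; self$mid <- mid

  for (i in seq_len(N)) {
    wts <- make_dsc_weights(ci, ks[i])
    self[[paste0("dw", i)]] <- wts$depthwise
    self[[paste0("pw", i)]] <- wts$pointwise
  }
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  if (cfg$use_ca) {
    cap <- make_ca_params(C, cfg$reduction_ratio)
    self$ca_w1 <- cap$w1; self$ca_wh <- cap$wh; self$ca_ww <- cap$ww
  }
  if (cfg$use_se) {
    sep <- make_se_params(C, cfg$reduction_ratio)
    self$se_w1 <- sep$w1; self$se_b1 <- sep$b1
    self$se_w2 <- sep$w2; self$se_b2 <- sep$b2
  }
  for (p in self$params)
    self[[paste0("g_", p)]] <- array(0, dim = dim(self[[p]]) %||% length(self[[p]]))

  subset_idx <- function(i) ((i - 1L) * ci + 1L):(i * ci)

  self$forward <- function(x) {
    d <- dim(x); H <- d[2]; W <- d[3]; n <- d[4]
    self$x <- x
    # --- CPRM: per-subset depthwise separable conv, concat, GN, softmax
    xp <- x
    self$dsc_mid <- vector("list", N)
    for (i in seq_len(N)) {
      p <- same_pad(ks[i])
      di <- conv2d_fwd_cpp(x[subset_idx(i), , , , drop = FALSE],
                           self[[paste0("dw", i)]], 1L, 1L, p, p, ci)
      self$dsc_mid[[i]] <- di
      xp[subset_idx(i), , , ] <- conv2d_fwd_cpp(di, self[[paste0("pw", i)]],
                                                1L, 1L, 0L, 0L, 1L)
    }
    gn <- list(gamma = self$gamma, beta = self$beta,
               num_groups = cfg$groupnorm_groups, eps = 1e-5)
    self$gn_cache <- gn_forward(xp, gn)
    M <- softmax_channels(self$gn_cache$out)
    self$M <- M
    # --- coordinate attention on the block input, gated by the descriptor
    if (cfg$use_ca) {
      zz <- directional_means_cpp(M)               # zh (C,H,n), zw (C,W,n)
      U <- array(0, c(C, H + W, n))
      U[, seq_len(H), ] <- zz$zh
      U[, H + seq_len(W), ] <- zz$zw
      Umat <- matrix(U, C, (H + W) * n)
      f <- pmax(self$ca_w1 %*% Umat, 0)            # (mid, (H+W)*n)
      farr <- array(f, c(mid, H + W, n))
      fh <- matrix(farr[, seq_len(H), , drop = FALSE], mid, H * n)
      fw <- matrix(farr[, H + seq_len(W), , drop = FALSE], mid, W * n)
      gh <- sigmoid(self$ca_wh %*% fh)             # (C, H*n)
      gw <- sigmoid(self$ca_ww %*% fw)             # (C, W*n)
      gh_arr <- array(gh, c(C, H, n))
      gw_arr <- array(gw, c(C, W, n))
      A <- ca_modulate_fwd_cpp(x, gh_arr, gw_arr)
      self$ca_cache <- list(Umat = Umat, f = f, fh = fh, fw = fw,
                            gh = gh, gw = gw, gh_arr = gh_arr, gw_arr = gw_arr,
                            H = H, W = W, n = n)
    } else {
      A <- x * (C * M)
    }
    self$A <- A
    # --- squeeze-and-excitation on the gated map
    if (cfg$use_se) {
      z <- spatial_mean_cpp(A)                     # (C, n)
      a <- pmax(self$se_w1 %*% z + self$se_b1, 0)
      s <- sigmoid(self$se_w2 %*% a + self$se_b2)  # (C, n)
      self$se_cache <- list(z = z, a = a, s = s)
      out <- channel_scale_fwd_cpp(A, s)
    } else {
      out <- A
    }
    out
  }

  self$backward <- function(dout) {
    d <- dim(self$x); H <- d[2]; W <- d[3]; n <- d[4]
    # --- SE backward
    if (cfg$use_se) {
      sc <- self$se_cache
      sb <- channel_scale_bwd_cpp(self$A, sc$s, dout)
      dA <- sb$da
      dspre <- sb$ds * sc$s * (1 - sc$s)
      self$g_se_w2 <- self$g_se_w2 + dspre %*% t(sc$a)
      self$g_se_b2 <- self$g_se_b2 + rowSums(dspre)
      da <- (t(self$se_w2) %*% dspre) * (sc$a > 0)
      self$g_se_w1 <- self$g_se_w1 + da %*% t(sc$z)
      self$g_se_b1 <- self$g_se_b1 + rowSums(da)
      dz <- t(self$se_w1) %*% da
      dA <- dA + channel_broadcast_cpp(dz, H, W, 1 / (H * W))
    } else {
      dA <- dout
    }
    # --- CA backward (or direct CPRM modulation backward)
    if (cfg$use_ca) {
      cc <- self$ca_cache
      cb <- ca_modulate_bwd_cpp(self$x, cc$gh_arr, cc$gw_arr, dA)
      dx <- cb$dx
      dgh <- matrix(cb$dgh, C, H * n)
      dgw <- matrix(cb$dgw, C, W * n)
      dah <- dgh * cc$gh * (1 - cc$gh)
      daw <- dgw * cc$gw * (1 - cc$gw)
      self$g_ca_wh <- self$g_ca_wh + dah %*% t(cc$fh)
      self$g_ca_ww <- self$g_ca_ww + daw %*% t(cc$fw)
      dfh <- t(self$ca_wh) %*% dah
      dfw <- t(self$ca_ww) %*% daw
      dfarr <- array(0, c(mid, H + W, n))
      dfarr[, seq_len(H), ] <- array(dfh, c(mid, H, n))
      dfarr[, H + seq_len(W), ] <- array(dfw, c(mid, W, n))
      dpre <- matrix(dfarr, mid, (H + W) * n) * (cc$f > 0)
      self$g_ca_w1 <- self$g_ca_w1 + dpre %*% t(cc$Umat)
      dU <- array(t(self$ca_w1) %*% dpre, c(C, H + W, n))
      dzh <- array(dU[, seq_len(H), , drop = FALSE], c(C, H, n))
      dzw <- array(dU[, H + seq_len(W), , drop = FALSE], c(C, W, n))
      dM <- directional_means_bwd_cpp(dzh, dzw)
    } else {
      dx <- dA * (C * self$M)
      dM <- C * (dA * self$x)
    }
    # --- CPRM backward: softmax -> GN -> per-subset DSC
    dXpp <- softmax_channels_bwd(self$M, dM)
    gn <- list(gamma = self$gamma, beta = self$beta,
               num_groups = cfg$groupnorm_groups, eps = 1e-5)
    gb <- gn_backward(self$gn_cache, gn, dXpp)
    self$g_gamma <- self$g_gamma + gb$dgamma
    self$g_beta <- self$g_beta + gb$dbeta
    dXp <- gb$dx
    for (i in seq_len(N)) {
      idx <- subset_idx(i)
      p <- same_pad(ks[i])
      rp <- conv2d_bwd_cpp(self$dsc_mid[[i]], self[[paste0("pw", i)]],
                           dXp[idx, , , , drop = FALSE], 1L, 1L, 0L, 0L, 1L)
      self[[paste0("g_pw", i)]] <- self[[paste0("g_pw", i)]] + rp$dw
      rd <- conv2d_bwd_cpp(self$x[idx, , , , drop = FALSE],
                           self[[paste0("dw", i)]], rp$dx, 1L, 1L, p, p, ci)
      self[[paste0("g_dw", i)]] <- self[[paste0("g_dw", i)]] + rd$dw
      dx[idx, , , ] <- dx[idx, , , , drop = FALSE] + rd$dx
    }
    dx
  }

  self
}
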