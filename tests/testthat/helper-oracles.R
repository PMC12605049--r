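# Independent explicit-loop re-implementations of every attention equation,
# used as oracles against the package's vectorized/compiled paths. These
# deliberately share no code with the package internals.

oracle_conv2d <- function(x, w, sh, sw, ph, pw, groups) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  wd <- dim(w); Cout <- wd[1]; cg <- wd[2]; kh <- wd[3]; kw <- wd[4]
  Kg <- Cout / groups
  Ho <- (H + 2 * ph - kh) %/% sh + 1
  Wo <- (W + 2 * pw - kw) %/% sw + 1
  out <- array(0, c(Cout, Ho, Wo))
  for (o in 1:Cout) {
    g <- (o - 1) %/% Kg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- 0
      for (ci in 1:cg) for (a in 1:kh) for (b in 1:kw) {
        h <- (ho - 1) * sh - ph + a
        wv <- (wo - 1) * sw - pw + b
        if (h >= 1 && h <= H && wv >= 1 && wv <= W)
          acc <- acc + x[g * cg + ci, h, wv] * w[o, ci, a, b]
      }
      out[o, ho, wo] <- acc
    }
  }
  out
}

oracle_dsc2d <- function(xi, k, weights) {
  ci <- dim(xi)[1]
  p <- (k - 1) %/% 2
  mid <- oracle_conv2d(xi, weights$depthwise, 1, 1, p, p, groups = ci)
  oracle_conv2d(mid, weights$pointwise, 1, 1, 0, 0, groups = 1)
}

oracle_group_normalize <- function(x, gn) {
  d <- dim(x); C <- d[1]
  cg <- C / gn$num_groups
  out <- x
  for (g in seq_len(gn$num_groups)) {
    idx <- ((g - 1) * cg + 1):(g * cg)
    v <- as.numeric(x[idx, , , drop = FALSE])
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2) + gn$eps)
    for (c in idx) for (h in 1:d[2]) for (w in 1:d[3])
      out[c, h, w] <- (x[c, h, w] - mu) / sigma * gn$gamma[c] + gn$beta[c]
  }
  out
}

oracle_channel_softmax <- function(x) {
  d <- dim(x)
  out <- x
  for (h in 1:d[2]) for (w in 1:d[3]) {
    v <- x[, h, w]
    e <- exp(v - max(v))
    out[, h, w] <- e / sum(e)
  }
  out
}

oracle_cprm <- function(x, cfg, gn, weights) {
  C <- dim(x)[1]
  ci <- C / cfg$n_subsets
  xp <- x
  for (i in seq_len(cfg$n_subsets)) {
    idx <- ((i - 1) * ci + 1):(i * ci)
    k <- cfg$kernel_rule(i)
    xp[idx, , ] <- oracle_dsc2d(x[idx, , , drop = FALSE], k, weights[[i]])
  }
  oracle_channel_softmax(oracle_group_normalize(xp, gn))
}

oracle_ca_pool <- function(y) {
  d <- dim(y)
  zh <- matrix(0, d[1], d[2]); zw <- matrix(0, d[1], d[3])
  for (c in 1:d[1]) {
    for (h in 1:d[2]) zh[c, h] <- mean(y[c, h, ])
    for (w in 1:d[3]) zw[c, w] <- mean(y[c, , w])
  }
  list(zh = zh, zw = zw)
}

oracle_ca_gates <- function(zh, zw, p) {
  H <- ncol(zh); W <- ncol(zw)
  U <- cbind(zh, zw)
  mid <- nrow(p$w1)
  f <- matrix(0, mid, H + W)
  for (i in 1:mid) for (j in 1:(H + W))
    f[i, j] <- max(0, sum(p$w1[i, ] * U[, j]))
  gh <- matrix(0, nrow(zh), H); gw <- matrix(0, nrow(zw), W)
  for (c in 1:nrow(zh)) {
    for (h in 1:H) gh[c, h] <- 1 / (1 + exp(-sum(p$wh[c, ] * f[, h])))
    for (w in 1:W) gw[c, w] <- 1 / (1 + exp(-sum(p$ww[c, ] * f[, H + w])))
  }
  list(gh = gh, gw = gw)
}

oracle_ca_apply <- function(x, gh, gw) {
  d <- dim(x)
  out <- x
  for (c in 1:d[1]) for (h in 1:d[2]) for (w in 1:d[3])
    out[c, h, w] <- x[c, h, w] * gh[c, h] * gw[c, w]
  out
}

oracle_se_squeeze <- function(y) {
  d <- dim(y)
  vapply(1:d[1], function(c) mean(y[c, , ]), numeric(1))
}

oracle_se_excite <- function(z, p) {
  mid <- nrow(p$w1); C <- length(z)
  a <- numeric(mid)
  for (i in 1:mid) a[i] <- max(0, sum(p$w1[i, ] * z) + p$b1[i])
  s <- numeric(C)
  for (c in 1:C) s[c] <- 1 / (1 + exp(-(sum(p$w2[c, ] * a) + p$b2[c])))
  s
}

oracle_se_apply <- function(y, s) {
  d <- dim(y)
  out <- y
  for (c in 1:d[1]) out[c, , ] <- y[c, , ] * s[c]
  out
}

oracle_cprsca <- function(x, cfg, params) {
  M <- oracle_cprm(x, cfg, params$gn, params$dsc)
  if (cfg$use_ca) {
    zp <- oracle_ca_pool(M)
    g <- oracle_ca_gates(zp$zh, zp$zw, params$ca)
    A <- oracle_ca_apply(x, g$gh, g$gw)
  } else {
    A <- x * dim(x)[1] * M
  }
  if (cfg$use_se) {
    s <- oracle_se_excite(oracle_se_squeeze(A), params$se)
    oracle_se_apply(A, s)
  } else {
    A
  }
}

# random small feature map
rand_map <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))
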