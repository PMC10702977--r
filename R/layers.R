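# Internal layer math for the residual network. Feature maps are 3-d arrays
# (H, W, C); one sample at a time (GroupNorm is per-sample, so batches are
# independent). Convolutions call the compiled im2col kernels.

gn_eps <- 1e-5

# GroupNorm forward: normalize over (H, W, channels-in-group) per group,
# then per-channel affine. Internally feature maps are reshaped to
# (H*W) x C matrices so group statistics are plain column-block reductions.
gn_fwd <- function(x, gamma, beta, groups) {
  d <- dim(x)
  C <- d[3]
  cg <- C / groups
  m <- matrix(x, d[1] * d[2], C)
  xhat <- m
  invstd <- numeric(groups)
  for (g in seq_len(groups)) {
    chs <- ((g - 1) * cg + 1):(g * cg)
    sub <- m[, chs, drop = FALSE]
    mu <- mean(sub)
    v <- mean(sub * sub) - mu * mu
    invstd[g] <- 1 / sqrt(max(v, 0) + gn_eps)
    xhat[, chs] <- (sub - mu) * invstd[g]
  }
  y <- xhat * rep(gamma, each = d[1] * d[2]) +
    rep(beta, each = d[1] * d[2])
  dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, gamma = gamma, groups = groups,
       d = d)
}

gn_bwd <- function(cache, dy) {
  d <- cache$d
  xhat <- cache$xhat           # (H*W) x C
  groups <- cache$groups
  C <- d[3]
  cg <- C / groups
  dym <- matrix(dy, d[1] * d[2], C)
  dxh <- dym * rep(cache$gamma, each = d[1] * d[2])
  dx <- dxh
  for (g in seq_len(groups)) {
    chs <- ((g - 1) * cg + 1):(g * cg)
    xs <- xhat[, chs, drop = FALSE]
    ds <- dxh[, chs, drop = FALSE]
    dx[, chs] <- cache$invstd[g] * (ds - mean(ds) - xs * mean(ds * xs))
  }
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

as_wmat <- function(W) matrix(W, ncol = dim(W)[4])

# forward pass for one sample; x0 is an H x W matrix
sample_forward <- function(net, x0, keep_cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  x <- array(x0, dim = c(dim(x0), 1L))
  cache <- if (keep_cache) list(stages = vector("list", length(cfg$stage_widths)))
  for (s in seq_along(cfg$stage_widths)) {
    nm <- function(part) sprintf("s%d.%s", s, part)
    a1 <- conv2d_fwd(x, as_wmat(p[[nm("conv_a.W")]]), p[[nm("conv_a.b")]], 3L)
    g1 <- gn_fwd(a1, p[[nm("gn_a.gamma")]], p[[nm("gn_a.beta")]], cfg$gn_groups)
    r1 <- relu(g1$y)
    a2 <- conv2d_fwd(r1, as_wmat(p[[nm("conv_b.W")]]), p[[nm("conv_b.b")]], 3L)
    g2 <- gn_fwd(a2, p[[nm("gn_b.gamma")]], p[[nm("gn_b.beta")]], cfg$gn_groups)
    if (cfg$residual) {
      short <- if (!is.null(p[[nm("proj.W")]]))
        conv2d_fwd(x, as_wmat(p[[nm("proj.W")]]), p[[nm("proj.b")]], 1L)
      else x
      pre <- g2$y + short
    } else {
      pre <- g2$y
    }
    r2 <- relu(pre)
    pl <- maxpool2_fwd(r2)
    if (keep_cache)
      cache$stages[[s]] <- list(x_in = x, g1 = g1, r1 = r1, g2 = g2,
                                pre = pre, pool_idx = pl$idx,
                                pool_in_dim = dim(r2))
    x <- pl$Y
  }
  feat_dim <- dim(x)
  gap <- colMeans(matrix(x, feat_dim[1] * feat_dim[2], feat_dim[3]))
  h1 <- drop(crossprod(p[["head.fc1.W"]], gap)) + p[["head.fc1.b"]]
  rh <- pmax(h1, 0)
  logits <- drop(crossprod(p[["head.fc2.W"]], rh)) + p[["head.fc2.b"]]
  if (keep_cache) {
    cache$feat_dim <- feat_dim
    cache$gap <- gap
    cache$h1 <- h1
    cache$rh <- rh
  }
  list(logits = logits, cache = cache)
}

# backward pass for one sample; dlogits is a length-C vector.
# Returns a named list of gradients matching net$params.
sample_backward <- function(net, cache, dlogits) {
  cfg <- net$cfg
  p <- net$params
  gr <- list()
  gr[["head.fc2.W"]] <- cache$rh %*% t(dlogits)
  gr[["head.fc2.b"]] <- dlogits
  drh <- drop(p[["head.fc2.W"]] %*% dlogits)
  dh1 <- drh * (cache$h1 > 0)
  gr[["head.fc1.W"]] <- cache$gap %*% t(dh1)
  gr[["head.fc1.b"]] <- dh1
  dgap <- drop(p[["head.fc1.W"]] %*% dh1)
  fd <- cache$feat_dim
  dx <- array(rep(dgap / (fd[1] * fd[2]), each = fd[1] * fd[2]), dim = fd)
  for (s in rev(seq_along(cfg$stage_widths))) {
    nm <- function(part) sprintf("s%d.%s", s, part)
    st <- cache$stages[[s]]
    dr2 <- maxpool2_bwd(dx, st$pool_idx, st$pool_in_dim[1], st$pool_in_dim[2])
    dpre <- dr2 * (st$pre > 0)
    gb2 <- gn_bwd(st$g2, dpre)
    gr[[nm("gn_b.gamma")]] <- gb2$dgamma
    gr[[nm("gn_b.beta")]] <- gb2$dbeta
    cb2 <- conv2d_bwd(st$r1, as_wmat(p[[nm("conv_b.W")]]), gb2$dx, 3L)
    gr[[nm("conv_b.W")]] <- array(cb2$dW, dim = dim(p[[nm("conv_b.W")]]))
    gr[[nm("conv_b.b")]] <- drop(cb2$db)
    dg1y <- cb2$dX * (st$g1$y > 0)
    gb1 <- gn_bwd(st$g1, dg1y)
    gr[[nm("gn_a.gamma")]] <- gb1$dgamma
    gr[[nm("gn_a.beta")]] <- gb1$dbeta
    cb1 <- conv2d_bwd(st$x_in, as_wmat(p[[nm("conv_a.W")]]), gb1$dx, 3L)
    gr[[nm("conv_a.W")]] <- array(cb1$dW, dim = dim(p[[nm("conv_a.W")]]))
    gr[[nm("conv_a.b")]] <- drop(cb1$db)
    dx_in <- cb1$dX
    if (cfg$residual) {
      if (!is.null(p[[nm("proj.W")]])) {
        cbp <- conv2d_bwd(st$x_in, as_wmat(p[[nm("proj.W")]]), dpre, 1L)
        gr[[nm("proj.W")]] <- array(cbp$dW, dim = dim(p[[nm("proj.W")]]))
        gr[[nm("proj.b")]] <- drop(cbp$db)
        dx_in <- dx_in + cbp$dX
      } else {
        dx_in <- dx_in + dpre
      }
    }
    dx <- dx_in
  }
  gr
}

# batch forward: xs is a list of H x W matrices; returns logits matrix and,
# when requested, per-sample caches
batch_forward <- function(net, xs, keep_cache = FALSE) {
  n <- length(xs)
  C <- net$cfg$n_classes
  logits <- matrix(0, n, C)
  caches <- if (keep_cache) vector("list", n)
  for (i in seq_len(n)) {
    fw <- sample_forward(net, xs[[i]], keep_cache)
    logits[i, ] <- fw$logits
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(logits = logits, caches = caches)
}

# batch backward: sums per-sample parameter gradients
batch_backward <- function(net, caches, dlogits) {
  total <- NULL
  for (i in seq_along(caches)) {
    gi <- sample_backward(net, caches[[i]], dlogits[i, ])
    if (is.null(total)) total <- gi
    else for (k in names(gi)) total[[k]] <- total[[k]] + gi[[k]]
  }
  total
}
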