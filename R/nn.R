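# Hand-rolled 3D convolutional network layers with explicit backward passes.
# Activations are 5D arrays dim c(nx, ny, nz, C, N); convolution is im2col
# (C++ kernel) followed by one GEMM per example through R's BLAS.

.he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        c(k, k, k, cin, cout))
}

.layer_conv <- function(k, cin, cout, circular) {
  list(type = "conv", k = k, cin = cin, cout = cout, circular = circular,
       W = .he_conv(k, cin, cout), b = numeric(cout))
}
.layer_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c), momentum = 0.1, eps = 1e-5)
}
.layer_se <- function(c, reduction) {
  cr <- max(1L, c %/% reduction)
  list(type = "se", c = c, cr = cr,
       W1 = matrix(stats::rnorm(cr * c, 0, sqrt(2 / c)), cr, c),
       b1 = numeric(cr),
       W2 = matrix(stats::rnorm(c * cr, 0, sqrt(2 / cr)), c, cr),
       b2 = numeric(c))
}
.layer_simple <- function(type) list(type = type)
.layer_resblock <- function(k, c, use_se, se_reduction) {
  list(type = "resblock",
       conv1 = .layer_conv(k, c, c, circular = TRUE),
       bn1 = .layer_bn(c),
       conv2 = .layer_conv(k, c, c, circular = TRUE),
       bn2 = .layer_bn(c),
       se = if (use_se) .layer_se(c, se_reduction) else NULL)
}

# The im2col matrices built in the forward pass are kept in the cache so the
# backward pass does not have to rebuild them (they dominate the runtime of
# small models; memory stays modest at desk-scale batch sizes).
.conv_fwd <- function(layer, x) {
  d <- dim(x); nx <- d[1]; ny <- d[2]; nz <- d[3]; N <- d[5]
  nvox <- nx * ny * nz
  Wmat <- matrix(layer$W, nrow = layer$k^3 * layer$cin)
  out <- array(0, c(nx, ny, nz, layer$cout, N))
  cols_list <- vector("list", N)
  for (n in seq_len(N)) {
    cols <- pn_im2col(as.vector(x[, , , , n]), nx, ny, nz, layer$cin,
                      layer$k, layer$circular)
    y <- cols %*% Wmat
    out[, , , , n] <- array(y + rep(layer$b, each = nvox),
                            c(nx, ny, nz, layer$cout))
    cols_list[[n]] <- cols
  }
  list(out = out, cache = list(dim = d, cols = cols_list))
}

.conv_bwd <- function(layer, dout, cache) {
  d <- cache$dim; nx <- d[1]; ny <- d[2]; nz <- d[3]; N <- d[5]
  nvox <- nx * ny * nz
  Wmat <- matrix(layer$W, nrow = layer$k^3 * layer$cin)
  dW <- array(0, dim(layer$W)); db <- numeric(layer$cout)
  dx <- array(0, d)
  for (n in seq_len(N)) {
    dmat <- matrix(dout[, , , , n], nvox, layer$cout)
    dW <- dW + array(crossprod(cache$cols[[n]], dmat), dim(layer$W))
    db <- db + colSums(dmat)
    dxn <- pn_col2im(dmat %*% t(Wmat), nx, ny, nz, layer$cin, layer$k,
                     layer$circular)
    dx[, , , , n] <- array(dxn, c(nx, ny, nz, layer$cin))
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

.bn_fwd <- function(layer, x, training) {
  C <- layer$c
  out <- x
  xhat <- x
  ivar <- numeric(C)
  mu_b <- numeric(C); var_b <- numeric(C)
  for (ci in seq_len(C)) {
    xs <- x[, , , ci, ]
    if (training) {
      mu <- mean(xs)
      v <- mean((xs - mu)^2)
      mu_b[ci] <- mu; var_b[ci] <- v
    } else {
      mu <- layer$rmean[ci]; v <- layer$rvar[ci]
    }
    iv <- 1 / sqrt(v + layer$eps)
    xh <- (xs - mu) * iv
    xhat[, , , ci, ] <- xh
    out[, , , ci, ] <- layer$gamma[ci] * xh + layer$beta[ci]
    ivar[ci] <- iv
  }
  list(out = out,
       cache = list(xhat = xhat, ivar = ivar),
       batch_stats = if (training) list(mean = mu_b, var = var_b) else NULL)
}

.bn_bwd <- function(layer, dout, cache) {
  C <- layer$c
  dx <- dout
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (ci in seq_len(C)) {
    dy <- dout[, , , ci, ]
    xh <- cache$xhat[, , , ci, ]
    m <- length(dy)
    dgamma[ci] <- sum(dy * xh)
    dbeta[ci] <- sum(dy)
    dxh <- dy * layer$gamma[ci]
    dx[, , , ci, ] <- cache$ivar[ci] / m *
      (m * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.se_fwd <- function(layer, x) {
  d <- dim(x); nvox <- d[1] * d[2] * d[3]; C <- d[4]; N <- d[5]
  out <- x
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    xm <- matrix(x[, , , , n], nvox, C)
    s <- colMeans(xm)
    hpre <- as.vector(layer$W1 %*% s + layer$b1)
    h <- pmax(hpre, 0)
    g <- 1 / (1 + exp(-(as.vector(layer$W2 %*% h + layer$b2))))
    out[, , , , n] <- array(xm * rep(g, each = nvox), d[1:4])
    cache[[n]] <- list(s = s, hpre = hpre, h = h, g = g)
  }
  list(out = out, cache = list(x = x, per_n = cache))
}

.se_bwd <- function(layer, dout, cache) {
  x <- cache$x
  d <- dim(x); nvox <- d[1] * d[2] * d[3]; C <- d[4]; N <- d[5]
  dx <- array(0, d)
  dW1 <- matrix(0, nrow(layer$W1), ncol(layer$W1)); db1 <- numeric(layer$cr)
  dW2 <- matrix(0, nrow(layer$W2), ncol(layer$W2)); db2 <- numeric(C)
  for (n in seq_len(N)) {
    cc <- cache$per_n[[n]]
    xm <- matrix(x[, , , , n], nvox, C)
    dm <- matrix(dout[, , , , n], nvox, C)
    dg <- colSums(dm * xm)
    dxm <- dm * rep(cc$g, each = nvox)
    dz2 <- dg * cc$g * (1 - cc$g)
    dW2 <- dW2 + dz2 %*% t(cc$h); db2 <- db2 + dz2
    dh <- as.vector(crossprod(layer$W2, dz2)) * (cc$hpre > 0)
    dW1 <- dW1 + dh %*% t(cc$s); db1 <- db1 + dh
    ds <- as.vector(crossprod(layer$W1, dh))
    dxm <- dxm + rep(ds / nvox, each = nvox)
    dx[, , , , n] <- array(dxm, d[1:4])
  }
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

.pool_fwd <- function(x) {
  d <- dim(x); nx <- d[1]; ny <- d[2]; nz <- d[3]; C <- d[4]; N <- d[5]
  if (any(d[1:3] %% 2 != 0)) {
    stop("max pooling requires even voxel counts per axis", call. = FALSE)
  }
  out <- array(0, c(nx / 2, ny / 2, nz / 2, C, N))
  arg <- vector("list", N)
  for (n in seq_len(N)) {
    r <- pn_maxpool(as.vector(x[, , , , n]), nx, ny, nz, C)
    out[, , , , n] <- array(r$out, c(nx / 2, ny / 2, nz / 2, C))
    arg[[n]] <- r$argmax
  }
  list(out = out, cache = list(argmax = arg, in_dim = d))
}

.pool_bwd <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  n_in <- prod(d[1:4])
  for (n in seq_len(d[5])) {
    dx[, , , , n] <- array(
      pn_maxpool_bwd(as.vector(dout[, , , , n]), cache$argmax[[n]], n_in),
      d[1:4])
  }
  list(dx = dx, grads = NULL)
}

.up_fwd <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], 2 * d[3], d[4], d[5]))
  for (n in seq_len(d[5])) {
    out[, , , , n] <- array(
      pn_upsample(as.vector(x[, , , , n]), d[1], d[2], d[3], d[4]),
      c(2 * d[1], 2 * d[2], 2 * d[3], d[4]))
  }
  list(out = out, cache = d)
}

.up_bwd <- function(dout, cache) {
  d <- cache
  dx <- array(0, d)
  for (n in seq_len(d[5])) {
    dx[, , , , n] <- array(
      pn_upsample_bwd(as.vector(dout[, , , , n]), d[1], d[2], d[3], d[4]),
      d[1:4])
  }
  list(dx = dx, grads = NULL)
}

# forward through one layer; returns out, cache, and (training BN) updated
# running statistics
.layer_fwd <- function(layer, x, training) {
  switch(layer$type,
    conv = .conv_fwd(layer, x),
    bn = .bn_fwd(layer, x, training),
    relu = list(out = pmax(x, 0), cache = x > 0),
    tanh = list(out = tanh(x), cache = NULL),
    maxpool = .pool_fwd(x),
    upsample = .up_fwd(x),
    se = .se_fwd(layer, x),
    resblock = .resblock_fwd(layer, x, training),
    stop("unknown layer type ", layer$type)
  )
}

.layer_bwd <- function(layer, dout, cache, out = NULL) {
  switch(layer$type,
    conv = .conv_bwd(layer, dout, cache),
    bn = .bn_bwd(layer, dout, cache),
    relu = list(dx = dout * cache, grads = NULL),
    tanh = list(dx = dout * (1 - out^2), grads = NULL),
    maxpool = .pool_bwd(dout, cache),
    upsample = .up_bwd(dout, cache),
    se = .se_bwd(layer, dout, cache),
    resblock = .resblock_bwd(layer, dout, cache),
    stop("unknown layer type ", layer$type)
  )
}

.resblock_fwd <- function(layer, x, training) {
  f1 <- .conv_fwd(layer$conv1, x)
  f2 <- .bn_fwd(layer$bn1, f1$out, training)
  r1 <- pmax(f2$out, 0)
  f3 <- .conv_fwd(layer$conv2, r1)
  f4 <- .bn_fwd(layer$bn2, f3$out, training)
  if (!is.null(layer$se)) {
    f5 <- .se_fwd(layer$se, f4$out)
    pre <- f5$out + x
    se_cache <- f5$cache
  } else {
    pre <- f4$out + x
    se_cache <- NULL
  }
  out <- pmax(pre, 0)
  list(out = out,
       cache = list(c1 = f1$cache, b1 = f2$cache, m1 = f2$out > 0,
                    r1 = r1, c2 = f3$cache, b2 = f4$cache, se = se_cache,
                    mout = pre > 0),
       batch_stats = list(bn1 = f2$batch_stats, bn2 = f4$batch_stats))
}

.resblock_bwd <- function(layer, dout, cache) {
  dpre <- dout * cache$mout
  if (!is.null(layer$se)) {
    bse <- .se_bwd(layer$se, dpre, cache$se)
    d4 <- bse$dx
  } else {
    d4 <- dpre
  }
  b4 <- .bn_bwd(layer$bn2, d4, cache$b2)
  b3 <- .conv_bwd(layer$conv2, b4$dx, cache$c2)
  dr1 <- b3$dx * cache$m1
  b2 <- .bn_bwd(layer$bn1, dr1, cache$b1)
  b1 <- .conv_bwd(layer$conv1, b2$dx, cache$c1)
  dx <- b1$dx + dpre  # skip connection
  grads <- list(conv1 = b1$grads, bn1 = b2$grads, conv2 = b3$grads,
                bn2 = b4$grads,
                se = if (!is.null(layer$se)) bse$grads else NULL)
  list(dx = dx, grads = grads)
}

# update BN running statistics from a training forward pass
.bn_update_running <- function(layer, stats) {
  m <- layer$momentum
  layer$rmean <- (1 - m) * layer$rmean + m * stats$mean
  layer$rvar <- (1 - m) * layer$rvar + m * stats$var
  layer
}
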