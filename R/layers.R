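# Minimal hand-differentiated 3D network layers.  Activations are 5D arrays
# (nx, ny, nz, channels, batch); every *_fwd returns the output plus the
# cache its *_bwd needs.  Convolutions run through the compiled
# im2col + GEMM kernels.

conv_params <- function(k, in_c, out_c, init = c("xavier", "zeros")) {
  init <- match.arg(init)
  n <- k^3 * in_c * out_c
  w <- if (init == "zeros") rep(0, n) else {
    a <- sqrt(6 / (k^3 * in_c + k^3 * out_c))
    runif(n, -a, a)
  }
  list(w = array(w, dim = c(k, k, k, in_c, out_c)), b = rep(0, out_c))
}

conv_fwd <- function(x, p) {
  list(y = cpp_conv3d_fwd(x, p$w, p$b), cache = x)
}

conv_bwd <- function(gy, cache, p, need_gx = TRUE) {
  r <- cpp_conv3d_bwd(cache, p$w, gy, need_gx)
  list(gx = r$gx, gp = list(w = r$gw, b = as.numeric(r$gb)))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bwd <- function(gy, mask) gy * mask

bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

bn_state <- function(c) list(mean = rep(0, c), var = rep(1, c))

bn_eps <- 1e-5
bn_momentum <- 0.9

# channel-wise broadcast helper for (nvox, C, K)-flattened activations
bn_expand <- function(v, nvox, C, K) rep(rep(v, each = nvox), times = K)

bn_fwd <- function(x, p, st, training) {
  d <- dim(x)
  nvox <- prod(d[1:3]); C <- d[4]; K <- d[5]
  xm <- x; dim(xm) <- c(nvox * C, K)
  if (training) {
    pc <- matrix(.colMeans(x, nvox, C * K), C, K)
    mu <- rowMeans(pc)
    pc2 <- matrix(.colMeans(x * x, nvox, C * K), C, K)
    v <- rowMeans(pc2) - mu^2
    st$mean <- bn_momentum * st$mean + (1 - bn_momentum) * mu
    st$var <- bn_momentum * st$var + (1 - bn_momentum) * v
  } else {
    mu <- st$mean; v <- st$var
  }
  invstd <- 1 / sqrt(v + bn_eps)
  xc <- x - bn_expand(mu, nvox, C, K)
  xhat <- xc * bn_expand(invstd, nvox, C, K)
  y <- xhat * bn_expand(p$gamma, nvox, C, K) + bn_expand(p$beta, nvox, C, K)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                           training = training),
       state = st)
}

bn_bwd <- function(gy, cache, p) {
  d <- cache$d
  nvox <- prod(d[1:3]); C <- d[4]; K <- d[5]
  N <- nvox * K
  xhat <- cache$xhat
  gsum <- function(a) rowSums(matrix(.colMeans(a, nvox, C * K) * nvox, C, K))
  dgamma <- gsum(gy * xhat)
  dbeta <- gsum(gy)
  dxhat <- gy * bn_expand(p$gamma, nvox, C, K)
  if (cache$training) {
    t1 <- gsum(dxhat)
    t2 <- gsum(dxhat * xhat)
    gx <- (dxhat - bn_expand(t1 / N, nvox, C, K) -
             xhat * bn_expand(t2 / N, nvox, C, K)) *
      bn_expand(cache$invstd, nvox, C, K)
  } else {
    gx <- dxhat * bn_expand(cache$invstd, nvox, C, K)
  }
  dim(gx) <- d
  list(gx = gx, gp = list(gamma = dgamma, beta = dbeta))
}

pool_corners <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

maxpool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], 2); j1 <- seq(1, d[2], 2); k1 <- seq(1, d[3], 2)
  subs <- lapply(seq_len(8), function(ci) {
    co <- pool_corners[ci, ]
    x[i1 + co[1], j1 + co[2], k1 + co[3], , , drop = FALSE]
  })
  y <- subs[[1]]
  for (ci in 2:8) y <- pmax(y, subs[[ci]])
  remaining <- array(TRUE, dim = dim(y))
  takes <- vector("list", 8)
  for (ci in seq_len(8)) {
    take <- (subs[[ci]] == y) & remaining
    remaining <- remaining & !take
    takes[[ci]] <- take
  }
  list(y = y, cache = list(takes = takes, d = d))
}

maxpool_bwd <- function(gy, cache) {
  d <- cache$d
  gx <- array(0, dim = d)
  i1 <- seq(1, d[1], 2); j1 <- seq(1, d[2], 2); k1 <- seq(1, d[3], 2)
  for (ci in seq_len(8)) {
    co <- pool_corners[ci, ]
    gx[i1 + co[1], j1 + co[2], k1 + co[3], , ] <- gy * cache$takes[[ci]]
  }
  gx
}

# zero-stuffing: x values at odd output indices, zeros in between; with the
# subsequent same-padded convolution this realises a stride-2 transpose
# convolution with learnable taps
zero_stuff <- function(x) {
  d <- dim(x)
  y <- array(0, dim = c(2 * d[1], 2 * d[2], 2 * d[3], d[4], d[5]))
  y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), seq(1, 2 * d[3], 2), , ] <- x
  y
}

unstuff <- function(g) {
  d <- dim(g)
  g[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), , , drop = FALSE]
}

deconv_fwd <- function(x, p) {
  xs <- zero_stuff(x)
  list(y = cpp_conv3d_fwd(xs, p$w, p$b), cache = xs)
}

deconv_bwd <- function(gy, cache, p) {
  r <- cpp_conv3d_bwd(cache, p$w, gy)
  list(gx = unstuff(r$gx), gp = list(w = r$gw, b = as.numeric(r$gb)))
}

# factor-2 trilinear upsampling matrix: output centre o maps to input
# coordinate o/2 - 1/4, edge-clamped (align-corners = FALSE convention)
upsample_matrix <- function(n) {
  key <- paste0("u", n)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- matrix(0, 2 * n, n)
  for (o in 0:(2 * n - 1)) {
    c0 <- o / 2 - 0.25
    i0 <- floor(c0); w <- c0 - i0
    ia <- min(max(i0, 0), n - 1); ib <- min(max(i0 + 1, 0), n - 1)
    U[o + 1, ia + 1] <- U[o + 1, ia + 1] + (1 - w)
    U[o + 1, ib + 1] <- U[o + 1, ib + 1] + w
  }
  .op_cache[[paste0("u", n)]] <- U
  U
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  for (ax in 1:3) x <- apply_axis(x, upsample_matrix(d[ax]), ax)
  x
}

upsample2_bwd <- function(gy, d_in) {
  for (ax in 1:3) gy <- apply_axis(gy, t(upsample_matrix(d_in[ax])), ax)
  gy
}

# trilinear additive upsampling: upsample then sum the two channel halves
additive_up_fwd <- function(x) {
  up <- upsample2_fwd(x)
  C <- dim(up)[4]
  h <- C / 2
  list(y = up[, , , 1:h, , drop = FALSE] +
         up[, , , (h + 1):C, , drop = FALSE],
       cache = dim(x))
}

additive_up_bwd <- function(gy, d_in) {
  g2 <- array(0, dim = c(2 * d_in[1:3], d_in[4], d_in[5]))
  h <- d_in[4] / 2
  g2[, , , 1:h, ] <- gy
  g2[, , , (h + 1):d_in[4], ] <- gy
  upsample2_bwd(g2, d_in)
}
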