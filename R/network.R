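# Registration networks: the baseline encoder-decoder predicting per-level
# displacement summands, its ablation variants, the affine Global-Net and
# the Composite-Net.  Forward passes cache what the mirrored hand-written
# backward passes need; parameters live in nested named lists so the
# optimiser can treat them as trees.

#' Network configuration
#'
#' @param n0 initial channel count (doubles at every down-sampling level).
#' @param levels number of down/up-sampling stages; the input grid must be
#'   divisible by 2^levels per axis.
#' @param variant one of \code{"baseline"}, \code{"delta0_only"},
#'   \code{"delta1_4"}, \code{"no_additive_upsampling"}, \code{"global"},
#'   \code{"composite"}.
#' @param first_kernel kernel size of the very first convolution (7 gives a
#'   large initial receptive field).
#' @param kernel kernel size of all other convolutions.
#' @param head_init \code{"zeros"} (the default: the untrained network
#'   outputs an exactly zero DDF, so the first gradients come from the
#'   label overlap at the identity alignment) or \code{"small_random"}.
#' @return A list of class \code{weakreg_netconfig}.
#' @export
network_config <- function(n0 = 32, levels = 4,
                           variant = c("baseline", "delta0_only", "delta1_4",
                                       "no_additive_upsampling", "global",
                                       "composite"),
                           first_kernel = 7, kernel = 3,
                           head_init = c("zeros", "small_random")) {
  variant <- match.arg(variant)
  head_init <- match.arg(head_init)
  if (levels < 1) stop("levels must be >= 1")
  structure(list(n0 = n0, levels = levels, variant = variant,
                 first_kernel = first_kernel, kernel = kernel,
                 head_init = head_init),
            class = "weakreg_netconfig")
}

active_head_levels <- function(cfg) {
  switch(cfg$variant,
         delta0_only = 0L,
         delta1_4 = seq_len(cfg$levels),
         seq(0L, cfg$levels))
}

# --- parameter trees -------------------------------------------------------

rb_params <- function(k1, in_c, out_c, k2) {
  list(c1 = conv_params(k1, in_c, out_c),
       bn1 = bn_params(out_c),
       c2 = conv_params(k2, out_c, out_c),
       bn2 = bn_params(out_c))
}

rb_state <- function(out_c) list(bn1 = bn_state(out_c), bn2 = bn_state(out_c))

head_params <- function(k, in_c, init) {
  p <- conv_params(k, in_c, 3L, init = "zeros")
  if (init == "small_random") {
    p$w <- array(rnorm(length(p$w), sd = 1e-3), dim = dim(p$w))
  }
  p
}

enc_channels <- function(cfg) {
  # output channels of encoder blocks 1..levels (levels s0..s_{levels-1})
  cfg$n0 * 2^(seq_len(cfg$levels) - 1)
}

local_params <- function(cfg) {
  L <- cfg$levels
  ec <- enc_channels(cfg)
  down <- lapply(seq_len(L), function(i) {
    rb_params(if (i == 1) cfg$first_kernel else cfg$kernel,
              if (i == 1) 2L else ec[i - 1], ec[i], cfg$kernel)
  })
  bottom <- rb_params(cfg$kernel, ec[L], 2 * ec[L], cfg$kernel)
  up <- lapply(rev(seq_len(L)), function(lv) {  # target levels L-1 .. 0
    cin <- cfg$n0 * 2^lv
    cout <- cin / 2
    list(dc = conv_params(cfg$kernel, cin, cout),
         rb = rb_params(cfg$kernel, cout, cout, cfg$kernel))
  })
  heads <- list()
  for (lv in active_head_levels(cfg)) {
    cin <- if (lv == L) 2 * ec[L] else cfg$n0 * 2^lv
    heads[[as.character(lv)]] <- head_params(cfg$kernel, cin, cfg$head_init)
  }
  list(down = down, bottom = bottom, up = up, heads = heads)
}

local_state <- function(cfg) {
  L <- cfg$levels
  ec <- enc_channels(cfg)
  list(down = lapply(seq_len(L), function(i) rb_state(ec[i])),
       bottom = rb_state(2 * ec[L]),
       up = lapply(rev(seq_len(L)), function(lv) {
         list(rb = rb_state(cfg$n0 * 2^(lv - 1)))
       }))
}

global_params <- function(cfg) {
  L <- cfg$levels
  ec <- enc_channels(cfg)
  down <- lapply(seq_len(L), function(i) {
    rb_params(if (i == 1) cfg$first_kernel else cfg$kernel,
              if (i == 1) 2L else ec[i - 1], ec[i], cfg$kernel)
  })
  # affine head: 12 outputs added to the identity transform; zero-initialised
  # so the initial prediction is exactly the identity
  list(down = down,
       head = list(W = matrix(0, ec[L], 12), b = rep(0, 12)))
}

global_state <- function(cfg) {
  ec <- enc_channels(cfg)
  list(down = lapply(seq_len(cfg$levels), function(i) rb_state(ec[i])))
}

#' Build a registration network
#'
#' Constructs the parameter and batch-norm-state trees for the configured
#' variant.  Non-head parameters use Xavier initialisation from R's current
#' RNG stream; displacement heads are zero-initialised by default so every
#' variant predicts the zero DDF before training.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return An object of class \code{weakreg_network}.
#' @export
build_network <- function(cfg = network_config()) {
  if (cfg$variant == "global") return(build_global_net(cfg))
  if (cfg$variant == "composite") {
    gcfg <- cfg; gcfg$variant <- "global"
    lcfg <- cfg; lcfg$variant <- "baseline"
    return(build_composite(build_global_net(gcfg), build_network(lcfg)))
  }
  structure(list(cfg = cfg, type = "local",
                 params = local_params(cfg), state = local_state(cfg)),
            class = "weakreg_network")
}

#' @rdname build_network
#' @export
build_global_net <- function(cfg = network_config(variant = "global")) {
  if (cfg$variant != "global") stop("cfg$variant must be 'global'")
  structure(list(cfg = cfg, type = "global",
                 params = global_params(cfg), state = global_state(cfg)),
            class = "weakreg_network")
}

#' @rdname build_network
#' @param global,local trained or untrained \code{weakreg_network}s of type
#'   global and local; the composite warps the moving image by the global
#'   (affine) DDF, feeds the result to the local network, and composes the
#'   two fields.
#' @export
build_composite <- function(global, local) {
  if (global$type != "global" || local$type != "local") {
    stop("build_composite needs a global and a local network")
  }
  cfg <- local$cfg; cfg$variant <- "composite"
  structure(list(cfg = cfg, type = "composite",
                 params = list(global = global$params, local = local$params),
                 state = list(global = global$state, local = local$state),
                 sub_cfg = list(global = global$cfg, local = local$cfg)),
            class = "weakreg_network")
}

#' @export
print.weakreg_network <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<weakreg_network %s: n0=%d, levels=%d, %d parameters>\n",
              x$cfg$variant, x$cfg$n0, x$cfg$levels, np))
  invisible(x)
}

#' Number of learnable parameters
#' @param net a \code{weakreg_network}.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(net) sum(rapply(net$params, length, how = "unlist"))

# --- parameter-tree utilities ---------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

tree_zero <- function(p) tree_map(function(x) x * 0, p)

# --- residual block --------------------------------------------------------

rb_fwd <- function(x, p, st, training) {
  c1 <- conv_fwd(x, p$c1)
  b1 <- bn_fwd(c1$y, p$bn1, st$bn1, training)
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(r1$y, p$c2)
  b2 <- bn_fwd(c2$y, p$bn2, st$bn2, training)
  r2 <- relu_fwd(r1$y + b2$y)
  list(y = r2$y,
       cache = list(x = x, b1 = b1$cache, m1 = r1$cache, h1 = r1$y,
                    b2 = b2$cache, m2 = r2$cache),
       state = list(bn1 = b1$state, bn2 = b2$state))
}

rb_bwd <- function(gy, cache, p, need_gx = TRUE) {
  g <- relu_bwd(gy, cache$m2)
  bb2 <- bn_bwd(g, cache$b2, p$bn2)
  cc2 <- conv_bwd(bb2$gx, cache$h1, p$c2)
  gh1 <- g + cc2$gx
  gb1 <- relu_bwd(gh1, cache$m1)
  bb1 <- bn_bwd(gb1, cache$b1, p$bn1)
  cc1 <- conv_bwd(bb1$gx, cache$x, p$c1, need_gx)
  list(gx = cc1$gx,
       gp = list(c1 = cc1$gp, bn1 = bb1$gp, c2 = cc2$gp, bn2 = bb2$gp))
}

# --- local (baseline-family) network --------------------------------------

forward_local <- function(params, state, x, cfg, training) {
  L <- cfg$levels
  skips <- vector("list", L)
  enc_caches <- vector("list", L)
  pool_caches <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    rb <- rb_fwd(h, params$down[[i]], state$down[[i]], training)
    state$down[[i]] <- rb$state
    skips[[i]] <- rb$y
    enc_caches[[i]] <- rb$cache
    mp <- maxpool_fwd(rb$y)
    pool_caches[[i]] <- mp$cache
    h <- mp$y
  }
  bt <- rb_fwd(h, params$bottom, state$bottom, training)
  state$bottom <- bt$state
  feats <- list()                 # decoder features by level (as character)
  feats[[as.character(L)]] <- bt$y
  dec_caches <- vector("list", L)
  y <- bt$y
  use_add <- cfg$variant != "no_additive_upsampling"
  for (j in seq_len(L)) {          # j-th up block targets level L - j
    lv <- L - j
    p <- params$up[[j]]
    dc <- deconv_fwd(y, p$dc)
    s <- dc$y
    add_cache <- NULL
    if (use_add) {
      au <- additive_up_fwd(y)
      s <- s + au$y
      add_cache <- au$cache
    }
    s <- s + skips[[lv + 1]]
    rb <- rb_fwd(s, p$rb, state$up[[j]]$rb, training)
    state$up[[j]]$rb <- rb$state
    dec_caches[[j]] <- list(dc = dc$cache, add = add_cache, rb = rb$cache)
    y <- rb$y
    feats[[as.character(lv)]] <- y
  }
  pyramid <- list()
  head_caches <- list()
  dshape <- dim(x)
  K <- dshape[5]
  ddf <- array(0, dim = c(dshape[1:3], 3L, K))
  for (lv in active_head_levels(cfg)) {
    key <- as.character(lv)
    hc <- conv_fwd(feats[[key]], params$heads[[key]])
    delta <- hc$y
    updims <- list()
    if (lv > 0) for (r in seq_len(lv)) {
      updims[[r]] <- dim(delta)
      delta <- upsample2_fwd(delta)
    }
    head_caches[[key]] <- list(conv = hc$cache, updims = updims)
    pyramid[[key]] <- delta
    ddf <- ddf + delta
  }
  list(ddf = ddf, pyramid = pyramid, state = state,
       cache = list(enc = enc_caches, pool = pool_caches, bottom = bt$cache,
                    dec = dec_caches, heads = head_caches, dshape = dshape))
}

backward_local <- function(g_ddf, cache, params, cfg,
                           need_input_grad = FALSE) {
  L <- cfg$levels
  gp <- tree_zero(params)
  g_feat <- list()                 # gradients flowing into decoder features
  for (lv in active_head_levels(cfg)) {
    key <- as.character(lv)
    hc <- cache$heads[[key]]
    g <- g_ddf
    if (lv > 0) for (r in rev(seq_len(lv))) g <- upsample2_bwd(g, hc$updims[[r]])
    cb <- conv_bwd(g, hc$conv, params$heads[[key]])
    gp$heads[[key]] <- cb$gp
    g_feat[[key]] <- cb$gx
  }
  use_add <- cfg$variant != "no_additive_upsampling"
  g_skips <- vector("list", L)
  gy <- NULL                       # gradient at decoder output, level 0 first
  for (j in rev(seq_len(L))) {     # walk decoder backwards: level 0 -> L-1
    lv <- L - j
    key <- as.character(lv)
    g_here <- if (is.null(gy)) 0 else gy
    if (!is.null(g_feat[[key]])) g_here <- g_here + g_feat[[key]]
    dcc <- cache$dec[[j]]
    rb <- rb_bwd(g_here, dcc$rb, params$up[[j]]$rb)
    gp$up[[j]]$rb <- rb$gp
    gs <- rb$gx
    g_skips[[lv + 1]] <- gs
    dc <- deconv_bwd(gs, dcc$dc, params$up[[j]]$dc)
    gp$up[[j]]$dc <- dc$gp
    gy <- dc$gx
    if (use_add) gy <- gy + additive_up_bwd(gs, dcc$add)
  }
  g_bottom <- gy
  keyL <- as.character(L)
  if (!is.null(g_feat[[keyL]])) g_bottom <- g_bottom + g_feat[[keyL]]
  bt <- rb_bwd(g_bottom, cache$bottom, params$bottom)
  gp$bottom <- bt$gp
  g <- bt$gx
  for (i in rev(seq_len(L))) {
    g <- maxpool_bwd(g, cache$pool[[i]])
    g <- g + g_skips[[i]]
    rb <- rb_bwd(g, cache$enc[[i]], params$down[[i]],
                 need_gx = need_input_grad || i > 1)
    gp$down[[i]] <- rb$gp
    g <- rb$gx
  }
  list(gp = gp, gx = g)
}

# --- global (affine) network ----------------------------------------------

affine_centre <- function(shape, spacing, origin) {
  origin + spacing * (shape - 1) / 2
}

forward_global <- function(params, state, x, cfg, training, spacing, origin) {
  L <- cfg$levels
  enc_caches <- vector("list", L)
  pool_caches <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    rb <- rb_fwd(h, params$down[[i]], state$down[[i]], training)
    state$down[[i]] <- rb$state
    enc_caches[[i]] <- rb$cache
    mp <- maxpool_fwd(rb$y)
    pool_caches[[i]] <- mp$cache
    h <- mp$y
  }
  d <- dim(h)
  nvox <- prod(d[1:3]); C <- d[4]; K <- d[5]
  hm <- h; dim(hm) <- c(nvox, C * K)
  xbar <- matrix(colMeans(hm), C, K)
  raw <- t(params$head$W) %*% xbar + params$head$b   # (12, K)
  shape <- dim(x)[1:3]
  ctr <- affine_centre(shape, spacing, origin)
  idx <- grid_index(shape)
  q <- sweep(sweep(idx, 2, spacing, "*"), 2, origin - ctr, "+")  # p_w - c
  ddf <- array(0, dim = c(shape, 3L, K))
  for (k in seq_len(K)) {
    M <- matrix(raw[1:9, k], 3, 3)           # A - I
    u <- q %*% t(M)
    u <- sweep(u, 2, raw[10:12, k], "+")
    ddf[, , , , k] <- array(u, dim = c(shape, 3L))
  }
  list(ddf = ddf, pyramid = list(), state = state,
       cache = list(enc = enc_caches, pool = pool_caches, q = q, xbar = xbar,
                    hdim = d, dshape = dim(x)))
}

backward_global <- function(g_ddf, cache, params, cfg) {
  L <- cfg$levels
  gp <- tree_zero(params)
  K <- dim(g_ddf)[5]
  nvox <- nrow(cache$q)
  graw <- matrix(0, 12, K)
  for (k in seq_len(K)) {
    gu <- matrix(g_ddf[, , , , k], ncol = 3)
    graw[1:9, k] <- as.numeric(crossprod(gu, cache$q))  # dM[i,j] = sum gu_i q_j
    graw[10:12, k] <- colSums(gu)
  }
  gp$head$W <- cache$xbar %*% t(graw)
  gp$head$b <- rowSums(graw)
  gxbar <- params$head$W %*% graw              # (C, K)
  d <- cache$hdim
  gh <- array(rep(as.numeric(gxbar), each = prod(d[1:3])) / prod(d[1:3]),
              dim = d)
  g <- gh
  for (i in rev(seq_len(L))) {
    g <- maxpool_bwd(g, cache$pool[[i]])
    rb <- rb_bwd(g, cache$enc[[i]], params$down[[i]], need_gx = i > 1)
    gp$down[[i]] <- rb$gp
    g <- rb$gx
  }
  list(gp = gp, gx = g)
}

# --- composite network -----------------------------------------------------

forward_composite <- function(net, x, training, spacing, origin) {
  shape <- dim(x)[1:3]; K <- dim(x)[5]
  gf <- forward_global(net$params$global, net$state$global, x,
                       net$sub_cfg$global, training, spacing, origin)
  net$state$global <- gf$state
  warp_vjps <- vector("list", K)
  xl <- x
  for (k in seq_len(K)) {
    ug <- ddf(array(gf$ddf[, , , , k], dim = c(shape, 3L)), spacing, origin)
    mov <- array(x[, , , 1, k], dim = shape)
    wv <- warp_field_vjp(mov, ug)
    warp_vjps[[k]] <- wv
    xl[, , , 1, k] <- wv$out
  }
  lf <- forward_local(net$params$local, net$state$local, xl,
                      net$sub_cfg$local, training)
  net$state$local <- lf$state
  # compose per sample: w = u_l + resample(u_g at p + u_l / h)
  ddf_out <- array(0, dim = dim(lf$ddf))
  comp_caches <- vector("list", K)
  for (k in seq_len(K)) {
    ug_arr <- array(gf$ddf[, , , , k], dim = c(shape, 3L))
    ul <- ddf(array(lf$ddf[, , , , k], dim = c(shape, 3L)), spacing, origin)
    pos <- ddf_sample_positions(ul)
    sampled <- cpp_resample3_fwd(ug_arr, pos)
    ddf_out[, , , , k] <- ul$disp + array(sampled, dim = c(shape, 3L))
    comp_caches[[k]] <- list(ug = ug_arr, pos = pos)
  }
  list(ddf = ddf_out, pyramid = lf$pyramid, state = net$state,
       cache = list(gf = gf$cache, lf = lf$cache, comp = comp_caches,
                    warp = warp_vjps, shape = shape, spacing = spacing))
}

backward_composite <- function(net, g_ddf, cache) {
  shape <- cache$shape; K <- dim(g_ddf)[5]
  h <- cache$spacing
  g_ul <- array(0, dim = dim(g_ddf))
  g_ug <- array(0, dim = dim(g_ddf))
  for (k in seq_len(K)) {
    gw <- matrix(g_ddf[, , , , k], ncol = 3)
    cc <- cache$comp[[k]]
    bw <- cpp_resample3_bwd(cc$ug, cc$pos, gw)
    g_ug[, , , , k] <- array(bw$gfield, dim = c(shape, 3L))
    gpos <- sweep(bw$gpos, 2, h, "/")
    g_ul[, , , , k] <- array(g_ddf[, , , , k], dim = c(shape, 3L)) +
      array(gpos, dim = c(shape, 3L))
  }
  lb <- backward_local(g_ul, cache$lf, net$params$local, net$sub_cfg$local,
                       need_input_grad = TRUE)
  for (k in seq_len(K)) {
    g_warped <- array(lb$gx[, , , 1, k], dim = shape)
    pb <- cache$warp[[k]]$pullback(g_warped)
    g_ug[, , , , k] <- g_ug[, , , , k] + pb$g_u
  }
  gb <- backward_global(g_ug, cache$gf, net$params$global,
                        net$sub_cfg$global)
  list(gp = list(global = gb$gp, local = lb$gp), gx = NULL)
}

# --- unified entry points --------------------------------------------------

check_grid_divisible <- function(shape, levels) {
  if (any(shape %% 2^levels != 0)) {
    stop("grid [", paste(shape, collapse = "x"),
         "] must be divisible by 2^levels = ", 2^levels, " per axis")
  }
}

net_forward <- function(net, x, training, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  check_grid_divisible(dim(x)[1:3], net$cfg$levels)
  switch(net$type,
         local = forward_local(net$params, net$state, x, net$cfg, training),
         global = forward_global(net$params, net$state, x, net$cfg, training,
                                 spacing, origin),
         composite = forward_composite(net, x, training, spacing, origin))
}

net_backward <- function(net, g_ddf, cache) {
  switch(net$type,
         local = backward_local(g_ddf, cache, net$params, net$cfg),
         global = backward_global(g_ddf, cache, net$params, net$cfg),
         composite = backward_composite(net, g_ddf, cache))
}

#' Predict the DDF for an image pair
#'
#' Runs the network in inference mode (batch-norm running statistics) on the
#' moving/fixed pair, which must already be preprocessed to a common grid
#' divisible by 2^levels.  Labels are never an input on this path.
#'
#' @param net a \code{weakreg_network}.
#' @param moving,fixed preprocessed \code{weakreg_volume}s.
#' @return List with \code{ddf} (a \code{weakreg_ddf}) and \code{pyramid}
#'   (per-level displacement summands, each already upsampled to the output
#'   grid; their sum is \code{ddf}).
#' @export
predict_ddf <- function(net, moving, fixed) {
  if (!identical(dim(moving$data), dim(fixed$data))) {
    stop("moving and fixed must share grid shape")
  }
  shape <- dim(fixed$data)
  x <- array(0, dim = c(shape, 2L, 1L))
  x[, , , 1, 1] <- moving$data
  x[, , , 2, 1] <- fixed$data
  out <- net_forward(net, x, training = FALSE, spacing = fixed$spacing,
                     origin = fixed$origin)
  u <- ddf(array(out$ddf[, , , , 1], dim = c(shape, 3L)),
           spacing = fixed$spacing, origin = fixed$origin)
  pyr <- lapply(out$pyramid, function(p) {
    ddf(array(p[, , , , 1], dim = c(shape, 3L)),
        spacing = fixed$spacing, origin = fixed$origin)
  })
  list(ddf = u, pyramid = pyr)
}

#' Analytic receptive field of the coarsest displacement head
#'
#' Computed from the layer list (kernel sizes and cumulative strides), in
#' input voxels.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return Receptive-field side length in voxels.
#' @export
receptive_field <- function(cfg) {
  rf <- 1; jump <- 1
  for (i in seq_len(cfg$levels)) {
    k1 <- if (i == 1) cfg$first_kernel else cfg$kernel
    rf <- rf + (k1 - 1) * jump + (cfg$kernel - 1) * jump
    jump <- jump * 2                      # max-pool stride 2
  }
  rf <- rf + 2 * (cfg$kernel - 1) * jump  # bottom block
  rf + (cfg$kernel - 1) * jump            # coarsest head convolution
}
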