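# Weakly-supervised training: two-stage unbiased minibatch sampling over
# cases and label pairs, per-side random-affine augmentation, Adam updates
# of the network parameter tree.

#' Training configuration
#'
#' The defaults reproduce the full-scale baseline protocol (minibatch K = 4,
#' Adam at learning rate 1e-5, regularisation weight 0.5, no weight decay,
#' zero-initialised displacement heads).  Desk-scale experiments on small
#' grids override \code{lr}, \code{net} and \code{loss$ms} — see
#' \code{\link{desk_train_config}}.
#'
#' @param K minibatch size (image-label pairs per step).
#' @param lr Adam learning rate.
#' @param max_iters number of optimisation steps.
#' @param loss a \code{\link{loss_config}} (carries alpha and the scale
#'   ladder).
#' @param net a \code{\link{network_config}}.
#' @param augment list of random-affine ranges (see
#'   \code{\link{random_affine}}), or NULL to disable augmentation.
#' @param seed integer seed controlling initialisation, sampling and
#'   augmentation.
#' @param log_every record the loss every this many steps (every step = 1).
#' @param checkpoint_every,checkpoint_dir optional checkpoint cadence and
#'   output directory (RDS files).
#' @return A list of class \code{weakreg_trainconfig}.
#' @export
train_config <- function(K = 4, lr = 1e-5, max_iters = 1000,
                         loss = loss_config(), net = network_config(),
                         augment = list(rot_deg = 5, scale = c(0.97, 1.03),
                                        shear = 0.02, trans_mm = 1),
                         seed = 1, log_every = 1,
                         checkpoint_every = Inf, checkpoint_dir = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (lr <= 0) stop("lr must be positive")
  structure(list(K = K, lr = lr, max_iters = max_iters, loss = loss,
                 net = net, augment = augment, seed = seed,
                 log_every = log_every, checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "weakreg_trainconfig")
}

#' Desk-scale training configuration
#'
#' The package's standard configuration for phantom experiments on 16^3
#' grids: n0 = 4 channels, the sigma ladder truncated to the grid
#' (0, 1, 2, 4, 8 mm), Adam at its conventional 1e-3 rate (1e-4 for the
#' affine Global-Net, mirroring the tenfold reduction the affine head
#' needs for stability).
#'
#' @param variant network variant.
#' @param max_iters training steps.
#' @param alpha regularisation weight.
#' @param similarity,regularizer,prefiltered loss selections.
#' @param seed integer seed.
#' @return A \code{\link{train_config}}.
#' @export
desk_train_config <- function(variant = "baseline", max_iters = 1200,
                              alpha = 0.5, similarity = "multiscale_dice",
                              regularizer = "bending_energy",
                              prefiltered = FALSE, seed = 1) {
  lr <- if (variant %in% c("global", "composite")) 1e-4 else 1e-3
  train_config(
    K = 4, lr = lr, max_iters = max_iters,
    loss = loss_config(similarity = similarity, regularizer = regularizer,
                       alpha = alpha, prefiltered = prefiltered,
                       ms = multiscale_config(sigmas = c(0, 1, 2, 4, 8))),
    net = network_config(n0 = 4, levels = 4, variant = variant),
    seed = seed)
}

#' Two-stage unbiased minibatch sampling
#'
#' Stage 1 draws K cases uniformly with replacement; stage 2 draws exactly
#' one label pair uniformly within each drawn case.  Every minibatch then
#' holds exactly K image-label pairs, each (case n, label m) pair appearing
#' with probability 1/(N * M_n) — the weighting of the label-averaged
#' training utility, which makes the minibatch gradient unbiased.
#'
#' @param dataset list of \code{weakreg_case}s, each with >= 1 label pair.
#' @param K minibatch size.
#' @return List of K elements \code{list(case = n, label = m)}.
#' @export
sample_minibatch <- function(dataset, K) {
  if (length(dataset) == 0) stop("empty dataset")
  M <- vapply(dataset, function(cs) length(cs$label_pairs), integer(1))
  if (any(M < 1)) {
    stop("case(s) without label pairs: ",
         paste(vapply(dataset[M < 1], function(cs) cs$case_id, ""),
               collapse = ", "))
  }
  ns <- sample.int(length(dataset), K, replace = TRUE)
  lapply(ns, function(n) list(case = n, label = sample.int(M[n], 1)))
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  opt$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# apply one augmentation affine to an image and a label on the same grid
augment_side <- function(img, lab, ranges) {
  ctr <- affine_centre(dim(img$data), img$spacing, img$origin)
  aff <- random_affine(ranges, centre = ctr)
  ua <- affine_to_ddf(aff, dim(img$data), img$spacing, img$origin)
  list(img = warp_volume(img, ua), lab = warp_volume(lab, ua))
}

# loss value and DDF gradient for one (fixed label, moving label, u) triple
member_loss <- function(fixed_lab, moving_lab, u, cfg_loss) {
  spacing <- u$spacing
  if (cfg_loss$prefiltered && cfg_loss$similarity == "multiscale_dice") {
    # filter both labels per scale up front, warp each pre-filtered moving
    # label, evaluate the plain soft Dice per scale
    ms <- cfg_loss$ms
    sim <- 0
    g_u <- array(0, dim = dim(u$disp))
    for (s in ms$sigmas) {
      fa <- gaussian_filter(fixed_lab, s, spacing, ms$truncation)
      fm <- gaussian_filter(moving_lab, s, spacing, ms$truncation)
      wv <- warp_field_vjp(fm, u)
      sim <- sim + soft_dice(fa, wv$out)
      gy <- -soft_dice_grad_b(fa, wv$out) / ms$Z
      g_u <- g_u + wv$pullback(gy)$g_u
    }
    sim <- sim / ms$Z
    reg <- regularizer_value(u, cfg_loss)
    g_u <- g_u + cfg_loss$alpha * regularizer_grad(u, cfg_loss)
    return(list(loss = -sim + cfg_loss$alpha * reg, sim = sim, reg = reg,
                g_u = g_u))
  }
  wv <- warp_field_vjp(moving_lab, u)
  sim <- similarity_value(fixed_lab, wv$out, cfg_loss, spacing)
  reg <- regularizer_value(u, cfg_loss)
  gy <- -similarity_grad(fixed_lab, wv$out, cfg_loss, spacing)
  g_u <- wv$pullback(gy)$g_u + cfg_loss$alpha * regularizer_grad(u, cfg_loss)
  list(loss = -sim + cfg_loss$alpha * reg, sim = sim, reg = reg, g_u = g_u)
}

#' One training step
#'
#' Applies independent random-affine augmentation to the moving and fixed
#' side of every sampled member, forward-predicts the DDFs for the minibatch
#' (batch-norm in minibatch statistics), warps each sampled moving label,
#' accumulates the regularised loss and its gradient, and performs one Adam
#' update.
#'
#' @param net a \code{weakreg_network}.
#' @param dataset list of cases.
#' @param batch output of \code{\link{sample_minibatch}}.
#' @param cfg a \code{\link{train_config}}.
#' @param opt Adam state from \code{adam_init}; pass the state returned by
#'   the previous step.
#' @return List with \code{net}, \code{opt}, \code{loss}, \code{sim},
#'   \code{reg}.
#' @export
training_step <- function(net, dataset, batch, cfg, opt) {
  K <- length(batch)
  ref <- dataset[[batch[[1]]$case]]$fixed
  shape <- dim(ref$data)
  spacing <- ref$spacing; origin <- ref$origin
  x <- array(0, dim = c(shape, 2L, K))
  fixed_labs <- moving_labs <- vector("list", K)
  for (k in seq_len(K)) {
    cs <- dataset[[batch[[k]]$case]]
    lp <- cs$label_pairs[[batch[[k]]$label]]
    mov <- cs$moving; fix <- cs$fixed
    ml <- lp$moving; fl <- lp$fixed
    if (!is.null(cfg$augment)) {
      am <- augment_side(mov, ml, cfg$augment)
      af <- augment_side(fix, fl, cfg$augment)
      mov <- am$img; ml <- am$lab
      fix <- af$img; fl <- af$lab
    }
    x[, , , 1, k] <- mov$data
    x[, , , 2, k] <- fix$data
    moving_labs[[k]] <- ml$data
    fixed_labs[[k]] <- fl$data
  }
  fw <- net_forward(net, x, training = TRUE, spacing = spacing,
                    origin = origin)
  net$state <- fw$state
  g_ddf <- array(0, dim = dim(fw$ddf))
  loss <- sim <- reg <- 0
  for (k in seq_len(K)) {
    u <- ddf(array(fw$ddf[, , , , k], dim = c(shape, 3L)), spacing, origin)
    ml <- member_loss(fixed_labs[[k]], moving_labs[[k]], u, cfg$loss)
    loss <- loss + ml$loss / K
    sim <- sim + ml$sim / K
    reg <- reg + ml$reg / K
    g_ddf[, , , , k] <- ml$g_u / K
  }
  if (!is.finite(loss)) {
    stop("non-finite loss at Adam step ", opt$t + 1, " (cases: ",
         paste(vapply(batch, function(b) dataset[[b$case]]$case_id, ""),
               collapse = ", "), ")")
  }
  bw <- net_backward(net, g_ddf, fw$cache)
  upd <- adam_step(net$params, bw$gp, opt, cfg$lr)
  net$params <- upd$params
  list(net = net, opt = upd$opt, loss = loss, sim = sim, reg = reg)
}

#' Train a registration network
#'
#' Runs \code{max_iters} steps of two-stage sampled, augmented minibatch
#' training from \code{cfg$seed}; fully reproducible from (seed, config,
#' dataset).
#'
#' @param dataset list of \code{weakreg_case}s (each with >= 1 label pair).
#' @param cfg a \code{\link{train_config}}.
#' @param net optionally a pre-built network (otherwise built from
#'   \code{cfg$net}).
#' @return List with \code{net} (trained network) and \code{log} (data frame
#'   of step, loss, similarity, regularizer).
#' @export
train_network <- function(dataset, cfg = train_config(), net = NULL) {
  set.seed(cfg$seed)
  if (is.null(net)) net <- build_network(cfg$net)
  opt <- adam_init(net$params)
  logs <- vector("list", 0)
  if (cfg$max_iters >= 1) {
    for (it in seq_len(cfg$max_iters)) {
      batch <- sample_minibatch(dataset, cfg$K)
      st <- training_step(net, dataset, batch, cfg, opt)
      net <- st$net; opt <- st$opt
      if (it %% cfg$log_every == 0 || it == cfg$max_iters) {
        logs[[length(logs) + 1]] <- data.frame(step = it, loss = st$loss,
                                               similarity = st$sim,
                                               regularizer = st$reg)
      }
      if (is.finite(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
          it %% cfg$checkpoint_every == 0) {
        dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(net, file.path(cfg$checkpoint_dir,
                               sprintf("ckpt_%06d.rds", it)))
      }
    }
  }
  list(net = net, log = do.call(rbind, logs))
}
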