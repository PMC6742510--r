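test_that("every variant predicts the zero DDF before training", {
  set.seed(1)
  mov <- random_volume(c(16, 16, 16), seed = 1)
  fix <- random_volume(c(16, 16, 16), seed = 2)
  for (v in c("baseline", "delta0_only", "delta1_4",
              "no_additive_upsampling", "global", "composite")) {
    net <- build_network(network_config(n0 = 2, levels = 4, variant = v))
    p <- predict_ddf(net, mov, fix)
    expect_identical(max(abs(p$ddf$disp)), 0)
  }
})

test_that("the displacement pyramid has the configured summands and sums to the DDF", {
  set.seed(2)
  mov <- random_volume(c(16, 16, 16), seed = 3)
  fix <- random_volume(c(16, 16, 16), seed = 4)
  mk <- function(variant) {
    build_network(network_config(n0 = 2, levels = 4, variant = variant,
                                 head_init = "small_random"))
  }
  p <- predict_ddf(mk("baseline"), mov, fix)
  expect_length(p$pyramid, 5)
  for (d in p$pyramid) expect_identical(dim(d$disp), c(16L, 16L, 16L, 3L))
  tot <- Reduce(`+`, lapply(p$pyramid, function(d) d$disp))
  expect_equal(tot, p$ddf$disp, tolerance = 1e-12)
  expect_length(predict_ddf(mk("delta0_only"), mov, fix)$pyramid, 1)
  expect_length(predict_ddf(mk("delta1_4"), mov, fix)$pyramid, 4)
})

test_that("prediction is asymmetric in the input order once heads are nonzero", {
  set.seed(5)
  net <- build_network(network_config(n0 = 2, levels = 2,
                                      head_init = "small_random"))
  mov <- random_volume(c(8, 8, 8), seed = 6)
  fix <- random_volume(c(8, 8, 8), seed = 7)
  p1 <- predict_ddf(net, mov, fix)$ddf$disp
  p2 <- predict_ddf(net, fix, mov)$ddf$disp
  expect_gt(max(abs(p1 - p2)), 0)
})

test_that("feature channels double per level and the coarse head sees the whole grid", {
  cfg <- network_config(n0 = 4, levels = 4)
  net <- build_network(cfg)
  for (i in 1:4) {
    expect_identical(dim(net$params$down[[i]]$c2$w)[5],
                     as.integer(4 * 2^(i - 1)))
  }
  expect_identical(dim(net$params$bottom$c2$w)[5], 64L)
  expect_gte(receptive_field(cfg), 32)
})

test_that("the affine head has 12 outputs and its DDF is exactly affine", {
  cfg <- network_config(n0 = 2, levels = 4, variant = "global")
  net <- build_global_net(cfg)
  expect_identical(dim(net$params$head$W)[2], 12L)
  expect_length(net$params$head$b, 12)
  # nonzero head: prediction stays in the affine family (zero bending energy)
  set.seed(8)
  net$params$head$W <- matrix(rnorm(length(net$params$head$W), sd = 0.02),
                              nrow(net$params$head$W))
  net$params$head$b <- rnorm(12, sd = 0.02)
  mov <- random_volume(c(16, 16, 16), seed = 9)
  fix <- random_volume(c(16, 16, 16), seed = 10)
  u <- predict_ddf(net, mov, fix)$ddf
  expect_gt(max(abs(u$disp)), 0)
  expect_lt(bending_energy(u), 1e-10)
})

test_that("the composite equals the global part when the local heads stay zero", {
  set.seed(11)
  gcfg <- network_config(n0 = 2, levels = 2, variant = "global",
                         first_kernel = 3)
  lcfg <- network_config(n0 = 2, levels = 2, variant = "baseline",
                         first_kernel = 3)
  gnet <- build_global_net(gcfg)
  gnet$params$head$b <- c(rep(0, 9), 0.8, -0.4, 0.2)  # pure translation
  lnet <- build_network(lcfg)
  cnet <- build_composite(gnet, lnet)
  expect_identical(n_parameters(cnet), n_parameters(gnet) + n_parameters(lnet))
  mov <- random_volume(c(8, 8, 8), seed = 12)
  fix <- random_volume(c(8, 8, 8), seed = 13)
  ug <- predict_ddf(gnet, mov, fix)$ddf$disp
  uc <- predict_ddf(cnet, mov, fix)$ddf$disp
  expect_equal(uc, ug, tolerance = 1e-9)
})

test_that("hand-written backprop matches finite differences through the whole network", {
  set.seed(14)
  cfgs <- list(
    network_config(n0 = 2, levels = 2, variant = "baseline",
                   first_kernel = 3, head_init = "small_random"),
    network_config(n0 = 2, levels = 2, variant = "global", first_kernel = 3))
  x <- array(rnorm(8 * 8 * 8 * 2 * 2) * 0.5, c(8, 8, 8, 2, 2))
  for (cfg in cfgs) {
    net <- build_network(cfg)
    if (cfg$variant == "global") {
      net$params$head$W <- matrix(rnorm(length(net$params$head$W), sd = 0.05),
                                  nrow(net$params$head$W))
    }
    fw <- weakreg:::net_forward(net, x, training = TRUE)
    gd <- array(rnorm(length(fw$ddf)), dim = dim(fw$ddf))
    bw <- weakreg:::net_backward(net, gd, fw$cache)
    fval <- function(params) {
      n2 <- net; n2$params <- params
      sum(weakreg:::net_forward(n2, x, training = TRUE)$ddf * gd)
    }
    paths <- tree_paths(net$params)
    eps <- 1e-5
    for (t in 1:8) {
      pth <- paths[[sample(length(paths), 1)]]
      leaf <- tree_get(net$params, pth)
      i <- sample(length(leaf), 1)
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      num <- (fval(tree_set(net$params, pth, lp)) -
                fval(tree_set(net$params, pth, lm))) / (2 * eps)
      ana <- tree_get(bw$gp, pth)[i]
      expect_equal(ana, num, tolerance = 1e-3 * max(abs(num), abs(ana), 1e-4))
    }
  }
})

test_that("one gradient step on misaligned spherical labels decreases the loss", {
  set.seed(15)
  sh <- c(16, 16, 16)
  mlab <- sphere_label(sh, c(6.0, 7.5, 7.5), 3)
  flab <- sphere_label(sh, c(9.0, 7.5, 7.5), 3)
  mov <- normalize_intensities(volume(mlab$data + 0.1 +
                                        0.01 * array(rnorm(prod(sh)), sh)))
  fix <- normalize_intensities(volume(flab$data + 0.2 +
                                        0.01 * array(rnorm(prod(sh)), sh)))
  cs <- registration_case("toy", mov, fix,
                          list(list(moving = mlab, fixed = flab,
                                    kind = "adhoc")))
  cfg <- desk_train_config(max_iters = 1, seed = 15)
  cfg$augment <- NULL
  net <- build_network(cfg$net)
  opt <- weakreg:::adam_init(net$params)
  batch <- list(list(case = 1, label = 1))
  s1 <- training_step(net, list(cs), batch, cfg, opt)
  s2 <- training_step(s1$net, list(cs), batch, cfg, s1$opt)
  expect_lt(s2$loss, s1$loss)
})
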