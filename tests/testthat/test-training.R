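toy_cases <- function() {
  sh <- c(8, 8, 8)
  mk <- function(ctr) sphere_label(sh, ctr, 2)
  img <- function(seed) normalize_intensities(random_volume(sh, seed))
  cs1 <- registration_case("c1", img(1), img(2),
                           list(list(moving = mk(c(3.5, 3.5, 3.5)),
                                     fixed = mk(c(4.5, 3.5, 3.5)),
                                     kind = "adhoc")))
  cs2 <- registration_case("c2", img(3), img(4), list(
    list(moving = mk(c(3.5, 3.5, 3.5)), fixed = mk(c(3.5, 4.5, 3.5)),
         kind = "adhoc"),
    list(moving = mk(c(4.5, 4.5, 3.5)), fixed = mk(c(4.5, 4.5, 4.5)),
         kind = "adhoc"),
    list(moving = mk(c(3.5, 4.5, 4.5)), fixed = mk(c(4.5, 4.5, 4.5)),
         kind = "adhoc")))
  list(cs1, cs2)
}

test_that("two-stage sampling hits each (case, label) pair with probability 1/(N*M_n)", {
  ds <- toy_cases()  # N = 2, M = {1, 3}
  set.seed(1)
  n_draws <- 20000
  counts <- matrix(0, 2, 3)
  for (r in seq_len(n_draws / 4)) {
    for (b in sample_minibatch(ds, 4)) {
      counts[b$case, b$label] <- counts[b$case, b$label] + 1
    }
  }
  p_hat <- counts / n_draws
  expect_equal(p_hat[1, 1], 1 / 2, tolerance = 3 * sqrt(0.25 / n_draws) / 0.5)
  for (m in 1:3) {
    expect_equal(p_hat[2, m], 1 / 6,
                 tolerance = 3 * sqrt(1 / 6 * 5 / 6 / n_draws) / (1 / 6))
  }
  # degenerate dataset: always the single pair
  one <- ds[1]
  b <- sample_minibatch(one, 3)
  expect_true(all(vapply(b, function(x) x$case == 1 && x$label == 1,
                         logical(1))))
  set.seed(7); b1 <- sample_minibatch(ds, 8)
  set.seed(7); b2 <- sample_minibatch(ds, 8)
  expect_identical(b1, b2)
  expect_error(sample_minibatch(list(), 2), "empty")
  bad <- ds
  bad[[1]]$label_pairs <- list()
  expect_error(sample_minibatch(bad, 2), "without label pairs")
})

test_that("minibatch gradients of a toy objective are unbiased (two-stage sampling)", {
  # toy predictor: scalar parameter theta, per-pair gradient g_nm known in
  # closed form; the exact full-objective gradient weights each pair by
  # 1/(N*M_n)
  g_pairs <- list(c(2), c(-1, 3, 5))       # case 1: M=1; case 2: M=3
  exact <- mean(c(mean(g_pairs[[1]]), mean(g_pairs[[2]])))
  ds <- toy_cases()
  set.seed(2)
  n_batches <- 10000
  est <- numeric(n_batches)
  for (r in seq_len(n_batches)) {
    b <- sample_minibatch(ds, 4)
    est[r] <- mean(vapply(b, function(x) g_pairs[[x$case]][x$label],
                          numeric(1)))
  }
  mc_sd <- sd(est) / sqrt(n_batches)
  expect_lt(abs(mean(est) - exact), 3 * mc_sd)
})

test_that("a perfectly aligned pair with zero-init network scores loss -1 at alpha = 0.5", {
  sh <- c(8, 8, 8)
  lab <- sphere_label(sh, c(3.5, 3.5, 3.5), 2.2)
  cs <- registration_case("aligned",
                          normalize_intensities(random_volume(sh, 10)),
                          normalize_intensities(random_volume(sh, 11)),
                          list(list(moving = lab, fixed = lab,
                                    kind = "gland")))
  cfg <- train_config(K = 1, lr = 1e-3, max_iters = 1,
                      loss = loss_config(alpha = 0.5,
                                         ms = multiscale_config(0)),
                      net = network_config(n0 = 2, levels = 3,
                                           first_kernel = 3),
                      augment = NULL, seed = 3)
  net <- build_network(cfg$net)
  st <- training_step(net, list(cs), list(list(case = 1, label = 1)), cfg,
                      weakreg:::adam_init(net$params))
  expect_equal(st$loss, -1, tolerance = 1e-9)
  # alpha = 0: the loss is exactly -similarity
  cfg0 <- cfg; cfg0$loss$alpha <- 0
  st0 <- training_step(build_network(cfg$net), list(cs),
                       list(list(case = 1, label = 1)), cfg0,
                       weakreg:::adam_init(net$params))
  expect_equal(st0$loss, -st0$sim)
})

test_that("training is reproducible from seed and config", {
  ds <- toy_cases()
  cfg <- train_config(K = 2, lr = 1e-3, max_iters = 3,
                      loss = loss_config(ms = multiscale_config(c(0, 2))),
                      net = network_config(n0 = 2, levels = 2,
                                           first_kernel = 3),
                      seed = 42)
  r1 <- train_network(ds, cfg)
  r2 <- train_network(ds, cfg)
  expect_identical(r1$log$loss, r2$log$loss)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("max_iters = 0 returns the freshly initialised network", {
  ds <- toy_cases()
  cfg <- train_config(max_iters = 0,
                      net = network_config(n0 = 2, levels = 2,
                                           first_kernel = 3), seed = 5)
  r <- train_network(ds, cfg)
  set.seed(5)
  want <- build_network(cfg$net)
  expect_identical(r$net$params, want$params)
  expect_null(r$log)
})

test_that("per-step work materialises one label pair per member regardless of M_n", {
  # a case with many labels trains at the same per-step footprint: the
  # sampled minibatch only ever references K (case, label) indices
  sh <- c(8, 8, 8)
  many <- replicate(500, list(moving = sphere_label(sh, c(3.5, 3.5, 3.5), 1.5),
                              fixed = sphere_label(sh, c(4.5, 3.5, 3.5), 1.5),
                              kind = "adhoc"), simplify = FALSE)
  cs <- registration_case("many",
                          normalize_intensities(random_volume(sh, 20)),
                          normalize_intensities(random_volume(sh, 21)), many)
  set.seed(6)
  b <- sample_minibatch(list(cs), 4)
  expect_length(b, 4)
  cfg <- train_config(K = 4, lr = 1e-3, max_iters = 1,
                      loss = loss_config(ms = multiscale_config(c(0, 2))),
                      net = network_config(n0 = 2, levels = 2,
                                           first_kernel = 3),
                      augment = NULL, seed = 6)
  net <- build_network(cfg$net)
  st <- training_step(net, list(cs), b, cfg, weakreg:::adam_init(net$params))
  expect_true(is.finite(st$loss))
})
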