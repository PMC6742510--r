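test_that("soft Dice matches hand-evaluated cases", {
  a <- array(c(1, 1, 0, 0, 0, 0, 0, 0), c(2, 2, 2))
  b <- array(c(1, 0, 1, 0, 0, 0, 0, 0), c(2, 2, 2))
  expect_equal(soft_dice(a, b), 0.5)
  lab <- sphere_label(c(8, 8, 8), rep(3.5, 3), 2.5)
  expect_equal(soft_dice(lab, lab), 1)
  disj <- array(0, c(2, 2, 2)); disj[1, 1, 1] <- 1
  disj2 <- array(0, c(2, 2, 2)); disj2[2, 2, 2] <- 1
  expect_equal(soft_dice(disj, disj2), 0)
  expect_equal(soft_dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_equal(soft_dice(a, b), soft_dice(b, a))
  expect_error(soft_dice(a * 2, b), "\\[0, 1\\]")
})

test_that("Gaussian filtering matches dense brute-force convolution", {
  # sigma 0 is the identity (Dirac delta)
  f <- array(runif(6^3), c(6, 6, 6))
  expect_identical(gaussian_filter(f, 0, c(1, 1, 1)), f)
  # interior of a constant field stays 1 (kernel normalisation)
  const <- array(1, c(16, 16, 16))
  expect_lt(abs(gaussian_filter(const, 1, c(1, 1, 1))[8, 8, 8] - 1), 1e-6)
  # brute-force oracle on 16^3 for sigma in {1,2,4} voxels
  set.seed(1)
  f <- array(runif(16^3), c(16, 16, 16))
  brute <- function(f, sigma, trunc = 3) {
    r <- ceiling(trunc * sigma)
    k1 <- exp(-0.5 * ((-r:r) / sigma)^2); k1 <- k1 / sum(k1)
    out <- array(0, dim(f))
    n <- dim(f)[1]
    for (i in 1:n) for (j in 1:n) for (kk in 1:n) {
      acc <- 0
      for (a_ in max(1, i - r):min(n, i + r))
        for (b_ in max(1, j - r):min(n, j + r))
          for (c_ in max(1, kk - r):min(n, kk + r)) {
            acc <- acc + k1[a_ - i + r + 1] * k1[b_ - j + r + 1] *
              k1[c_ - kk + r + 1] * f[a_, b_, c_]
          }
      out[i, j, kk] <- acc
    }
    out
  }
  for (s in c(1, 2, 4)) {
    expect_lt(max(abs(gaussian_filter(f, s, c(1, 1, 1)) - brute(f, s))),
              1e-6)
  }
})

test_that("multiscale Dice reduces to soft Dice at sigma = 0 and matches a per-scale oracle", {
  lab1 <- sphere_label(c(16, 16, 16), c(4.5, 7.5, 7.5), 2)
  lab2 <- sphere_label(c(16, 16, 16), c(10.5, 7.5, 7.5), 2)
  cfg0 <- multiscale_config(sigmas = 0)
  expect_identical(multiscale_dice(lab1$data, lab2$data, cfg0, c(1, 1, 1)),
                   soft_dice(lab1$data, lab2$data))
  # identical *binary* labels score exactly 1 only at sigma = 0; at larger
  # scales the filtered fields are fractional and S(f, f) = sum(f^2)/sum(f)
  # < 1 -- the intended penalty on high-confidence binary predictions
  cfgl <- multiscale_config(c(0, 1, 2, 4))
  self_ms <- multiscale_dice(lab1$data, lab1$data, cfgl, c(1, 1, 1))
  self_oracle <- mean(vapply(cfgl$sigmas, function(s) {
    f <- gaussian_filter(lab1$data, s, c(1, 1, 1))
    soft_dice(f, f)
  }, numeric(1)))
  expect_equal(self_ms, self_oracle, tolerance = 1e-12)
  expect_lt(self_ms, 1)
  expect_gt(self_ms, 0)
  # distant single-voxel labels: raw Dice is blind, the multiscale form not
  a <- array(0, c(32, 32, 32)); a[13, 16, 16] <- 1
  b <- array(0, c(32, 32, 32)); b[19, 16, 16] <- 1
  cfg <- multiscale_config()
  msd <- multiscale_dice(a, b, cfg, c(1, 1, 1))
  expect_identical(soft_dice(a, b), 0)
  expect_gt(msd, 0)
  oracle <- mean(vapply(cfg$sigmas, function(s) {
    soft_dice(gaussian_filter(a, s, c(1, 1, 1)),
              gaussian_filter(b, s, c(1, 1, 1)))
  }, numeric(1)))
  expect_equal(msd, oracle)
  expect_equal(msd, multiscale_dice(b, a, cfg, c(1, 1, 1)))
  expect_lte(msd, 1)
})

test_that("multiscale Dice decays with centroid separation", {
  base <- c(8.5, 15.5, 15.5)
  cfg <- multiscale_config(c(0, 1, 2, 4, 8))
  vals <- vapply(seq(0, 12, by = 2), function(d) {
    a <- sphere_label(c(32, 32, 32), base, 2)
    b <- sphere_label(c(32, 32, 32), base + c(d, 0, 0), 2)
    multiscale_dice(a$data, b$data, cfg, c(1, 1, 1))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("multiscale cross-entropy matches closed forms and stays finite", {
  half <- array(0.5, c(4, 4, 4))
  cfg0 <- multiscale_config(sigmas = 0)
  expect_equal(multiscale_cross_entropy(half, half, cfg0, c(1, 1, 1)),
               log(0.5), tolerance = 1e-12)
  # clip-floor optimum for perfectly matching binaries
  clip <- 1e-6
  ones <- array(1, c(4, 4, 4))
  # only the warped-label argument is clipped: a = 1 against b clipped to
  # 1 - clip scores log(1 - clip); if both fields sit at the clip floor the
  # value is the clip-floor optimum
  expect_equal(multiscale_cross_entropy(ones, ones, cfg0, c(1, 1, 1),
                                        ce_clip = clip),
               log(1 - clip), tolerance = 1e-12)
  at_floor <- array(1 - clip, c(4, 4, 4))
  want <- (1 - clip) * log(1 - clip) + clip * log(clip)
  expect_equal(multiscale_cross_entropy(at_floor, at_floor, cfg0, c(1, 1, 1),
                                        ce_clip = clip),
               want, tolerance = 1e-9)
  # worst case (a = 1, b = 0) is finite thanks to clipping
  zeros <- array(0, c(4, 4, 4))
  expect_true(is.finite(multiscale_cross_entropy(ones, zeros, cfg0,
                                                 c(1, 1, 1))))
})

test_that("bending energy vanishes for affine fields and matches a polynomial closed form", {
  sh <- c(8, 8, 8)
  expect_equal(bending_energy(zero_ddf(sh)), 0)
  aff <- affine_to_ddf(affine_params(weakreg:::rotation_matrix(c(7, -4, 3)) %*%
                                       diag(c(1.1, 0.95, 1.02)),
                                     c(1, 2, -1)), sh)
  expect_lt(bending_energy(aff), 1e-8)
  # u_x = x^2 on a 1 mm grid: d2/dx2 = 2 everywhere, contribution 4/voxel
  u <- zero_ddf(sh)
  x <- weakreg:::grid_index(sh)[, 1]
  u$disp[, , , 1] <- array(x^2, dim = sh)
  expect_equal(bending_energy(u), 4, tolerance = 1e-10)
})

test_that("gradient-L2 regulariser matches closed forms", {
  sh <- c(8, 8, 8)
  expect_equal(gradient_l2(zero_ddf(sh)), 0)
  expect_equal(gradient_l2(constant_ddf(sh, c(2, -1, 5))), 0)
  u <- affine_to_ddf(affine_params(diag(3) * 1.1), sh)
  expect_equal(gradient_l2(u), 3 * 0.1^2, tolerance = 1e-10)
})

test_that("the total loss combines similarity and regulariser as -J + alpha*Omega", {
  lab <- sphere_label(c(8, 8, 8), rep(3.5, 3), 2.5)
  cfg <- loss_config(alpha = 0.5, ms = multiscale_config(0))
  expect_equal(total_loss(lab$data, lab$data, zero_ddf(c(8, 8, 8)), cfg), -1)
  # the bending-energy term is blind to affine deformations
  aff <- affine_to_ddf(affine_params(diag(3) * 1.1), c(8, 8, 8))
  expect_equal(total_loss(lab$data, lab$data, aff, cfg), -1,
               tolerance = 1e-8)
  cfg2 <- loss_config(regularizer = "gradient_l2", alpha = 0.5,
                      ms = multiscale_config(0))
  expect_equal(total_loss(lab$data, lab$data, aff, cfg2), -1 + 0.5 * 0.03,
               tolerance = 1e-8)
  # with the full ladder the loss is exactly -multiscale_dice + alpha*reg
  cfg3 <- loss_config(alpha = 0.5, ms = multiscale_config(c(0, 1, 2)))
  expect_equal(total_loss(lab$data, lab$data, aff, cfg3),
               -multiscale_dice(lab$data, lab$data, cfg3$ms, c(1, 1, 1)),
               tolerance = 1e-8)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(3)
  a <- array(runif(8^3), c(8, 8, 8))
  b <- array(runif(8^3) * 0.8 + 0.1, c(8, 8, 8))
  ms <- multiscale_config(c(0, 1, 2))
  eps <- 1e-6
  check <- function(fun, grad) {
    for (i in sample(length(b), 5)) {
      bp <- b; bp[i] <- bp[i] + eps
      bm <- b; bm[i] <- bm[i] - eps
      num <- (fun(bp) - fun(bm)) / (2 * eps)
      expect_equal(grad[i], num,
                   tolerance = 1e-3 * max(abs(num), 1e-6))
    }
  }
  check(function(bb) multiscale_dice(a, bb, ms, c(1, 1, 1)),
        weakreg:::multiscale_dice_grad(a, b, ms, c(1, 1, 1)))
  check(function(bb) multiscale_cross_entropy(a, bb, ms, c(1, 1, 1)),
        weakreg:::multiscale_cross_entropy_grad(a, b, ms, c(1, 1, 1), 1e-6))
  u <- smooth_random_ddf(c(8, 8, 8), amp = 1.5, seed = 4)
  for (nm in c("bending_energy", "gradient_l2")) {
    fun <- get(nm)
    g <- if (nm == "bending_energy") weakreg:::bending_energy_grad(u) else
      weakreg:::gradient_l2_grad(u)
    for (i in sample(length(u$disp), 5)) {
      up <- u; up$disp[i] <- up$disp[i] + eps
      um <- u; um$disp[i] <- um$disp[i] - eps
      num <- (fun(up) - fun(um)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-3 * max(abs(num), 1e-6))
    }
  }
})

test_that("pre-filtered evaluation agrees with on-the-fly filtering without warping", {
  lab1 <- sphere_label(c(12, 12, 12), c(4.5, 5.5, 5.5), 2.5)
  lab2 <- sphere_label(c(12, 12, 12), c(6.5, 6.5, 5.5), 2.5)
  ms <- multiscale_config(c(0, 1, 2, 4))
  onfly <- multiscale_dice(lab1$data, lab2$data, ms, c(1, 1, 1))
  z <- zero_ddf(c(12, 12, 12))
  pre <- weakreg:::member_loss(lab1$data, lab2$data, z,
                               loss_config(alpha = 0, prefiltered = TRUE,
                                           ms = ms))
  expect_equal(pre$sim, onfly, tolerance = 1e-10)
})
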