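# Label-similarity measures and deformation regularisers, with analytic
# gradients along the warped-label / DDF paths (used by the trainer).

#' Multiscale filtering configuration
#'
#' The scale ladder of the multiscale label similarity: Gaussian standard
#' deviations in mm (0 means no filtering, the raw label).  The default is
#' the seven-scale ladder 0,1,2,4,8,16,32 mm; desk-scale experiments on
#' small grids use a truncated ladder via \code{sigmas}.
#'
#' @param sigmas distinct non-negative SDs in mm.
#' @param truncation kernel half-width in SDs (kernel renormalised to unit
#'   sum).
#' @return A list of class \code{weakreg_msconfig}.
#' @export
multiscale_config <- function(sigmas = c(0, 1, 2, 4, 8, 16, 32),
                              truncation = 3) {
  sigmas <- as.numeric(sigmas)
  if (any(sigmas < 0) || anyDuplicated(sigmas)) {
    stop("sigmas must be distinct and non-negative")
  }
  structure(list(sigmas = sigmas, Z = length(sigmas), truncation = truncation),
            class = "weakreg_msconfig")
}

#' Loss configuration
#'
#' @param similarity \code{"multiscale_dice"} or
#'   \code{"multiscale_cross_entropy"}.
#' @param regularizer \code{"bending_energy"} or \code{"gradient_l2"}.
#' @param alpha non-negative regularisation weight (0.5 in the baseline).
#' @param ms a \code{\link{multiscale_config}}.
#' @param prefiltered if TRUE, labels are Gaussian-filtered once up front
#'   and warped per scale, instead of filtering the warped label on the fly.
#' @param ce_clip probability floor for the cross-entropy (in (0, 0.5)).
#' @return A list of class \code{weakreg_lossconfig}.
#' @export
loss_config <- function(similarity = c("multiscale_dice",
                                       "multiscale_cross_entropy"),
                        regularizer = c("bending_energy", "gradient_l2"),
                        alpha = 0.5, ms = multiscale_config(),
                        prefiltered = FALSE, ce_clip = 1e-6) {
  similarity <- match.arg(similarity)
  regularizer <- match.arg(regularizer)
  if (alpha < 0) stop("alpha must be non-negative")
  if (ce_clip <= 0 || ce_clip >= 0.5) stop("ce_clip must be in (0, 0.5)")
  structure(list(similarity = similarity, regularizer = regularizer,
                 alpha = alpha, ms = ms, prefiltered = isTRUE(prefiltered),
                 ce_clip = ce_clip),
            class = "weakreg_lossconfig")
}

gauss_kernel <- function(sigma_vox, truncation) {
  r <- max(1L, as.integer(ceiling(truncation * sigma_vox)))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

.op_cache <- new.env(parent = emptyenv())

gauss_matrix <- function(n, sigma_vox, truncation) {
  if (sigma_vox < 1e-8) return(diag(n))
  key <- paste0("g", n, "_", signif(sigma_vox, 10), "_", truncation)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gauss_kernel(sigma_vox, truncation)
  r <- (length(k) - 1L) / 2L
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    G[i, j[keep]] <- k[keep]
  }
  .op_cache[[key]] <- G
  G
}

label_field <- function(x) {
  if (inherits(x, "weakreg_volume")) x$data else as.array(x)
}

#' Separable 3D Gaussian filtering of a label field
#'
#' Filters with an isotropic Gaussian of standard deviation
#' \code{sigma_mm} (converted to voxels via the spacing), truncated at
#' \code{truncation} SDs, kernel normalised to unit sum, zero padding at the
#' borders.  \code{sigma_mm = 0} returns the input unchanged.
#'
#' @param v 3D array or \code{weakreg_volume} with values in [0,1].
#' @param sigma_mm Gaussian SD in mm (>= 0).
#' @param spacing voxel sizes in mm (taken from \code{v} when it is a
#'   volume).
#' @param truncation kernel half-width in SDs.
#' @return Filtered field, same type as the input.
#' @export
gaussian_filter <- function(v, sigma_mm, spacing = NULL, truncation = 3) {
  if (sigma_mm < 0) stop("sigma_mm must be non-negative")
  isvol <- inherits(v, "weakreg_volume")
  if (is.null(spacing)) {
    if (!isvol) stop("spacing required when filtering a plain array")
    spacing <- v$spacing
  }
  a <- label_field(v)
  if (sigma_mm > 0) {
    for (ax in 1:3) {
      a <- apply_axis(a, gauss_matrix(dim(a)[ax], sigma_mm / spacing[ax],
                                      truncation), ax)
    }
  }
  if (isvol) volume(pmin(pmax(a, 0), 1), v$spacing, v$origin,
                    is_label = v$is_label) else a
}

# adjoint of gaussian_filter (transpose along each axis)
gaussian_filter_adjoint <- function(a, sigma_mm, spacing, truncation = 3) {
  if (sigma_mm > 0) {
    for (ax in 1:3) {
      a <- apply_axis(a, t(gauss_matrix(dim(a)[ax], sigma_mm / spacing[ax],
                                        truncation)), ax)
    }
  }
  a
}

check_unit_range <- function(a, what) {
  if (min(a) < -1e-6 || max(a) > 1 + 1e-6) {
    stop(what, " values must lie in [0, 1]")
  }
}

#' Soft (probabilistic) Dice between two label fields
#'
#' 2 * sum(a*b) / (sum(a) + sum(b)) over all voxels, for fractional label
#' values in [0,1].  Two empty labels score 1 (perfect agreement of empty
#' sets).
#'
#' @param a,b arrays or \code{weakreg_volume}s of identical shape with
#'   values in [0,1].
#' @return Scalar in [0,1].
#' @export
soft_dice <- function(a, b) {
  a <- label_field(a); b <- label_field(b)
  if (!identical(dim(a), dim(b))) stop("label fields must share shape")
  check_unit_range(a, "label"); check_unit_range(b, "label")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

soft_dice_grad_b <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0) return(array(0, dim = dim(a)))
  s <- 2 * sum(a * b) / denom
  (2 * a - s) / denom
}

#' Multiscale soft Dice
#'
#' The mean of \code{\link{soft_dice}} over Gaussian-filtered versions of
#' both labels at every scale of the ladder.  Filtering spreads distant
#' labels toward each other, restoring gradient signal that the raw Dice
#' loses once structures do not overlap.
#'
#' @param fixed_label,warped_label fields in [0,1] of identical shape.
#' @param cfg a \code{\link{multiscale_config}}.
#' @param spacing voxel sizes in mm.
#' @return Scalar in [0,1].
#' @export
multiscale_dice <- function(fixed_label, warped_label, cfg = multiscale_config(),
                            spacing = c(1, 1, 1)) {
  a <- label_field(fixed_label); b <- label_field(warped_label)
  vals <- vapply(cfg$sigmas, function(s) {
    soft_dice(gaussian_filter(a, s, spacing, cfg$truncation),
              gaussian_filter(b, s, spacing, cfg$truncation))
  }, numeric(1))
  mean(vals)
}

multiscale_dice_grad <- function(fixed_label, warped_label, cfg, spacing) {
  a <- label_field(fixed_label); b <- label_field(warped_label)
  g <- array(0, dim = dim(b))
  for (s in cfg$sigmas) {
    fa <- gaussian_filter(a, s, spacing, cfg$truncation)
    fb <- gaussian_filter(b, s, spacing, cfg$truncation)
    g <- g + gaussian_filter_adjoint(soft_dice_grad_b(fa, fb), s, spacing,
                                     cfg$truncation)
  }
  g / cfg$Z
}

#' Multiscale negative cross-entropy similarity
#'
#' Per scale, the mean over voxels of
#' a*log(b') + (1-a)*log(1-b') with b clipped to [ce_clip, 1-ce_clip],
#' averaged over the scale ladder; a negative quantity whose maximum is
#' attained when the filtered fields agree, used interchangeably with the
#' multiscale Dice inside the training utility.
#'
#' @inheritParams multiscale_dice
#' @param ce_clip probability floor.
#' @return Scalar <= 0.
#' @export
multiscale_cross_entropy <- function(fixed_label, warped_label,
                                     cfg = multiscale_config(),
                                     spacing = c(1, 1, 1), ce_clip = 1e-6) {
  a <- label_field(fixed_label); b <- label_field(warped_label)
  check_unit_range(a, "label"); check_unit_range(b, "label")
  vals <- vapply(cfg$sigmas, function(s) {
    fa <- gaussian_filter(a, s, spacing, cfg$truncation)
    fb <- gaussian_filter(b, s, spacing, cfg$truncation)
    fb <- pmin(pmax(fb, ce_clip), 1 - ce_clip)
    mean(fa * log(fb) + (1 - fa) * log(1 - fb))
  }, numeric(1))
  mean(vals)
}

multiscale_cross_entropy_grad <- function(fixed_label, warped_label, cfg,
                                          spacing, ce_clip = 1e-6) {
  a <- label_field(fixed_label); b <- label_field(warped_label)
  g <- array(0, dim = dim(b))
  nv <- length(b)
  for (s in cfg$sigmas) {
    fa <- gaussian_filter(a, s, spacing, cfg$truncation)
    fb <- gaussian_filter(b, s, spacing, cfg$truncation)
    inside <- fb > ce_clip & fb < 1 - ce_clip
    fbc <- pmin(pmax(fb, ce_clip), 1 - ce_clip)
    gs <- (fa / fbc - (1 - fa) / (1 - fbc)) * inside / nv
    g <- g + gaussian_filter_adjoint(gs, s, spacing, cfg$truncation)
  }
  g / cfg$Z
}

be_terms <- function(u) {
  shape <- ddf_grid_shape(u)
  D1 <- lapply(1:3, function(ax) diff1_matrix(shape[ax], u$spacing[ax]))
  D2 <- lapply(1:3, function(ax) diff2_matrix(shape[ax], u$spacing[ax]))
  mixed <- list(c(1, 2), c(2, 3), c(1, 3))
  lapply(1:3, function(cc) {
    comp <- u$disp[, , , cc, drop = FALSE]; dim(comp) <- shape
    pure <- lapply(1:3, function(ax) apply_axis(comp, D2[[ax]], ax))
    mix <- lapply(mixed, function(ab) {
      apply_axis(apply_axis(comp, D1[[ab[1]]], ab[1]), D1[[ab[2]]], ab[2])
    })
    list(pure = pure, mix = mix)
  })
}

#' Bending energy of a displacement field
#'
#' The mean over voxels of the summed squared second derivatives of each
#' displacement component (the three pure terms plus the doubled mixed
#' terms), finite differences in world mm.  Exactly zero for any affine
#' field.
#'
#' @param u a \code{weakreg_ddf} on a grid with >= 3 voxels per axis.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(u) {
  terms <- be_terms(u)
  nv <- prod(ddf_grid_shape(u))
  tot <- 0
  for (ct in terms) {
    tot <- tot + sum(vapply(ct$pure, function(x) sum(x^2), numeric(1))) +
      2 * sum(vapply(ct$mix, function(x) sum(x^2), numeric(1)))
  }
  tot / nv
}

bending_energy_grad <- function(u) {
  shape <- ddf_grid_shape(u)
  nv <- prod(shape)
  D1 <- lapply(1:3, function(ax) diff1_matrix(shape[ax], u$spacing[ax]))
  D2 <- lapply(1:3, function(ax) diff2_matrix(shape[ax], u$spacing[ax]))
  mixed <- list(c(1, 2), c(2, 3), c(1, 3))
  terms <- be_terms(u)
  g <- array(0, dim = dim(u$disp))
  for (cc in 1:3) {
    acc <- array(0, dim = shape)
    for (ax in 1:3) {
      acc <- acc + 2 * apply_axis(terms[[cc]]$pure[[ax]], t(D2[[ax]]), ax)
    }
    for (mi in seq_along(mixed)) {
      ab <- mixed[[mi]]
      adj <- apply_axis(apply_axis(terms[[cc]]$mix[[mi]], t(D1[[ab[2]]]), ab[2]),
                        t(D1[[ab[1]]]), ab[1])
      acc <- acc + 4 * adj
    }
    g[, , , cc] <- acc / nv
  }
  g
}

#' Mean squared L2 norm of the displacement gradients
#'
#' The mean over voxels of the squared Frobenius norm of du/dp (nine
#' first-derivative terms), finite differences in mm; the lighter-weight
#' alternative regulariser to the bending energy.
#'
#' @param u a \code{weakreg_ddf}.
#' @return Non-negative scalar.
#' @export
gradient_l2 <- function(u) {
  g <- ddf_gradients(u)
  nv <- prod(ddf_grid_shape(u))
  tot <- 0
  for (cc in 1:3) for (ax in 1:3) tot <- tot + sum(g[[cc]][[ax]]^2)
  tot / nv
}

gradient_l2_grad <- function(u) {
  shape <- ddf_grid_shape(u)
  nv <- prod(shape)
  D1 <- lapply(1:3, function(ax) diff1_matrix(shape[ax], u$spacing[ax]))
  g <- ddf_gradients(u)
  out <- array(0, dim = dim(u$disp))
  for (cc in 1:3) {
    acc <- array(0, dim = shape)
    for (ax in 1:3) {
      acc <- acc + 2 * apply_axis(g[[cc]][[ax]], t(D1[[ax]]), ax)
    }
    out[, , , cc] <- acc / nv
  }
  out
}

similarity_value <- function(fixed_label, warped_label, cfg, spacing) {
  switch(cfg$similarity,
         multiscale_dice = multiscale_dice(fixed_label, warped_label, cfg$ms,
                                           spacing),
         multiscale_cross_entropy = multiscale_cross_entropy(
           fixed_label, warped_label, cfg$ms, spacing, cfg$ce_clip),
         stop("unknown similarity: ", cfg$similarity))
}

similarity_grad <- function(fixed_label, warped_label, cfg, spacing) {
  switch(cfg$similarity,
         multiscale_dice = multiscale_dice_grad(fixed_label, warped_label,
                                                cfg$ms, spacing),
         multiscale_cross_entropy = multiscale_cross_entropy_grad(
           fixed_label, warped_label, cfg$ms, spacing, cfg$ce_clip))
}

regularizer_value <- function(u, cfg) {
  switch(cfg$regularizer,
         bending_energy = bending_energy(u),
         gradient_l2 = gradient_l2(u),
         stop("unknown regularizer: ", cfg$regularizer))
}

regularizer_grad <- function(u, cfg) {
  switch(cfg$regularizer,
         bending_energy = bending_energy_grad(u),
         gradient_l2 = gradient_l2_grad(u))
}

#' Total training loss for one image-label pair
#'
#' -similarity(fixed_label, warped_label) + alpha * regulariser(u): lower is
#' better, decreasing in label agreement and increasing in deformation
#' roughness.
#'
#' @param fixed_label,warped_label label fields in [0,1].
#' @param u the predicted \code{weakreg_ddf}.
#' @param cfg a \code{\link{loss_config}}.
#' @return Scalar loss value.
#' @export
total_loss <- function(fixed_label, warped_label, u, cfg = loss_config()) {
  -similarity_value(fixed_label, warped_label, cfg, u$spacing) +
    cfg$alpha * regularizer_value(u, cfg)
}
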