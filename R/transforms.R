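# Differentiable warping, affine fields, composition and DDF diagnostics.
# All displacements are in mm with backward (pull-back) semantics on the
# fixed grid; voxel <-> world conversion uses the isotropic-per-axis spacing.

grid_index <- function(shape) {
  as.matrix(expand.grid(x = seq_len(shape[1]) - 1,
                        y = seq_len(shape[2]) - 1,
                        z = seq_len(shape[3]) - 1))
}

# continuous source voxel coordinates p + u(p)/h for every fixed voxel
ddf_sample_positions <- function(u) {
  shape <- ddf_grid_shape(u)
  grid_index(shape) + sweep(matrix(u$disp, ncol = 3), 2, u$spacing, "/")
}

#' Warp a volume by a dense displacement field
#'
#' Backward warping: the output at fixed-grid voxel p samples the input at
#' world position p + u(p) by trilinear (or nearest-neighbour)
#' interpolation, with zero outside the input extent.  The linear mode is
#' differentiable with respect to u and keeps fractional label values (as
#' required on the loss path); use \code{mode = "nearest"} only for
#' categorical resampling.
#'
#' @param v a \code{weakreg_volume} sharing its grid shape with \code{u}.
#' @param u a \code{weakreg_ddf}.
#' @param mode \code{"linear"} or \code{"nearest"}.
#' @return The warped \code{weakreg_volume} on the fixed grid.
#' @export
warp_volume <- function(v, u, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  shape <- dim(v$data)
  if (!identical(shape, ddf_grid_shape(u))) {
    stop("volume and DDF must share grid shape")
  }
  pos <- ddf_sample_positions(u)
  if (mode == "nearest") pos <- round(pos)
  f <- v$data
  dim(f) <- c(shape, 1L)
  out <- array(cpp_resample3_fwd(f, pos)[, 1], dim = shape)
  if (v$is_label) out <- pmin(pmax(out, 0), 1)
  dim(out) <- shape
  volume(out, spacing = u$spacing, origin = u$origin, is_label = v$is_label)
}

# warp with gradient bookkeeping: returns warped data plus a pullback
# closure mapping d(loss)/d(warped) to gradients w.r.t. u (mm) and field
warp_field_vjp <- function(field3d, u) {
  shape <- dim(field3d)
  pos <- ddf_sample_positions(u)
  f <- field3d
  dim(f) <- c(shape, 1L)
  out <- array(cpp_resample3_fwd(f, pos)[, 1], dim = shape)
  list(out = out, pullback = function(g_out) {
    g <- matrix(as.numeric(g_out), ncol = 1)
    bw <- cpp_resample3_bwd(f, pos, g)
    gu <- sweep(bw$gpos, 2, u$spacing, "/")  # d pos / d u = 1/h
    dim(gu) <- c(shape, 3L)
    gfield <- bw$gfield
    dim(gfield) <- shape
    list(g_u = gu, g_field = gfield)
  })
}

#' Affine transform parameters
#'
#' World-coordinate affine map p -> A p + t (mm).  The linear part must have
#' positive determinant (no flips).
#'
#' @param A 3x3 linear part.
#' @param t length-3 translation (mm).
#' @param draws optional record of the random draws that produced the
#'   parameters (augmentation provenance).
#' @return An object of class \code{weakreg_affine}.
#' @export
affine_params <- function(A, t = c(0, 0, 0), draws = NULL) {
  A <- matrix(as.numeric(A), 3, 3)
  if (det(A) <= 0) stop("affine linear part must have positive determinant")
  structure(list(A = A, t = as.numeric(t), draws = draws),
            class = "weakreg_affine")
}

#' Convert affine parameters to a DDF
#'
#' u(p) = A p + t - p evaluated at the world position of every fixed-grid
#' voxel.
#'
#' @param a a \code{weakreg_affine}.
#' @param shape fixed-grid dimensions.
#' @param spacing,origin fixed-grid geometry (mm).
#' @return A \code{weakreg_ddf}.
#' @export
affine_to_ddf <- function(a, shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  idx <- grid_index(shape)
  p <- sweep(sweep(idx, 2, spacing, "*"), 2, origin, "+")
  up <- p %*% t(a$A - diag(3))
  up <- sweep(up, 2, a$t, "+")
  ddf(array(up, dim = c(shape, 3L)), spacing = spacing, origin = origin)
}

#' Compose two displacement fields
#'
#' Returns the field w with warp(v, w) == warp(warp(v, u_first), u_second)
#' up to interpolation error: w(p) = u_second(p) + u_first(p + u_second(p)),
#' the inner field resampled trilinearly (zero displacement outside its
#' extent).
#'
#' @param u_first,u_second \code{weakreg_ddf}s on the same grid.
#' @return The composed \code{weakreg_ddf}.
#' @export
compose_ddf <- function(u_first, u_second) {
  if (!identical(ddf_grid_shape(u_first), ddf_grid_shape(u_second))) {
    stop("DDFs must share grid shape")
  }
  pos <- ddf_sample_positions(u_second)
  sampled <- cpp_resample3_fwd(u_first$disp, pos)
  w <- u_second$disp + array(sampled, dim = dim(u_second$disp))
  ddf(w, spacing = u_second$spacing, origin = u_second$origin)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Draw a random affine transform (augmentation)
#'
#' Rotations, anisotropic scales, shears and translations are drawn
#' uniformly within the configured ranges and composed about \code{centre};
#' the linear part always has positive determinant (no flips).  Draws come
#' from R's RNG stream, so a prior \code{set.seed} makes them reproducible.
#'
#' @param ranges list with \code{rot_deg} (max rotation per axis, degrees),
#'   \code{scale} (interval around 1), \code{shear} (max shear coefficient)
#'   and \code{trans_mm} (max translation per axis, mm).
#' @param centre world point the rotation/scaling is taken about (mm).
#' @return A \code{weakreg_affine}.
#' @export
random_affine <- function(ranges = list(rot_deg = 10, scale = c(0.95, 1.05),
                                        shear = 0.05, trans_mm = 2),
                          centre = c(0, 0, 0)) {
  if (min(ranges$scale) <= 0) {
    stop("scale interval must be strictly positive (flips are not allowed)")
  }
  ang <- runif(3, -ranges$rot_deg, ranges$rot_deg)
  sc <- runif(3, min(ranges$scale), max(ranges$scale))
  sh <- runif(3, -ranges$shear, ranges$shear)
  tr <- runif(3, -ranges$trans_mm, ranges$trans_mm)
  Sh <- diag(3); Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
  A <- rotation_matrix(ang) %*% Sh %*% diag(sc)
  t <- as.numeric(centre - A %*% centre) + tr
  affine_params(A, t, draws = list(angles_deg = ang, scales = sc,
                                   shears = sh, trans_mm = tr))
}

# first-derivative operator along one axis: central differences in the
# interior, one-sided at the boundaries, in units of 1/h.  Exact for
# linear (affine) fields everywhere, including the boundary rows.
diff1_matrix <- function(n, h) {
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in 2:(n - 1)) { D[i, i - 1] <- -1 / (2 * h); D[i, i + 1] <- 1 / (2 * h) }
  D[1, 1] <- -1 / h; D[1, 2] <- 1 / h
  D[n, n - 1] <- -1 / h; D[n, n] <- 1 / h
  D
}

# second-derivative operator: standard 3-point stencil, boundary rows reuse
# the adjacent interior stencil (exact zero for affine fields).
diff2_matrix <- function(n, h) {
  if (n < 3) stop("grid must have >= 3 voxels per axis for second derivatives")
  D <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    D[i, i - 1] <- 1; D[i, i] <- -2; D[i, i + 1] <- 1
  }
  D[1, 1:3] <- c(1, -2, 1)
  D[n, (n - 2):n] <- c(1, -2, 1)
  D / h^2
}

# contract matrix M over one axis of an N-dimensional array (compiled
# per-slice GEMMs; no aperm)
apply_axis <- function(a, M, axis) {
  d <- dim(a)
  pre <- if (axis == 1) 1L else prod(d[seq_len(axis - 1)])
  post <- if (axis == length(d)) 1L else prod(d[seq(axis + 1, length(d))])
  out <- cpp_apply_axis(a, M, pre, d[axis], post)
  d[axis] <- nrow(M)
  dim(out) <- d
  out
}

# list over components c of list over axes j of d u_c / d x_j (1/mm units
# cancel: u is mm, derivative w.r.t. mm -> dimensionless)
ddf_gradients <- function(u) {
  shape <- ddf_grid_shape(u)
  D <- lapply(1:3, function(ax) diff1_matrix(shape[ax], u$spacing[ax]))
  lapply(1:3, function(cc) {
    comp <- u$disp[, , , cc, drop = FALSE]
    dim(comp) <- shape
    lapply(1:3, function(ax) apply_axis(comp, D[[ax]], ax))
  })
}

#' Per-voxel Jacobian determinant of a deformation
#'
#' Computes det(I + du/dp) with finite differences in world mm (central in
#' the interior, one-sided at boundaries).  Values of 1 indicate locally
#' volume-preserving deformation; non-positive values indicate folding.
#'
#' @param u a \code{weakreg_ddf} with at least 2 voxels per axis.
#' @return A scalar \code{weakreg_volume} of determinants.
#' @export
jacobian_determinant <- function(u) {
  shape <- ddf_grid_shape(u)
  if (any(shape < 2)) stop("grid must have >= 2 voxels per axis")
  g <- ddf_gradients(u)
  J <- function(cc, ax) g[[cc]][[ax]] + (cc == ax)
  det_field <- J(1, 1) * (J(2, 2) * J(3, 3) - J(2, 3) * J(3, 2)) -
    J(1, 2) * (J(2, 1) * J(3, 3) - J(2, 3) * J(3, 1)) +
    J(1, 3) * (J(2, 1) * J(3, 2) - J(2, 2) * J(3, 1))
  volume(det_field, spacing = u$spacing, origin = u$origin)
}

#' Deformation-field diagnostics
#'
#' Per-voxel displacement magnitudes and displacement-gradient L2 norms with
#' their summary statistics, plus the count and fraction of voxels whose
#' Jacobian determinant is non-positive (folding).
#'
#' @param u a \code{weakreg_ddf}.
#' @return A list with fields \code{magnitude}, \code{gradient_norm}
#'   (scalar \code{weakreg_volume}s), their \code{*_summary} (mean, sd, min,
#'   max), and \code{n_nonpositive_jacobian} / \code{frac_nonpositive_jacobian}.
#' @export
ddf_statistics <- function(u) {
  shape <- ddf_grid_shape(u)
  mag <- sqrt(rowSums(matrix(u$disp, ncol = 3)^2))
  dim(mag) <- shape
  g <- ddf_gradients(u)
  gn2 <- array(0, dim = shape)
  for (cc in 1:3) for (ax in 1:3) gn2 <- gn2 + g[[cc]][[ax]]^2
  gn <- sqrt(gn2)
  jd <- jacobian_determinant(u)$data
  summ <- function(x) c(mean = mean(x), sd = sd(as.numeric(x)),
                        min = min(x), max = max(x))
  list(magnitude = volume(mag, u$spacing, u$origin),
       gradient_norm = volume(gn, u$spacing, u$origin),
       magnitude_summary = summ(mag),
       gradient_norm_summary = summ(gn),
       jacobian_summary = summ(jd),
       n_nonpositive_jacobian = sum(jd <= 0),
       frac_nonpositive_jacobian = mean(jd <= 0))
}
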