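# Self-contained two-modality phantom generator.  A gland-like ellipsoid
# with an inner zone, a curved tube ("urethra") and a variable number of
# small spherical landmarks are defined analytically in the fixed frame,
# deformed by a known smooth invertible transformation, and rendered under
# two deliberately non-monotonically-related intensity mappings with
# modality-specific noise.  Because the moving frame is evaluated
# analytically at inverse-mapped coordinates, the stored ground-truth DDF is
# exactly the field a backward-warping registration should recover.

#' Phantom dataset specification
#'
#' @param shape,spacing fixed grid (voxels, mm); must be divisible by
#'   2^levels of the network that will consume it.
#' @param gland_semiaxes range (mm) the three gland semi-axes are drawn from.
#' @param inner_scale inner-zone semi-axes as a fraction of the gland's.
#' @param tube_radius urethra tube radius (mm).
#' @param n_landmarks range of per-case landmark counts (emulating the
#'   variable number of label pairs per case).
#' @param landmark_radius range of landmark sphere radii (mm).
#' @param rot_deg,scale,shear,trans_mm affine component of the ground-truth
#'   deformation (no flips).
#' @param warp_amp_mm,warp_sigma_mm maximum magnitude and Gaussian
#'   smoothing SD of the smooth random deformation component.
#' @param noise_mr additive noise SD of the MR-like (moving) rendering.
#' @param noise_us multiplicative speckle SD of the US-like (fixed)
#'   rendering.
#' @param max_tries retry budget for landmark placement and for drawing a
#'   fold-free deformation.
#' @return A list of class \code{weakreg_phantomspec}.
#' @export
phantom_spec <- function(shape = c(16, 16, 16), spacing = c(1, 1, 1),
                         gland_semiaxes = c(5.0, 6.5), inner_scale = 0.55,
                         tube_radius = 1.8, n_landmarks = c(2, 6),
                         landmark_radius = c(2.0, 2.6),
                         rot_deg = 6, scale = c(0.96, 1.04), shear = 0.03,
                         trans_mm = 1.5, warp_amp_mm = 1.5,
                         warp_sigma_mm = 4, noise_mr = 0.04, noise_us = 0.08,
                         max_tries = 50) {
  structure(as.list(environment()), class = "weakreg_phantomspec")
}

# membership functions evaluated at world positions P (m x 3, mm)
anatomy_masks <- function(anat, P) {
  inside_ellipsoid <- function(e) {
    q <- sweep(P, 2, e$centre) %*% e$R
    as.numeric(rowSums(sweep(q, 2, e$semiaxes, "/")^2) <= 1)
  }
  tube <- anat$tube
  zr <- (P[, 3] - tube$z0) / (tube$z1 - tube$z0)
  cx <- tube$centre[1] + tube$bend * sin(pi * pmin(pmax(zr, 0), 1))
  in_tube <- as.numeric(
    (P[, 1] - cx)^2 + (P[, 2] - tube$centre[2])^2 <= tube$radius^2 &
      zr >= 0 & zr <= 1)
  lms <- lapply(anat$landmarks, function(lm) {
    as.numeric(rowSums(sweep(P, 2, lm$centre)^2) <= lm$radius^2)
  })
  list(gland = inside_ellipsoid(anat$gland),
       inner = inside_ellipsoid(anat$inner),
       urethra = in_tube, landmarks = lms)
}

#' Generate the phantom anatomy for one case
#'
#' Draws a randomly oriented ellipsoidal gland with an inner-zone
#' sub-ellipsoid, a curved tube through the gland, and 2-6 small spheres
#' placed inside the gland (patient-specific landmarks), and rasterises
#' them as binary label volumes on the fixed grid.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{shapes} (analytic descriptors) and \code{masks}
#'   (named list of binary \code{weakreg_volume}s: gland, inner, urethra,
#'   landmark_1..k).
#' @export
make_anatomy <- function(spec) {
  shape <- spec$shape; h <- spec$spacing
  fov_centre <- h * (shape - 1) / 2
  centre <- fov_centre + runif(3, -1, 1)
  semi <- runif(3, spec$gland_semiaxes[1], spec$gland_semiaxes[2])
  R <- rotation_matrix(runif(3, -15, 15))
  gland <- list(centre = centre, semiaxes = semi, R = R)
  inner <- list(centre = centre + runif(3, -0.5, 0.5),
                semiaxes = spec$inner_scale * semi, R = R)
  tube <- list(centre = centre[1:2] + runif(2, -0.5, 0.5),
               bend = runif(1, 0.5, 1.5), radius = spec$tube_radius,
               z0 = centre[3] - semi[3], z1 = centre[3] + semi[3])
  k <- sample(seq(spec$n_landmarks[1], spec$n_landmarks[2]), 1)
  landmarks <- list()
  tries <- 0
  while (length(landmarks) < k) {
    tries <- tries + 1
    if (tries > spec$max_tries * k) {
      stop("could not place ", k, " landmarks inside the gland; ",
           "reduce landmark_radius or enlarge gland_semiaxes")
    }
    r <- runif(1, spec$landmark_radius[1], spec$landmark_radius[2])
    d <- runif(3, -0.7, 0.7)
    if (sum(d^2) > 0.49) next
    ctr <- centre + as.numeric(R %*% (d * semi))
    # sphere fully inside the grid extent
    if (any(ctr - r < 0) || any(ctr + r > h * (shape - 1))) next
    landmarks[[length(landmarks) + 1]] <- list(centre = ctr, radius = r)
  }
  shapes <- list(gland = gland, inner = inner, tube = tube,
                 landmarks = landmarks)
  P <- sweep(grid_index(shape), 2, h, "*")
  mk <- anatomy_masks(shapes, P)
  vol <- function(v) volume(array(v, dim = shape), h, origin = c(0, 0, 0),
                            is_label = TRUE)
  masks <- c(list(gland = vol(mk$gland), inner = vol(mk$inner),
                  urethra = vol(mk$urethra)),
             stats::setNames(lapply(mk$landmarks, vol),
                             paste0("landmark_", seq_along(mk$landmarks))))
  list(shapes = shapes, masks = masks)
}

#' Draw a smooth invertible ground-truth deformation
#'
#' The field is an affine component (uniform draws within the spec ranges,
#' no flips, taken about the grid centre) plus a smooth random component
#' (white-noise vector field Gaussian-filtered at \code{warp_sigma_mm} and
#' rescaled so its largest magnitude equals \code{warp_amp_mm}).  Fields
#' whose Jacobian determinant is not strictly positive everywhere are
#' redrawn (bounded retries).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{weakreg_ddf} (moving-to-fixed correspondence on the
#'   fixed grid).
#' @export
make_deformation <- function(spec) {
  shape <- spec$shape; h <- spec$spacing
  ctr <- h * (shape - 1) / 2
  for (try in seq_len(spec$max_tries)) {
    aff <- random_affine(list(rot_deg = spec$rot_deg, scale = spec$scale,
                              shear = spec$shear, trans_mm = spec$trans_mm),
                         centre = ctr)
    u <- affine_to_ddf(aff, shape, h, origin = c(0, 0, 0))$disp
    if (spec$warp_amp_mm > 0) {
      sm <- array(0, dim = c(shape, 3L))
      for (cc in 1:3) {
        w <- array(rnorm(prod(shape)), dim = shape)
        for (ax in 1:3) {
          w <- apply_axis(w, gauss_matrix(shape[ax],
                                          spec$warp_sigma_mm / h[ax], 3), ax)
        }
        sm[, , , cc] <- w
      }
      mag <- sqrt(rowSums(matrix(sm, ncol = 3)^2))
      if (max(mag) > 0) sm <- sm * (spec$warp_amp_mm / max(mag))
      u <- u + sm
    }
    cand <- ddf(u, h, origin = c(0, 0, 0))
    if (min(jacobian_determinant(cand)$data) > 0) return(cand)
  }
  stop("no fold-free deformation found in ", spec$max_tries,
       " draws; reduce warp_amp_mm or the affine ranges")
}

# voxel-displacement field d with (id + u/h)(q + d(q)) = q  (fixed-point
# iteration on d(q) = -u(q + d(q))/h), tolerance in voxels
invert_displacement <- function(u, tol = 0.05, max_iter = 50) {
  shape <- ddf_grid_shape(u)
  idx <- grid_index(shape)
  uv <- u$disp
  for (cc in 1:3) uv[, , , cc] <- uv[, , , cc] / u$spacing[cc]
  d <- matrix(0, nrow(idx), 3)
  for (it in seq_len(max_iter)) {
    s <- cpp_resample3_fwd(uv, idx + d)
    dn <- -s
    if (max(abs(dn - d)) < tol) return(dn)
    d <- dn
  }
  d
}

render_us <- function(mk, noise_sd, spacing, shape) {
  I <- rep(0.15, length(mk$gland))
  I[mk$gland > 0] <- 0.55
  I[mk$inner > 0] <- 0.48
  # spurious bright interface at the inner-zone boundary (the structure that
  # defeats monotone intensity matching)
  f <- array(mk$inner, dim = shape)
  for (ax in 1:3) f <- apply_axis(f, gauss_matrix(shape[ax],
                                                  1 / spacing[ax], 3), ax)
  I <- I + 0.35 * as.numeric(4 * f * (1 - f))
  I[mk$urethra > 0] <- 0.25
  for (lm in mk$landmarks) I[lm > 0] <- 0.78
  I <- I * (1 + noise_sd * rnorm(length(I)))
  pmax(I, 0)
}

render_mr <- function(mk, noise_sd) {
  I <- rep(0.50, length(mk$gland))
  I[mk$gland > 0] <- 0.28
  I[mk$inner > 0] <- 0.72
  I[mk$urethra > 0] <- 0.62
  for (lm in mk$landmarks) I[lm > 0] <- 0.10
  I + noise_sd * rnorm(length(I))
}

#' Render the two modalities for one phantom case
#'
#' The fixed "US-like" image is rendered from the fixed-frame masks with
#' structure-dependent base intensities, a spurious bright interface at the
#' inner-zone boundary and multiplicative speckle-like noise.  The moving
#' "MR-like" image is rendered in the moving frame (the anatomy evaluated
#' analytically at inverse-mapped coordinates) with a different,
#' non-monotonically-related intensity mapping and additive noise.  Both
#' are normalised to zero mean / unit variance.
#'
#' @param anatomy output of \code{\link{make_anatomy}}.
#' @param u ground-truth \code{weakreg_ddf} from
#'   \code{\link{make_deformation}}.
#' @param spec a \code{\link{phantom_spec}}.
#' @return List with \code{moving}, \code{fixed} (intensity volumes) and
#'   \code{moving_masks} (binary moving-frame label volumes).
#' @export
render_modalities <- function(anatomy, u, spec) {
  shape <- spec$shape; h <- spec$spacing
  P_fix <- sweep(grid_index(shape), 2, h, "*")
  mk_fix <- anatomy_masks(anatomy$shapes, P_fix)
  d <- invert_displacement(u)
  P_mov <- sweep(grid_index(shape) + d, 2, h, "*")
  mk_mov <- anatomy_masks(anatomy$shapes, P_mov)
  vol <- function(v, lab = FALSE) {
    volume(array(v, dim = shape), h, origin = c(0, 0, 0), is_label = lab)
  }
  fixed <- normalize_intensities(vol(render_us(mk_fix, spec$noise_us, h,
                                               shape)))
  moving <- normalize_intensities(vol(render_mr(mk_mov, spec$noise_mr)))
  moving_masks <- c(
    list(gland = vol(mk_mov$gland, TRUE), inner = vol(mk_mov$inner, TRUE),
         urethra = vol(mk_mov$urethra, TRUE)),
    stats::setNames(lapply(mk_mov$landmarks, vol, lab = TRUE),
                    paste0("landmark_", seq_along(mk_mov$landmarks))))
  list(moving = moving, fixed = fixed, moving_masks = moving_masks)
}

phantom_case <- function(spec, case_id) {
  anat <- make_anatomy(spec)
  u <- make_deformation(spec)
  rm_ <- render_modalities(anat, u, spec)
  kinds <- c(gland = "gland", inner = "zonal", urethra = "urethra")
  lps <- lapply(names(anat$masks), function(nm) {
    kind <- if (nm %in% names(kinds)) kinds[[nm]] else "adhoc"
    list(moving = rm_$moving_masks[[nm]], fixed = anat$masks[[nm]],
         kind = kind)
  })
  registration_case(case_id, rm_$moving, rm_$fixed, lps,
                    ground_truth_ddf = u)
}

#' Generate phantom cases in memory
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_cases number of cases.
#' @param seed integer seed (R RNG).
#' @return List of \code{weakreg_case}s with ground-truth DDFs attached.
#' @export
generate_cases <- function(spec = phantom_spec(), n_cases = 16, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    phantom_case(spec, sprintf("phantom_%03d", i))
  })
}

#' Generate and write a phantom dataset
#'
#' Writes every case as NIfTI volumes (images, binary labels, ground-truth
#' DDF) plus a JSON manifest consumable by the training and evaluation
#' entry points.
#'
#' @inheritParams generate_cases
#' @param out_dir output directory (created if needed).
#' @return The manifest path, invisibly; the generated cases as attribute
#'   \code{"cases"}.
#' @export
generate_dataset <- function(spec = phantom_spec(), n_cases = 16,
                             out_dir = "phantom_data", seed = 1) {
  cases <- generate_cases(spec, n_cases, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cases, function(cs) {
    cdir <- cs$case_id
    dir.create(file.path(out_dir, cdir), showWarnings = FALSE)
    write_volume(cs$moving, file.path(out_dir, cdir, "moving.nii.gz"))
    write_volume(cs$fixed, file.path(out_dir, cdir, "fixed.nii.gz"))
    labs <- lapply(seq_along(cs$label_pairs), function(i) {
      lp <- cs$label_pairs[[i]]
      mp <- file.path(cdir, sprintf("label_%02d_moving.nii.gz", i))
      fp <- file.path(cdir, sprintf("label_%02d_fixed.nii.gz", i))
      write_volume(lp$moving, file.path(out_dir, mp))
      write_volume(lp$fixed, file.path(out_dir, fp))
      list(moving = mp, fixed = fp, kind = lp$kind)
    })
    write_ddf(cs$ground_truth_ddf,
              file.path(out_dir, cdir, "ground_truth_ddf.nii.gz"))
    list(case_id = cs$case_id,
         moving = file.path(cdir, "moving.nii.gz"),
         fixed = file.path(cdir, "fixed.nii.gz"),
         labels = labs,
         ground_truth_ddf = file.path(cdir, "ground_truth_ddf.nii.gz"))
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  structure(invisible(manifest), cases = cases)
}
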