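#' @useDynLib weakreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd median
NULL

#' Construct a volume
#'
#' A volume is a 3D scalar grid with voxel spacing and a world origin, the
#' basic container for intensity images, binary anatomical label masks and
#' (with 4D data) displacement fields.  World coordinates are
#' \code{origin + spacing * index} with 0-based indices, axes aligned, in mm.
#'
#' @param data 3D numeric array (intensities, or label values in [0,1]).
#' @param spacing voxel sizes in mm (length 3, all positive).
#' @param origin world position of voxel (0,0,0) in mm.
#' @param is_label logical; label masks are kept in [0,1] and re-binarised
#'   at 0.5 whenever they are stored or used for binary overlap.
#' @return An object of class \code{weakreg_volume}.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   is_label = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive voxel sizes (mm)")
  }
  if (is_label && (min(data) < -1e-6 || max(data) > 1 + 1e-6)) {
    stop("label volume values must lie in [0, 1]")
  }
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), is_label = isTRUE(is_label)),
            class = "weakreg_volume")
}

#' @export
print.weakreg_volume <- function(x, ...) {
  cat(sprintf("<weakreg_volume %s%s spacing [%s] mm, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"),
              if (x$is_label) " (label)" else "",
              paste(format(x$spacing), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a dense displacement field
#'
#' A DDF stores one 3-component displacement vector per voxel of the fixed
#' image grid, in mm, with backward (pull-back) semantics: the warped value
#' at fixed voxel p is sampled from the moving volume at world position
#' p + u(p).
#'
#' @param disp 4D numeric array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing fixed-grid voxel sizes in mm.
#' @param origin fixed-grid world origin in mm.
#' @return An object of class \code{weakreg_ddf}.
#' @export
ddf <- function(disp, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  disp <- as.array(disp)
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) stop("a DDF must be (nx, ny, nz, 3)")
  if (!all(is.finite(disp))) stop("a DDF must contain finite values only")
  structure(list(disp = disp, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "weakreg_ddf")
}

#' @export
print.weakreg_ddf <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$disp, ncol = 3)^2))
  cat(sprintf("<weakreg_ddf %s, |u| mean %.3g mm, max %.3g mm>\n",
              paste(dim(x$disp)[1:3], collapse = "x"), mean(m), max(m)))
  invisible(x)
}

ddf_grid_shape <- function(u) dim(u$disp)[1:3]

nifti_xform <- function(spacing, origin) {
  rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
}

#' Read / write volumes as NIfTI
#'
#' @param path path to a .nii or .nii.gz file.
#' @param is_label logical; if TRUE the data are rescaled to [0,1] (integer
#'   encodings such as 0/255 are divided by their maximum) and binarised at
#'   0.5.
#' @return \code{read_volume} returns a \code{weakreg_volume};
#'   \code{write_volume} returns \code{path} invisibly.
#' @export
read_volume <- function(path, is_label = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D volume in ", path, " (got ",
                            length(d), "D)")
  spacing <- abs(RNifti::pixdim(img)[1:3])
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  dat <- array(as.numeric(img), dim = d)
  if (is_label) {
    mx <- max(dat)
    if (min(dat) < 0) stop("label file ", path, " has negative values")
    if (mx > 1) dat <- dat / mx
    if (max(dat) > 1 + 1e-9) stop("label file ", path,
                                  " has values outside [0, 1] after scaling")
    dat <- (dat >= 0.5) + 0
    dim(dat) <- d
  }
  volume(dat, spacing = spacing, origin = origin, is_label = is_label)
}

#' @rdname read_volume
#' @param v a \code{weakreg_volume}.
#' @export
write_volume <- function(v, path) {
  dat <- v$data
  if (v$is_label) dat <- (dat >= 0.5) + 0
  dim(dat) <- dim(v$data)
  img <- RNifti::asNifti(structure(dat, pixdim = v$spacing,
                                   pixunits = c("mm", "s")))
  img <- RNifti::`qform<-`(img, structure(nifti_xform(v$spacing, v$origin),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a DDF as 4D NIfTI
#'
#' The field is stored as a 4D NIfTI with three components along the fourth
#' dimension, displacements in mm on the fixed-image grid.
#'
#' @param u a \code{weakreg_ddf}; \code{path} a .nii / .nii.gz path.
#' @return \code{read_ddf} returns a \code{weakreg_ddf}.
#' @export
write_ddf <- function(u, path) {
  img <- RNifti::asNifti(structure(u$disp, pixdim = c(u$spacing, 1),
                                   pixunits = c("mm", "s")))
  img <- RNifti::`qform<-`(img, structure(nifti_xform(u$spacing, u$origin),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ddf
#' @export
read_ddf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L) {
    stop("a DDF file must be 4D with 3 components, got dims [",
         paste(d, collapse = ", "), "] in ", path)
  }
  spacing <- abs(RNifti::pixdim(img)[1:3])
  origin <- RNifti::xform(img)[1:3, 4]
  ddf(array(as.numeric(img), dim = d), spacing = spacing, origin = origin)
}

#' Normalise intensities to zero mean and unit variance
#'
#' Uses the population standard deviation over all voxels; grid metadata is
#' unchanged.  Label volumes are rejected, as is a constant volume (zero
#' variance).
#'
#' @param v a \code{weakreg_volume} intensity image.
#' @return The normalised volume.
#' @export
normalize_intensities <- function(v) {
  if (v$is_label) stop("normalize_intensities expects an intensity volume")
  mu <- mean(v$data)
  s <- sqrt(mean((v$data - mu)^2))
  if (s < 1e-12) stop("degenerate input: constant volume has zero variance")
  volume((v$data - mu) / s, spacing = v$spacing, origin = v$origin)
}

#' Resample a volume to a target voxel spacing
#'
#' The output grid covers the same world extent, centre-aligned with the
#' source grid.  Intensities are interpolated trilinearly (zero outside the
#' source extent); labels are interpolated trilinearly and re-binarised at
#' 0.5.
#'
#' @param v a \code{weakreg_volume}.
#' @param target_spacing length-3 (or scalar) voxel size in mm.
#' @return The resampled volume.
#' @export
resample_to_grid <- function(v, target_spacing) {
  h2 <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(h2 <= 0)) stop("target_spacing must be positive")
  d <- dim(v$data)
  h <- v$spacing
  n2 <- pmax(1L, as.integer(round(d * h / h2)))
  # centre-aligned grids: world centres coincide
  o2 <- v$origin + 0.5 * (h * (d - 1) - h2 * (n2 - 1))
  idx <- as.matrix(expand.grid(x = seq_len(n2[1]) - 1,
                               y = seq_len(n2[2]) - 1,
                               z = seq_len(n2[3]) - 1))
  # continuous source voxel coordinates of the target voxel centres
  pos <- sweep(sweep(idx, 2, h2, "*"), 2, o2 - v$origin, "+")
  pos <- sweep(pos, 2, h, "/")
  f <- v$data
  dim(f) <- c(d, 1L)
  out <- cpp_resample3_fwd(f, pos)
  dat <- array(out[, 1], dim = n2)
  if (v$is_label) dat <- array((dat >= 0.5) + 0, dim = n2)
  volume(dat, spacing = h2, origin = o2, is_label = v$is_label)
}

#' Assemble a registration case
#'
#' A registration case is one moving/fixed image pair plus a variable-count
#' set of corresponding label-mask pairs (gland, apex/base, zonal, urethra or
#' ad-hoc landmarks).  Only the two intensity images are ever presented to a
#' network; labels feed the training loss and the evaluation metrics.
#'
#' @param case_id identifier string.
#' @param moving,fixed intensity \code{weakreg_volume}s on identical grids.
#' @param label_pairs list of \code{list(moving=, fixed=, kind=)} entries;
#'   kinds are one of \code{"gland"}, \code{"apex_base"}, \code{"zonal"},
#'   \code{"urethra"}, \code{"adhoc"}.
#' @param ground_truth_ddf optional \code{weakreg_ddf} (synthetic cases).
#' @return An object of class \code{weakreg_case}.
#' @export
registration_case <- function(case_id, moving, fixed, label_pairs = list(),
                              ground_truth_ddf = NULL) {
  kinds <- c("gland", "apex_base", "zonal", "urethra", "adhoc")
  if (!identical(dim(moving$data), dim(fixed$data))) {
    stop("moving and fixed images must share grid shape")
  }
  for (lp in label_pairs) {
    if (!lp$kind %in% kinds) stop("unknown label kind: ", lp$kind)
    if (!identical(dim(lp$moving$data), dim(moving$data)) ||
        !identical(dim(lp$fixed$data), dim(fixed$data))) {
      stop("label grids must match their parent image grids")
    }
  }
  structure(list(case_id = as.character(case_id), moving = moving,
                 fixed = fixed, label_pairs = label_pairs,
                 ground_truth_ddf = ground_truth_ddf),
            class = "weakreg_case")
}

#' @export
print.weakreg_case <- function(x, ...) {
  cat(sprintf("<weakreg_case '%s': %s grid, %d label pair(s)%s>\n",
              x$case_id, paste(dim(x$fixed$data), collapse = "x"),
              length(x$label_pairs),
              if (is.null(x$ground_truth_ddf)) "" else ", ground truth DDF"))
  invisible(x)
}

#' Load one case from a manifest record
#'
#' @param entry a manifest record: named list with \code{case_id},
#'   \code{moving}, \code{fixed}, optional \code{labels} (each with
#'   \code{moving}, \code{fixed}, \code{kind}) and optional
#'   \code{ground_truth_ddf}, all paths relative to \code{base_dir}.
#' @param base_dir directory against which relative paths are resolved.
#' @return A \code{weakreg_case}.
#' @export
load_case <- function(entry, base_dir = ".") {
  rp <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  mov <- read_volume(rp(entry$moving))
  fix <- read_volume(rp(entry$fixed))
  lps <- lapply(entry$labels, function(l) {
    list(moving = read_volume(rp(l$moving), is_label = TRUE),
         fixed = read_volume(rp(l$fixed), is_label = TRUE),
         kind = l$kind)
  })
  gt <- if (!is.null(entry$ground_truth_ddf)) read_ddf(rp(entry$ground_truth_ddf))
  registration_case(entry$case_id, mov, fix, lps, ground_truth_ddf = gt)
}

#' Load a dataset manifest
#'
#' The manifest is a JSON array of case records (see \code{\link{load_case}}).
#'
#' @param path manifest JSON path.
#' @return List of \code{weakreg_case} objects.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  entries <- jsonlite::read_json(path)
  lapply(entries, load_case, base_dir = dirname(path))
}
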