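# Registration quality metrics: landmark-centroid TRE, gland Dice, DDF
# diagnostics, and run-level summaries in the median / [10th, 25th, 75th,
# 90th] percentile layout.

label_centroid <- function(lab, spacing, origin) {
  a <- label_field(lab)
  tot <- sum(a)
  if (tot <= 0) return(NULL)
  idx <- grid_index(dim(a))
  w <- as.numeric(a) / tot
  sweep(matrix(colSums(idx * w), 1), 2, spacing, "*")[1, ] + origin
}

#' Centroid distance between two label fields
#'
#' Euclidean distance in world mm between the intensity-weighted centres of
#' mass; fractional (warped) label values are used as weights, avoiding
#' re-binarisation jitter on small landmarks.
#'
#' @param warped_label,fixed_label \code{weakreg_volume}s on the same grid.
#' @return Distance in mm, or NA (with a warning) if either label has zero
#'   total mass.
#' @export
centroid_distance <- function(warped_label, fixed_label) {
  c1 <- label_centroid(warped_label, warped_label$spacing, warped_label$origin)
  c2 <- label_centroid(fixed_label, fixed_label$spacing, fixed_label$origin)
  if (is.null(c1) || is.null(c2)) {
    warning("label with zero total mass; centroid distance is missing")
    return(NA_real_)
  }
  sqrt(sum((c1 - c2)^2))
}

#' Per-case target registration error
#'
#' Warps every moving landmark label of the case by \code{u} and returns the
#' root-mean-square of the centroid distances to the fixed counterparts, in
#' mm.  Gland pairs are excluded by default (the gland is scored by Dice,
#' TRE by the landmark centroids); labels that vanish after warping are
#' excluded with a warning.
#'
#' @param case a \code{weakreg_case}.
#' @param u a \code{weakreg_ddf}.
#' @param include_gland include gland pairs in the RMS.
#' @return TRE in mm (NA if no usable landmark pair).
#' @export
case_tre <- function(case, u, include_gland = FALSE) {
  d2 <- c()
  for (lp in case$label_pairs) {
    if (!include_gland && lp$kind == "gland") next
    w <- warp_volume(lp$moving, u, mode = "linear")
    dd <- centroid_distance(w, lp$fixed)
    if (!is.na(dd)) d2 <- c(d2, dd^2)
  }
  if (length(d2) == 0) {
    warning("case ", case$case_id, ": no usable landmark pair for TRE")
    return(NA_real_)
  }
  sqrt(mean(d2))
}

#' Gland Dice similarity coefficient
#'
#' Binary Dice 2|A n B| / (|A| + |B|) between the warped moving gland
#' (re-binarised at 0.5) and the fixed gland.
#'
#' @inheritParams case_tre
#' @return DSC in [0,1] (NA if the case has no gland pair).
#' @export
gland_dsc <- function(case, u) {
  gi <- which(vapply(case$label_pairs, function(lp) lp$kind == "gland",
                     logical(1)))
  if (length(gi) == 0) return(NA_real_)
  lp <- case$label_pairs[[gi[1]]]
  w <- warp_volume(lp$moving, u, mode = "linear")
  a <- (w$data >= 0.5)
  b <- (lp$fixed$data >= 0.5)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Percentile summary in the reporting layout
#'
#' Median plus the 10th, 25th, 75th and 90th percentiles, computed with
#' linear interpolation between closest ranks (R's default quantile type 7).
#'
#' @param x numeric vector (NAs dropped).
#' @return Named numeric vector.
#' @export
percentile_summary <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, probs = c(0.5, 0.1, 0.25, 0.75, 0.9), type = 7,
                names = FALSE)
  c(median = q[1], p10 = q[2], p25 = q[3], p75 = q[4], p90 = q[5])
}

#' Evaluate a network over held-out cases
#'
#' Predicts a DDF per case from the image pair alone, then computes per-case
#' TRE (landmark centroids) and gland DSC, plus DDF diagnostics (Jacobian
#' determinants, displacement magnitudes, gradient norms, folding counts),
#' and run-level median / percentile summaries.
#'
#' @param cases list of \code{weakreg_case}s.
#' @param net a \code{weakreg_network} (or NULL to evaluate the identity /
#'   zero-DDF alignment, i.e. the untrained reference).
#' @param out_dir optional directory: writes per-case CSV and a summary
#'   JSON.
#' @return List of class \code{weakreg_evalreport} with \code{per_case}
#'   (data frame), \code{tre_summary}, \code{dsc_summary} and
#'   \code{ddf_diagnostics}.
#' @export
evaluate_run <- function(cases, net = NULL, out_dir = NULL) {
  if (length(cases) == 0) stop("need at least one case")
  rows <- lapply(cases, function(cs) {
    u <- if (is.null(net)) {
      ddf(array(0, dim = c(dim(cs$fixed$data), 3L)), cs$fixed$spacing,
          cs$fixed$origin)
    } else {
      predict_ddf(net, cs$moving, cs$fixed)$ddf
    }
    st <- ddf_statistics(u)
    data.frame(case_id = cs$case_id,
               tre_mm = case_tre(cs, u),
               dsc = gland_dsc(cs, u),
               n_landmarks = sum(vapply(cs$label_pairs,
                                        function(lp) lp$kind != "gland",
                                        logical(1))),
               disp_mag_mean = st$magnitude_summary["mean"],
               grad_norm_mean = st$gradient_norm_summary["mean"],
               grad_norm_sd = st$gradient_norm_summary["sd"],
               jac_min = st$jacobian_summary["min"],
               n_nonpos_jac = st$n_nonpositive_jacobian,
               frac_nonpos_jac = st$frac_nonpositive_jacobian)
  })
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  rep <- structure(
    list(per_case = per_case,
         tre_summary = percentile_summary(per_case$tre_mm),
         dsc_summary = percentile_summary(per_case$dsc),
         ddf_diagnostics = list(
           disp_mag_mean = mean(per_case$disp_mag_mean),
           grad_norm_mean = mean(per_case$grad_norm_mean),
           grad_norm_sd = mean(per_case$grad_norm_sd),
           n_nonpositive_jacobian = sum(per_case$n_nonpos_jac),
           frac_nonpositive_jacobian = mean(per_case$frac_nonpos_jac))),
    class = "weakreg_evalreport")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_case, file.path(out_dir, "per_case.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(tre_summary = as.list(rep$tre_summary),
           dsc_summary = as.list(rep$dsc_summary),
           ddf_diagnostics = rep$ddf_diagnostics),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.weakreg_evalreport <- function(x, ...) {
  cat(sprintf("<weakreg_evalreport: %d case(s)>\n", nrow(x$per_case)))
  cat(sprintf("  TRE mm  median %.2f, percentiles [%.2f, %.2f, %.2f, %.2f]\n",
              x$tre_summary["median"], x$tre_summary["p10"],
              x$tre_summary["p25"], x$tre_summary["p75"],
              x$tre_summary["p90"]))
  cat(sprintf("  DSC     median %.3f, percentiles [%.3f, %.3f, %.3f, %.3f]\n",
              x$dsc_summary["median"], x$dsc_summary["p10"],
              x$dsc_summary["p25"], x$dsc_summary["p75"],
              x$dsc_summary["p90"]))
  cat(sprintf("  folding voxels: %d (fraction %.4g)\n",
              x$ddf_diagnostics$n_nonpositive_jacobian,
              x$ddf_diagnostics$frac_nonpositive_jacobian))
  invisible(x)
}
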