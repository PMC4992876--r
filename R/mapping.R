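# Voxelwise parametric mapping: Patlak Ki maps over the whole body and
# compartmental k3 maps restricted to the tumour, plus map/tumour overlap and
# contrast summaries.

#' Parametric map constructor
#'
#' @param values 3D array of parameter values; invalid voxels carry NA.
#' @param valid Logical 3D array marking voxels whose estimate succeeded.
#' @param parameter Parameter tag, e.g. \code{"Ki"} or \code{"k3"}.
#' @param units Unit string.
#' @return An object of class \code{parametric_map}.
#' @export
parametric_map <- function(values, valid, parameter, units) {
  fp_assert(is.array(values) && length(dim(values)) == 3L, "format",
            "values must be a 3D array")
  fp_assert(identical(dim(values), dim(valid)), "grid",
            "valid mask must match the value grid")
  structure(list(values = values, valid = valid,
                 parameter = parameter, units = units),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<parametric_map> %s [%s], %d valid voxels, median %.4g\n",
              x$parameter, x$units, sum(x$valid),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}

#' Voxelwise Patlak Ki map
#'
#' Per-voxel Patlak regression of the voxel TAC against the driver curve
#' (plasma input function, or a reference-tissue TAC for whole-body mapping).
#' Negative slopes are clamped to 0; voxels with too few valid points or
#' non-finite regressions are marked invalid rather than failing globally.
#'
#' @param image4d 4D dynamic image.
#' @param driver An \code{\link{input_function}} or a reference
#'   \code{\link{tac}}.
#' @param schedule Acquisition \code{\link{frame_schedule}}.
#' @param body_mask Optional logical 3D mask restricting the computation
#'   (default: whole grid).
#' @param t_star Patlak linearity onset in minutes (default 30).
#' @param clamp_negative Clamp negative slopes to 0 (default TRUE).
#' @return A \code{\link{parametric_map}} of Ki (mL/g/min).
#' @export
ki_map <- function(image4d, driver, schedule, body_mask = NULL,
                   t_star = 30, clamp_negative = TRUE) {
  fp_assert(is.array(image4d) && length(dim(image4d)) == 4L, "format",
            "image4d must be a 4D array")
  dm <- dim(image4d)
  fp_assert(dm[4] == n_frames(schedule), "consistency",
            "frame count mismatch between image and schedule")
  if (inherits(driver, "tac")) driver <- as_input_function(driver)
  stopifnot(inherits(driver, "input_function"))
  if (is.null(body_mask)) body_mask <- array(TRUE, dm[1:3])
  fp_assert(any(body_mask), "empty_roi", "body mask selects no voxels")

  mids <- frame_midpoints(schedule)
  cpt <- eval_input(driver, mids)
  cum <- input_cumint(driver, mids)
  sel <- cpt > 0.01 * max(driver$values) & mids >= t_star * 60
  fp_assert(sum(sel) >= 3, "insufficient_points",
            "fewer than 3 usable frames at t >= %g min", t_star)
  x <- (cum / cpt / 60)[sel]
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  vox <- which(body_mask)
  mat <- matrix(image4d, ncol = dm[4])[vox, sel, drop = FALSE]
  Y <- sweep(mat, 2, cpt[sel], "/")
  slope <- as.numeric(Y %*% xc) / sxx
  ok <- is.finite(slope)
  if (clamp_negative) slope <- pmax(slope, 0)

  values <- array(NA_real_, dm[1:3])
  valid <- array(FALSE, dm[1:3])
  values[vox] <- ifelse(ok, slope, NA_real_)
  valid[vox] <- ok
  parametric_map(values, valid, "Ki", "mL/g/min")
}

#' Voxelwise k3 map from compartmental fits
#'
#' Fits the irreversible two-tissue model to every tumour voxel's TAC and
#' extracts the specific trapping rate k3. The whole-ROI fit is used as a
#' warm start for the voxel fits (cuts non-convergence and run time);
#' non-converged voxels are marked invalid.
#'
#' @param image4d 4D dynamic image.
#' @param cp Plasma \code{\link{input_function}}.
#' @param tumor_mask Logical 3D tumour mask (non-empty).
#' @param schedule Acquisition \code{\link{frame_schedule}}.
#' @param cfg A \code{\link{fit_config}} for the voxel fits. The default
#'   pins the diffusive-compartment weight at the package's reference tissue
#'   composition (\code{wd = 0.60}) because the weighted model with wd free
#'   is structurally non-identifiable -- voxelwise k3 values would be
#'   arbitrary points on a flat likelihood manifold (see the methods
#'   vignette); restarts are triggered only on non-convergence.
#' @param warm_start Use the ROI fit as initialisation (default TRUE).
#' @return A \code{\link{parametric_map}} of k3 (1/min).
#' @export
k3_map <- function(image4d, cp, tumor_mask, schedule, cfg = NULL,
                   warm_start = TRUE) {
  fp_assert(is.array(image4d) && length(dim(image4d)) == 4L, "format",
            "image4d must be a 4D array")
  dm <- dim(image4d)
  fp_assert(identical(dim(tumor_mask), dm[1:3]), "grid",
            "tumour mask grid mismatch")
  fp_assert(any(tumor_mask), "empty_roi", "tumour mask selects no voxels")
  if (is.null(cfg))
    cfg <- fit_config("irreversible", fixed = c(wd = 0.60),
                      restarts = 2, restart_epsilon = Inf, max_iter = 150)
  fp_assert(cfg$model == "irreversible", "invalid_spec",
            "the k3 map is defined on the irreversible model")

  if (warm_start) {
    roi_tac <- extract_tac(image4d, tumor_mask, schedule)
    roi_fit <- tryCatch(fit_tac(roi_tac, cp, cfg), fmisopet_error = function(e) NULL)
    if (!is.null(roi_fit)) {
      p <- roi_fit$params
      cfg <- utils::modifyList(cfg, list(
        init = stats::setNames(
          pmax(c(p$K1, p$k2, p$k3, p$wp, p$wd), 1e-4),
          c("K1", "k2", "k3", "wp", "wd"))[cfg$pnames]))
      class(cfg) <- "fit_config"
    }
  }

  vox <- which(tumor_mask)
  mat <- matrix(image4d, ncol = dm[4])
  values <- array(NA_real_, dm[1:3])
  valid <- array(FALSE, dm[1:3])
  for (v in vox) {
    res <- tryCatch({
      tv <- tac(schedule, mat[v, ], allow_negative = TRUE)
      fit <- fit_tac(tv, cp, cfg)
      if (fit$converged) fit$params$k3 else NA_real_
    }, fmisopet_error = function(e) NA_real_)
    if (is.finite(res)) {
      values[v] <- res
      valid[v] <- TRUE
    }
  }
  parametric_map(values, valid, "k3", "1/min")
}

#' Fraction of the tumour volume above a map level
#'
#' The "map volume" relative to the tumour volume: the percentage of tumour
#' voxels whose (valid) map value reaches \code{level}.
#'
#' @param pmap A \code{\link{parametric_map}}.
#' @param tumor_mask Logical 3D tumour mask (non-empty).
#' @param level Threshold in map units.
#' @return Percentage in [0, 100].
#' @export
map_positive_fraction <- function(pmap, tumor_mask, level) {
  stopifnot(inherits(pmap, "parametric_map"))
  fp_assert(identical(dim(pmap$values), dim(tumor_mask)), "grid",
            "tumour mask grid mismatch")
  fp_assert(any(tumor_mask), "empty_roi", "tumour mask selects no voxels")
  hit <- tumor_mask & pmap$valid & !is.na(pmap$values) & pmap$values >= level
  100 * sum(hit) / sum(tumor_mask)
}

#' Default map threshold level
#'
#' The display/overlap threshold defining the "map volume": a fraction
#' (default 20\%) of the within-tumour maximum of the valid map values.
#'
#' @param pmap A \code{\link{parametric_map}}.
#' @param tumor_mask Logical tumour mask.
#' @param frac Fraction of the within-tumour maximum (default 0.2).
#' @export
map_level <- function(pmap, tumor_mask, frac = 0.2) {
  stopifnot(inherits(pmap, "parametric_map"))
  v <- pmap$values[tumor_mask & pmap$valid]
  fp_assert(length(v) > 0, "empty_roi", "no valid map voxels in the tumour")
  frac * max(v)
}

#' Tumour-to-background contrast ratio
#'
#' Mean over the tumour voxels divided by the mean over the background
#' voxels; accepts either a plain 3D array (e.g. a late frame) or a
#' \code{\link{parametric_map}} (invalid voxels excluded).
#'
#' @param volume 3D array or \code{parametric_map}.
#' @param tumor_mask,background_mask Logical 3D masks.
#' @return Unitless ratio.
#' @export
contrast_ratio <- function(volume, tumor_mask, background_mask) {
  if (inherits(volume, "parametric_map")) {
    vals <- volume$values
    ok <- volume$valid
  } else {
    fp_assert(is.array(volume) && length(dim(volume)) == 3L, "format",
              "volume must be a 3D array or parametric_map")
    vals <- volume
    ok <- array(TRUE, dim(volume))
  }
  fp_assert(any(tumor_mask & ok) && any(background_mask & ok), "empty_roi",
            "masks select no valid voxels")
  tm <- mean(vals[tumor_mask & ok])
  bg <- mean(vals[background_mask & ok])
  fp_assert(is.finite(bg) && bg > 0, "invalid_background",
            "background mean must be > 0 (got %g)", bg)
  tm / bg
}
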