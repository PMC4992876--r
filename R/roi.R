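# ROI definition by thresholding, TAC extraction from 4D images, and the
# static tumour-to-blood hypoxia criterion.
#
# Images are plain R arrays: 3D (x, y, z) volumes or 4D (x, y, z, frame)
# dynamic series, with physical voxel spacing carried in the "pixdim"
# attribute (mm). Masks are logical 3D arrays on the same grid.

#' Threshold-based region of interest
#'
#' Selects voxels within a bounding box whose intensity is at least
#' \code{frac} of the in-box maximum (the conventional way to delineate the
#' metabolically active tumour and exclude necrotic regions), then keeps the
#' largest 6-connected component to suppress speckle.
#'
#' @param volume 3D numeric array.
#' @param seed_box Optional bounding box \code{list(lo = c(i, j, k), hi =
#'   c(i, j, k))} (1-based, inclusive); default is the whole grid.
#' @param frac Threshold as a fraction of the in-box maximum, in (0, 1).
#' @param keep_largest Keep only the largest connected component (default
#'   TRUE).
#' @return A logical 3D mask (class \code{region_mask}) with attributes
#'   \code{label} and \code{pixdim}.
#' @export
threshold_roi <- function(volume, seed_box = NULL, frac = 0.5,
                          keep_largest = TRUE) {
  fp_assert(is.array(volume) && length(dim(volume)) == 3L, "format",
            "volume must be a 3D array")
  fp_assert(is_scalar_num(frac) && frac > 0 && frac < 1, "invalid_spec",
            "frac must lie in (0, 1)")
  dm <- dim(volume)
  if (is.null(seed_box)) seed_box <- list(lo = c(1L, 1L, 1L), hi = dm)
  lo <- as.integer(seed_box$lo); hi <- as.integer(seed_box$hi)
  fp_assert(length(lo) == 3L && length(hi) == 3L && all(lo >= 1L) &&
              all(hi <= dm) && all(lo <= hi), "invalid_spec",
            "seed_box must lie within the image grid")
  inbox <- array(FALSE, dm)
  inbox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  thr <- frac * max(volume[inbox])
  mask <- inbox & (volume >= thr)
  if (keep_largest && any(mask)) mask <- largest_component(mask)
  fp_assert(any(mask), "empty_roi", "threshold produced an empty ROI")
  structure(mask, class = c("region_mask", class(mask)),
            label = "threshold_roi", pixdim = attr(volume, "pixdim"))
}

# Largest 6-connected component of a logical 3D array. Flood fill on linear
# indices with an explicit stack; border effects handled by index arithmetic
# guards.
largest_component <- function(mask) {
  dm <- dim(mask)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  lab <- integer(length(mask))
  seeds <- which(mask)
  sizes <- integer(0)
  comp <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    stack <- s
    lab[s] <- comp
    size <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      v0 <- v - 1L
      i <- v0 %% nx
      j <- (v0 %/% nx) %% ny
      k <- v0 %/% (nx * ny)
      nbrs <- c(if (i > 0L) v - 1L, if (i < nx - 1L) v + 1L,
                if (j > 0L) v - nx, if (j < ny - 1L) v + nx,
                if (k > 0L) v - nx * ny, if (k < nz - 1L) v + nx * ny)
      nbrs <- nbrs[mask[nbrs] & lab[nbrs] == 0L]
      if (length(nbrs)) {
        lab[nbrs] <- comp
        stack <- c(stack, nbrs)
      }
    }
    sizes[comp] <- size
  }
  array(lab == which.max(sizes), dm)
}

#' Extract a region TAC from a 4D dynamic image
#'
#' Per-frame mean over the mask voxels, the standard ROI TAC definition.
#'
#' @param image4d 4D numeric array (x, y, z, frame).
#' @param mask Logical 3D mask on the same spatial grid (non-empty).
#' @param schedule The acquisition \code{\link{frame_schedule}} (frame count
#'   must match the image).
#' @return A \code{\link{tac}} (negative noisy means permitted).
#' @export
extract_tac <- function(image4d, mask, schedule) {
  fp_assert(is.array(image4d) && length(dim(image4d)) == 4L, "format",
            "image4d must be a 4D array")
  dm <- dim(image4d)
  fp_assert(identical(dim(mask), dm[1:3]), "grid",
            "mask grid does not match the image grid")
  fp_assert(any(mask), "empty_roi", "mask selects no voxels")
  fp_assert(dm[4] == n_frames(schedule), "consistency",
            "image has %d frames but schedule %d", dm[4], n_frames(schedule))
  vox <- which(mask)
  mat <- matrix(image4d, ncol = dm[4])
  vals <- colMeans(mat[vox, , drop = FALSE])
  tac(schedule, vals, unit = "Bq/mL", allow_negative = TRUE)
}

#' Image-derived left-ventricle input function
#'
#' Defines the blood-pool ROI by thresholding the duration-weighted mean of
#' the frames fully inside the first minute (the bolus makes the left
#' ventricle the hottest early structure) and returns that region's TAC,
#' promoted to a plasma \code{\link{input_function}}.
#'
#' @param image4d 4D dynamic image.
#' @param schedule Acquisition \code{\link{frame_schedule}}; at least one
#'   frame must end within the first 60 s.
#' @param frac Threshold fraction for the blood-pool ROI (default 0.5).
#' @return An \code{\link{input_function}} with the blood mask attached as
#'   attribute \code{"mask"} and the raw TAC as attribute \code{"tac"}.
#' @export
lv_input_function <- function(image4d, schedule, frac = 0.5) {
  fp_assert(is.array(image4d) && length(dim(image4d)) == 4L, "format",
            "image4d must be a 4D array")
  early <- which(schedule$frame_end <= 60 + 1e-9)
  fp_assert(length(early) >= 1L, "invalid_spec",
            "no frame lies fully inside the first 60 s")
  durs <- frame_durations(schedule)[early]
  sub <- image4d[, , , early, drop = FALSE]
  wsum <- array(0, dim(image4d)[1:3])
  for (i in seq_along(early)) wsum <- wsum + sub[, , , i] * durs[i]
  mean_early <- wsum / sum(durs)
  mask <- threshold_roi(mean_early, frac = frac)
  blood <- extract_tac(image4d, mask, schedule)
  cp <- as_input_function(blood)
  attr(cp, "mask") <- mask
  attr(cp, "tac") <- blood
  cp
}

#' Static uptake summary and hypoxia call
#'
#' Tumour-to-blood activity ratio with the conventional hypoxia criterion:
#' a region is scored hypoxic when T/B exceeds 1.2 (strictly).
#'
#' @param tumor_mean Mean tumour uptake (\%ID/g).
#' @param blood_mean Mean blood (heart) uptake (\%ID/g), > 0.
#' @param cutoff Hypoxia threshold on T/B (default 1.2).
#' @param n_voxels Optional voxel count of the tumour ROI.
#' @return An object of class \code{roi_summary}: \code{mean_uptake},
#'   \code{tb_ratio}, \code{hypoxic}, \code{n_voxels}.
#' @examples
#' static_summary(1.92, 0.65)  # T/B ~ 3, hypoxic
#' static_summary(0.75, 0.82)  # T/B ~ 0.9, not hypoxic
#' @export
static_summary <- function(tumor_mean, blood_mean, cutoff = 1.2,
                           n_voxels = NA_integer_) {
  fp_assert(is_scalar_num(tumor_mean) && tumor_mean >= 0, "invalid_spec",
            "tumor_mean must be >= 0")
  fp_assert(is_scalar_num(blood_mean) && blood_mean > 0, "invalid_blood",
            "blood_mean must be > 0")
  tb <- tumor_mean / blood_mean
  structure(list(mean_uptake = tumor_mean, tb_ratio = tb,
                 hypoxic = tb > cutoff, cutoff = cutoff,
                 n_voxels = n_voxels),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> uptake %.3g %%ID/g, T/B = %.3g -> %s\n",
              x$mean_uptake, x$tb_ratio,
              if (x$hypoxic) "hypoxic" else "not hypoxic"))
  invisible(x)
}
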