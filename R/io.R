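# Image IO (NIfTI) and provenance records.

#' Read a 4D dynamic image
#'
#' @param path Path to a 3D/4D NIfTI file; only 4D is accepted here.
#' @return 4D numeric array with voxel spacing (mm) in attribute
#'   \code{"pixdim"}.
#' @export
read_image4d <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  fp_assert(length(dim(arr)) == 4L, "format",
            "expected a 4D image, got %dD", length(dim(arr)))
  pd <- RNifti::pixdim(img)
  attributes(arr) <- list(dim = dim(arr), pixdim = pd[seq_len(3)])
  arr
}

#' Read a 3D volume or mask
#'
#' @param path Path to a 3D NIfTI file.
#' @param logical Coerce to a logical mask (values > 0).
#' @return 3D array (logical if \code{logical = TRUE}).
#' @export
read_image3d <- function(path, logical = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  fp_assert(length(dim(arr)) == 3L, "format",
            "expected a 3D image, got %dD", length(dim(arr)))
  pd <- RNifti::pixdim(img)
  attributes(arr) <- list(dim = dim(arr), pixdim = pd[seq_len(3)])
  if (logical) arr > 0 else arr
}

#' Write a volume or dynamic image as NIfTI
#'
#' Data are stored as float32; masks and parametric maps pass through this
#' too (invalid map voxels are written as the \code{sentinel}).
#'
#' @param volume 3D/4D array, logical mask, or \code{parametric_map}.
#' @param path Output path (.nii or .nii.gz).
#' @param sentinel Value written at invalid map voxels (default -1).
#' @export
write_image <- function(volume, path, sentinel = -1) {
  if (inherits(volume, "parametric_map")) {
    v <- volume$values
    v[!volume$valid | is.na(v)] <- sentinel
    volume <- v
  }
  if (is.logical(volume)) volume <- array(as.numeric(volume), dim(volume))
  pd <- attr(volume, "pixdim")
  arr <- array(as.numeric(volume), dim(volume))
  if (!is.null(pd))
    attr(arr, "pixdim") <- c(pd, rep(1, max(0, length(dim(arr)) - length(pd))))
  RNifti::writeNifti(arr, path, datatype = "float")
  invisible(path)
}

#' Check image / schedule consistency
#'
#' @param image4d 4D array.
#' @param schedule A \code{frame_schedule}.
#' @export
check_frames <- function(image4d, schedule) {
  fp_assert(is.array(image4d) && length(dim(image4d)) == 4L, "format",
            "image4d must be a 4D array")
  fp_assert(dim(image4d)[4] == n_frames(schedule), "consistency",
            "image has %d frames but the schedule %d",
            dim(image4d)[4], n_frames(schedule))
  invisible(TRUE)
}

# JSON provenance record: enough to re-run the stage from scratch.
write_provenance <- function(outdir, command, args, seed = NULL) {
  rec <- list(command = command, args = args, seed = seed,
              package = "fmisopet",
              version = as.character(utils::packageVersion("fmisopet")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(rec, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec)
}
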