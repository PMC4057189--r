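#' Automatic lung segmentation by thresholding
#'
#' Threshold-based lung boundary extraction intended for high-contrast
#' (well-aerated) lungs: voxels below `threshold_hu` are taken as
#' candidate lung, connected components (6-connectivity) touching the
#' volume border are removed as exterior air, components smaller than
#' `min_volume_ml` are discarded, and the union of the survivors is
#' regularised by morphological closing and interior hole filling (so
#' isolated dense voxels inside the lung are recovered).
#'
#' Consolidated lungs have CT numbers close to the surrounding soft
#' tissue and cannot be delimited by a threshold; when more than
#' `warn_dense_fraction` of the returned mask lies above -500 HU the
#' function warns that a manually drawn mask should be used instead.
#'
#' @param ct A [ct_volume()] in HU.
#' @param threshold_hu Upper HU bound for candidate lung voxels
#'   (default -200).
#' @param min_volume_ml Minimum connected-component volume retained, ml.
#' @param closing_iter Iterations of 6-neighbourhood morphological closing.
#' @param warn_dense_fraction Warn when this fraction of the mask measures
#'   above -500 HU.
#' @return A [lung_mask()] with `source = "auto"`.
#' @export
segment_lungs_auto <- function(ct, threshold_hu = -200, min_volume_ml = 50,
                               closing_iter = 1L, warn_dense_fraction = 0.25) {
  stopifnot(inherits(ct, "ct_volume"))
  cand <- ct$data < threshold_hu
  cc <- label_components(cand)
  vox_ml <- prod(ct$spacing) / 1000
  keep <- which(!cc$touches_border & cc$sizes * vox_ml >= min_volume_ml)
  if (length(keep) == 0L) {
    stop("no lung found: no interior component of at least ", min_volume_ml,
         " ml below ", threshold_hu, " HU")
  }
  mask <- array(cc$labels %in% keep, dim(cand))
  mask <- closing3(mask, closing_iter)
  mask <- fill_holes3(mask)
  dense <- mean(ct$data[mask] > -500)
  if (dense > warn_dense_fraction) {
    warning(sprintf(
      paste("%.0f%% of the segmented region measures above -500 HU:",
            "threshold segmentation is unreliable for poorly aerated or",
            "consolidated lungs; supply a manually drawn mask instead"),
      100 * dense))
  }
  lung_mask(mask, ct$spacing, source = "auto")
}

#' Read and validate an externally drawn lung mask
#'
#' Loads a binary mask from a NIfTI file and checks that it is nonempty
#' and aligned (grid shape and voxel spacing) with the CT volume it is
#' meant for.
#'
#' @param path Path to a NIfTI mask (values 0/1).
#' @param ct The [ct_volume()] the mask belongs to.
#' @return A [lung_mask()] with `source = "manual"`.
#' @export
load_mask <- function(path, ct) {
  vol <- load_volume(path)
  m <- lung_mask(vol$data != 0, vol$spacing, source = "manual")
  check_aligned(ct, m)
  if (!any(m$mask)) stop("mask at ", path, " is empty")
  m
}

#' Write a lung mask as uint8 NIfTI
#'
#' @param mask A [lung_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  im <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(im) <- mask$spacing
  RNifti::writeNifti(im, path, datatype = "uint8")
  invisible(path)
}
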