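#' CT volume container
#'
#' Bundle a 3-D array of Hounsfield units with its voxel spacing and the
#' acquisition settings that produced it. This is the unit of analysis for
#' all densitometry functions.
#'
#' @param data 3-D numeric array of CT numbers in Hounsfield units (HU).
#' @param spacing Numeric length-3, voxel spacing in mm per axis
#'   (strictly positive).
#' @param mAs Tube current-time product used for the acquisition, or `NULL`
#'   when unknown / noise-free.
#' @param sigma_hu Standard deviation of the injected noise in HU, recorded
#'   by [simulate_scan()]; `NULL` for measured or noise-free volumes.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, mAs = NULL, sigma_hu = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array of HU values")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel dimensions in mm")
  }
  if (!is.null(mAs) && (!is.numeric(mAs) || mAs <= 0)) {
    stop("`mAs` must be a positive number")
  }
  structure(
    list(data = data, spacing = spacing, mAs = mAs, sigma_hu = sigma_hu),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", paste(dim(x$data), collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  if (!is.null(x$mAs)) cat("  acquired at", x$mAs, "mAs\n")
  cat("  HU range:", paste(signif(range(x$data), 4), collapse = " to "), "\n")
  invisible(x)
}

#' Lung mask container
#'
#' A binary region of interest aligned to a [ct_volume()]. Masks come from
#' automatic segmentation ([segment_lungs_auto()]), from files drawn
#' manually in external software, or from phantom ground truth.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing Voxel spacing in mm per axis, matching the CT volume.
#' @param source One of `"auto"`, `"manual"`, `"truth"`.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(mask, spacing, source = c("manual", "auto", "truth")) {
  source <- match.arg(source)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a 3-D array")
  }
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop("`mask` contains values that are not 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive voxel dimensions in mm")
  }
  structure(list(mask = mask, spacing = spacing, source = source),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  vol_ml <- sum(x$mask) * prod(x$spacing) / 1000
  cat("Lung mask (", x$source, "): ", sum(x$mask), " voxels, ",
      round(vol_ml, 1), " ml\n", sep = "")
  invisible(x)
}

# check that a mask is aligned with a CT volume
check_aligned <- function(ct, mask) {
  if (!identical(dim(ct$data), dim(mask$mask))) {
    stop("CT volume and mask have different grid shapes")
  }
  if (max(abs(ct$spacing - mask$spacing)) > 1e-6) {
    stop("CT volume and mask have different voxel spacings")
  }
  invisible(TRUE)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b `lung_mask` objects or logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "lung_mask")) a <- a$mask
  if (inherits(b, "lung_mask")) b <- b$mask
  if (!identical(dim(a), dim(b))) stop("masks have different shapes")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
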