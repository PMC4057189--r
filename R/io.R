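#' Read a CT volume from NIfTI
#'
#' Reads a 3-D NIfTI volume of CT numbers (HU) and its voxel spacing from
#' the header. Spacing must be present and strictly positive; a missing or
#' degenerate spacing is an error, never a silent default. If a JSON
#' sidecar `<path>.json` exists, acquisition metadata (`mAs`, `sigma_hu`)
#' is restored from it.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unsupported format: ", path, " (NIfTI .nii/.nii.gz expected)")
  }
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L) stop("expected a 3-D volume: ", path)
  spacing <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("missing or invalid voxel spacing in NIfTI header of ", path)
  }
  mAs <- NULL; sigma <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    mAs <- meta$mAs %||% NULL
    sigma <- meta$sigma_hu %||% NULL
  }
  ct_volume(array(as.numeric(im), dim(im)), spacing, mAs = mAs,
            sigma_hu = sigma)
}

#' Write a CT volume as NIfTI
#'
#' Values and spacing round-trip exactly through [load_volume()].
#' Acquisition metadata, which NIfTI headers cannot carry, is written to a
#' JSON sidecar `<path>.json` when present.
#'
#' @param ct A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  im <- RNifti::asNifti(ct$data)
  RNifti::pixdim(im) <- ct$spacing
  RNifti::writeNifti(im, path, datatype = "double")
  if (!is.null(ct$mAs) || !is.null(ct$sigma_hu)) {
    jsonlite::write_json(list(mAs = ct$mAs, sigma_hu = ct$sigma_hu),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Save a quantitative result as JSON
#'
#' @param result A `qct_result` (or any list-like result object).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_result <- function(result, path) {
  out <- unclass(result)
  out$scheme <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
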