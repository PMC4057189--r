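#' Volumetric CT dose index from tube current
#'
#' At fixed tube voltage and pitch, scanner output dose is linear in the
#' tube current-time product: `CTDIvol = calib * mAs`. The default
#' calibration coefficient is taken from the reference protocol's 60-mAs
#' measurement (9.2 mGy / 60 mAs).
#'
#' @param mAs Positive tube current-time product(s).
#' @param calib mGy-per-mAs coefficient, > 0.
#' @return CTDIvol in mGy.
#' @export
ctdi_vol <- function(mAs, calib = 9.2 / 60) {
  if (any(!is.finite(mAs)) || any(mAs <= 0)) stop("`mAs` must be positive")
  if (!is.numeric(calib) || calib <= 0) stop("`calib` must be positive")
  calib * mAs
}

#' Effective dose by the DLP method
#'
#' `E = DLP * k`, where `k` is a region-specific conversion coefficient
#' in mSv per mGy cm. The default `k = 0.0204` is calibrated from the
#' reference protocol's printed effective-dose-to-DLP ratios.
#'
#' @param dlp Dose-length product, mGy cm, >= 0.
#' @param k Conversion coefficient, mSv/(mGy cm), > 0.
#' @return Effective dose in mSv.
#' @export
effective_dose <- function(dlp, k = 0.0204) {
  if (any(dlp < 0)) stop("`dlp` must be nonnegative")
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  dlp * k
}

#' Relative dose reduction between two effective doses
#'
#' `100 * (1 - e_low / e_ref)` percent, rounded to the nearest integer
#' for reporting (set `round = FALSE` for the raw value).
#'
#' @param e_ref Reference effective dose, > 0.
#' @param e_low Compared (lower-dose) effective dose, >= 0.
#' @param round Round to integer percent?
#' @return Dose reduction in percent.
#' @export
dose_reduction <- function(e_ref, e_low, round = TRUE) {
  if (any(!is.finite(e_ref)) || any(e_ref <= 0)) stop("`e_ref` must be positive")
  if (any(e_low < 0)) stop("`e_low` must be nonnegative")
  pct <- 100 * (1 - e_low / e_ref)
  if (round) round_half_away(pct) else pct
}

#' Dose record for one acquisition
#'
#' Bundles the dose metrics of a scan with the internal consistency
#' `DLP = CTDIvol * scan length` and `E = DLP * k` guaranteed by
#' construction.
#'
#' @param mAs Tube current-time product, > 0.
#' @param scan_length_cm Scanned z-extent in cm, > 0.
#' @param calib mGy-per-mAs coefficient for [ctdi_vol()].
#' @param k Effective-dose conversion coefficient, mSv/(mGy cm).
#' @return An object of class `dose_record` with `mAs`, `ctdi_vol`,
#'   `scan_length_cm`, `dlp`, `k`, `effective_dose`.
#' @export
dose_record <- function(mAs, scan_length_cm, calib = 9.2 / 60, k = 0.0204) {
  if (!is.numeric(scan_length_cm) || scan_length_cm <= 0) {
    stop("`scan_length_cm` must be positive")
  }
  ctdi <- ctdi_vol(mAs, calib)
  dlp <- ctdi * scan_length_cm
  structure(list(mAs = mAs, ctdi_vol = ctdi, scan_length_cm = scan_length_cm,
                 dlp = dlp, k = k, effective_dose = effective_dose(dlp, k)),
            class = "dose_record")
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf(
    "Dose record: %g mAs -> CTDIvol %.2f mGy, DLP %.1f mGy cm, E %.2f mSv\n",
    x$mAs, x$ctdi_vol, x$dlp, x$effective_dose))
  invisible(x)
}

#' Image noise from a uniform region of interest
#'
#' Estimates the image-noise level as the mean, across scans, of the
#' per-scan standard deviation (n-1 denominator) of CT numbers inside a
#' uniform region of interest (classically a region within the aorta).
#'
#' @param scans A [ct_volume()] or list of them, sharing one grid.
#' @param roi Logical array (or `lung_mask`) selecting the uniform region;
#'   at least 2 voxels.
#' @return Estimated noise SD in HU.
#' @export
estimate_noise <- function(scans, roi) {
  if (inherits(scans, "ct_volume")) scans <- list(scans)
  if (length(scans) < 1L) stop("need at least one scan")
  if (inherits(roi, "lung_mask")) roi <- roi$mask
  if (sum(roi) < 2L) stop("uniform ROI must contain at least 2 voxels")
  sds <- vapply(scans, function(ct) {
    if (!identical(dim(ct$data), dim(roi))) stop("ROI does not match scan grid")
    stats::sd(ct$data[roi])
  }, numeric(1))
  mean(sds)
}
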