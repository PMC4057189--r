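# Bundled calibration measurements from the paired-mAs ovine chest-CT
# protocol that this package's defaults emulate: a reference scan at 60 mAs
# paired, within one breath-hold, with a scan at 140, 15 or 7.5 mAs, all
# other settings unchanged.

#' Reference image-noise measurements
#'
#' Mean (+/- SD) standard deviation of CT numbers measured in a uniform
#' aortic region of interest, by tube current, for the protocol the
#' package defaults emulate. These four points calibrate the default
#' [noise_model()].
#'
#' @return Data frame with columns `mAs`, `sigma` (mean noise SD, HU) and
#'   `sigma_sd` (between-scan SD of the noise estimate, HU).
#' @export
reference_noise_table <- function() {
  data.frame(
    mAs = c(140, 60, 15, 7.5),
    sigma = c(10.0, 15.9, 37.5, 73.8),
    sigma_sd = c(1.1, 3.5, 10.6, 17.5)
  )
}

#' Reference dose measurements
#'
#' Scanner-reported CTDIvol and DLP and the DLP-method effective dose for
#' the four tube currents of the reference protocol (mean +/- SD over
#' scans). These calibrate the default mGy-per-mAs coefficient of
#' [ctdi_vol()] and the effective-dose conversion coefficient `k`.
#'
#' @return Data frame with columns `mAs`, `ctdi_vol` (mGy), `ctdi_sd`,
#'   `dlp` (mGy cm), `dlp_sd`, `e` (effective dose, mSv), `e_sd`.
#' @export
reference_dose_table <- function() {
  data.frame(
    mAs = c(140, 60, 15, 7.5),
    ctdi_vol = c(22.1, 9.2, 2.2, 1.1),
    ctdi_sd = c(0.0, 0.8, 0.3, 0.1),
    dlp = c(870.5, 362.2, 96.5, 44.9),
    dlp_sd = c(47.7, 45.2, 39.0, 6.4),
    e = c(17.8, 7.4, 2.0, 0.9),
    e_sd = c(1.0, 0.9, 0.8, 0.1)
  )
}

#' Reference paired-comparison design
#'
#' Number of paired 60-vs-alternative-mAs comparisons per study arm in the
#' reference protocol, split by condition (healthy baseline vs
#' oleic-acid ARDS). Each comparison consumes two scans.
#'
#' @return Data frame with columns `mAs_alt`, `n_baseline`, `n_ards`.
#' @export
reference_study_design <- function() {
  data.frame(
    mAs_alt = c(140, 15, 7.5),
    n_baseline = c(12, 18, 16),
    n_ards = c(28, 18, 17)
  )
}

#' Default noise model calibrated to the reference measurements
#'
#' Power-law fit to [reference_noise_table()], with the measured points
#' kept as a lookup table so the four protocol tube currents reproduce the
#' measured noise exactly.
#'
#' @return A [noise_model()].
#' @export
default_noise_model <- function() {
  tab <- reference_noise_table()
  fit_noise_model(tab$mAs, tab$sigma, form = "power", keep_lookup = TRUE)
}
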