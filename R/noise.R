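#' Acquisition settings
#'
#' Scanner settings for a helical chest acquisition. Defaults follow the
#' paired-mAs sheep protocol bundled with the package: 120 kVp, 0.5 s
#' rotation, 32 x 0.5 mm collimation, pitch 0.85, 5-mm reconstructed
#' slices, 0.625-mm pixels; only the tube current-time product (mAs) is
#' varied between paired scans.
#'
#' @param mAs Tube current-time product, > 0.
#' @param kVp Tube voltage (kV).
#' @param pitch Helical pitch.
#' @param collimation_mm Total beam collimation in mm (32 x 0.5 mm = 16).
#' @param rotation_time_s Gantry rotation time in seconds.
#' @param slice_width_mm Reconstructed slice width in mm.
#' @param pixel_size_mm In-plane pixel size in mm.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(mAs, kVp = 120, pitch = 0.85,
                                 collimation_mm = 16, rotation_time_s = 0.5,
                                 slice_width_mm = 5, pixel_size_mm = 0.625) {
  if (!is.numeric(mAs) || length(mAs) != 1L || !is.finite(mAs) || mAs <= 0) {
    stop("`mAs` must be a single positive number")
  }
  structure(list(mAs = mAs, kVp = kVp, pitch = pitch,
                 collimation_mm = collimation_mm,
                 rotation_time_s = rotation_time_s,
                 slice_width_mm = slice_width_mm,
                 pixel_size_mm = pixel_size_mm),
            class = "acquisition_settings")
}

#' Image-noise model as a function of tube current
#'
#' Maps mAs to the standard deviation of CT-number noise (HU). Two
#' parametric families are supported:
#' \describe{
#'   \item{`"quantum"`}{`sigma(mAs) = sqrt(a / mAs + b)` - quantum noise
#'     proportional to 1/sqrt(mAs) plus an electronic floor `b` (HU^2).}
#'   \item{`"power"`}{`sigma(mAs) = c * mAs^(-p)` - an empirical power
#'     law. Measured scanner noise often grows faster than the quantum
#'     1/sqrt(mAs) prediction at very low tube currents, which a
#'     nonnegative floor cannot reproduce (it only flattens the curve);
#'     the power law captures that steepening.}
#' }
#' An optional lookup table of measured `(mAs, sigma)` pairs takes
#' precedence over the parametric form at exactly matching mAs.
#'
#' @param a Quantum coefficient, HU^2 mAs, >= 0.
#' @param b Electronic noise floor, HU^2, >= 0.
#' @param c,p Power-law scale (HU) and exponent, `c > 0`, `p >= 0`.
#' @param lookup Optional data frame with columns `mAs` and `sigma`.
#' @param form `"quantum"` or `"power"`.
#' @return An object of class `noise_model`.
#' @seealso [fit_noise_model()], [noise_sigma()]
#' @export
noise_model <- function(a = NULL, b = NULL, c = NULL, p = NULL,
                        lookup = NULL, form = NULL) {
  if (is.null(form)) {
    form <- if (!is.null(c) || !is.null(p)) "power" else "quantum"
  }
  form <- match.arg(form, c("quantum", "power"))
  if (form == "quantum") {
    a <- a %||% 0; b <- b %||% 0
    if (a < 0 || b < 0) stop("`a` and `b` must be nonnegative")
  } else {
    c <- c %||% 0; p <- p %||% 0
    if (c < 0 || p < 0) stop("`c` and `p` must be nonnegative")
  }
  if (!is.null(lookup)) {
    lookup <- as.data.frame(lookup)
    if (!all(c("mAs", "sigma") %in% names(lookup))) {
      stop("`lookup` needs columns `mAs` and `sigma`")
    }
    if (any(lookup$mAs <= 0) || any(lookup$sigma < 0)) {
      stop("lookup mAs must be positive and sigma nonnegative")
    }
  }
  structure(list(form = form, a = a, b = b, c = c, p = p, lookup = lookup),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$form == "quantum") {
    cat(sprintf("Noise model: sigma(mAs) = sqrt(%.4g/mAs + %.4g) HU\n",
                x$a, x$b))
  } else {
    cat(sprintf("Noise model: sigma(mAs) = %.4g * mAs^-%.4g HU\n", x$c, x$p))
  }
  if (!is.null(x$lookup)) {
    cat("  lookup table (takes precedence):",
        paste(sprintf("%g mAs -> %g HU", x$lookup$mAs, x$lookup$sigma),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Noise standard deviation at a given tube current
#'
#' Returns the lookup value when `mAs` matches a tabulated point, otherwise
#' evaluates the model's parametric law.
#'
#' @param mAs Positive tube current-time product(s).
#' @param model A [noise_model()].
#' @return Noise SD(s) in HU.
#' @export
noise_sigma <- function(mAs, model) {
  if (any(!is.finite(mAs)) || any(mAs <= 0)) stop("`mAs` must be positive")
  sig <- if (model$form == "quantum") {
    sqrt(model$a / mAs + model$b)
  } else {
    model$c * mAs^(-model$p)
  }
  if (!is.null(model$lookup)) {
    for (i in seq_len(nrow(model$lookup))) {
      hit <- abs(mAs - model$lookup$mAs[i]) < 1e-9 * max(1, model$lookup$mAs[i])
      sig[hit] <- model$lookup$sigma[i]
    }
  }
  sig
}

#' Calibrate a noise model to measured (mAs, sigma) pairs
#'
#' For the power family (default), fits `log(sigma) = log(c) - p*log(mAs)`
#' by ordinary least squares. For the quantum family, fits
#' `sigma^2 = a/mAs + b` by least squares in the variance domain with the
#' nonnegativity constraints `a, b >= 0` (the two-parameter constrained
#' optimum is found by comparing the unconstrained fit with the two
#' single-parameter boundary fits).
#'
#' @param mAs Numeric vector of tube currents (>= 2 distinct values).
#' @param sigma Measured noise SDs in HU, same length, nonnegative.
#' @param form Model family to fit, `"power"` (default) or `"quantum"`.
#' @param keep_lookup If `TRUE`, store the observations as the model's
#'   lookup table so tabulated mAs reproduce the measurements exactly.
#' @return A [noise_model()] with extra fields `residuals` (observed minus
#'   fitted sigma, HU) and `fitted`.
#' @export
fit_noise_model <- function(mAs, sigma, form = c("power", "quantum"),
                            keep_lookup = FALSE) {
  form <- match.arg(form)
  mAs <- as.numeric(mAs); sigma <- as.numeric(sigma)
  if (length(mAs) != length(sigma)) stop("`mAs` and `sigma` lengths differ")
  if (length(unique(mAs)) < 2L) {
    stop("need at least 2 distinct mAs values to fit a noise model")
  }
  if (any(mAs <= 0) || any(sigma < 0)) {
    stop("mAs must be positive and sigma nonnegative")
  }
  if (form == "power") {
    if (any(sigma <= 0)) stop("power-law fit requires strictly positive sigma")
    fit <- stats::lm(log(sigma) ~ log(mAs))
    p <- max(0, -unname(stats::coef(fit)[2]))
    cc <- exp(unname(stats::coef(fit)[1]))
    model <- noise_model(c = cc, p = p, form = "power")
  } else {
    x <- 1 / mAs
    y <- sigma^2
    sse <- function(a, b) sum((y - (a * x + b))^2)
    fit <- stats::lm(y ~ x)
    b0 <- unname(stats::coef(fit)[1]); a0 <- unname(stats::coef(fit)[2])
    cand <- list(c(a0, b0),
                 c(max(0, sum(y * x) / sum(x * x)), 0),  # b = 0 boundary
                 c(0, max(0, mean(y))))                  # a = 0 boundary
    cand <- Filter(function(ab) ab[1] >= 0 && ab[2] >= 0, cand)
    best <- cand[[which.min(vapply(cand, function(ab) sse(ab[1], ab[2]),
                                   numeric(1)))]]
    model <- noise_model(a = best[1], b = best[2], form = "quantum")
  }
  if (keep_lookup) {
    model$lookup <- data.frame(mAs = mAs, sigma = sigma)
  }
  fitted <- if (model$form == "power") {
    model$c * mAs^(-model$p)
  } else {
    sqrt(model$a / mAs + model$b)
  }
  model$fitted <- fitted
  model$residuals <- sigma - fitted
  model
}
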