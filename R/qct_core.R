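#' Aeration compartment scheme
#'
#' The four standard Hounsfield-unit bands used in quantitative lung CT:
#' hyperinflated (-1000 to -901 HU), normally aerated (-900 to -501 HU),
#' poorly aerated (-500 to -101 HU) and nonaerated (-100 HU up to the
#' exclusion bound, +200 HU by default). Voxels measuring above the
#' exclusion bound are tallied separately and excluded from volume and mass
#' totals; voxels below -1000 HU are clamped to -1000 (zero tissue mass).
#'
#' @param exclusion_hu Upper inclusion bound in HU. The default +200 HU is
#'   the customary nonaerated ceiling; raising it (for example to +500 HU)
#'   recovers dense tissue that heavy image noise pushes above +200 HU.
#' @param floor_hu Clamp floor in HU (default -1000, pure gas).
#' @return An object of class `compartment_scheme` with a `compartments`
#'   data frame (`name`, `lo`, `hi`) and the two bounds.
#' @export
compartment_scheme <- function(exclusion_hu = 200, floor_hu = -1000) {
  if (exclusion_hu <= -100) stop("`exclusion_hu` must exceed -100 HU")
  if (floor_hu != -1000) stop("the HU scale is anchored at -1000 = pure gas")
  comp <- data.frame(
    name = c("hyperinflated", "normally_aerated", "poorly_aerated",
             "nonaerated"),
    lo = c(-1000, -900, -500, -100),
    hi = c(-901, -501, -101, exclusion_hu),
    stringsAsFactors = FALSE
  )
  stopifnot(all(comp$lo[-1] == comp$hi[-4] + 1))  # contiguous, non-overlapping
  structure(list(compartments = comp, exclusion_hu = exclusion_hu,
                 floor_hu = floor_hu),
            class = "compartment_scheme")
}

#' Tissue fraction of a voxel from its CT number
#'
#' The density of lung tissue is modelled as a linear mixture of gas
#' (-1000 HU, density 0) and water-equivalent tissue (0 HU, density
#' 1 g/ml), so the tissue (volume) fraction of a voxel is
#' `(HU + 1000) / 1000` after clamping HU to the analysed range. The
#' complement `1 - tissue_fraction(hu)` is the gas fraction for
#' `hu <= 0`. Values up to the default +200 HU ceiling give fractions up
#' to 1.2 (tissue denser than water).
#'
#' @param hu Numeric vector of CT numbers in HU.
#' @param scheme A [compartment_scheme()]; supplies the clamp bounds.
#' @return Tissue fraction(s) in `[0, 1 + exclusion_hu/1000]`.
#' @export
tissue_fraction <- function(hu, scheme = compartment_scheme()) {
  (pmin(pmax(hu, scheme$floor_hu), scheme$exclusion_hu) + 1000) / 1000
}

# compartment index (1..4) of rounded HU values within the analysed range
compartment_index <- function(hu_rounded, scheme) {
  findInterval(hu_rounded, scheme$compartments$lo)
}

#' Quantitative CT analysis of a masked lung volume
#'
#' Computes, over the in-mask voxels: total lung volume (gas + tissue, ml),
#' total tissue mass (g), the mass and mass fraction of each aeration
#' compartment, and the tally of voxels excluded for measuring above the
#' exclusion bound. Each included voxel contributes
#' `voxel volume (ml) x tissue_fraction(HU)` grams of tissue, assigned to
#' the compartment containing its CT number rounded to the nearest integer
#' (ties away from zero). Voxels above the exclusion bound contribute to
#' neither volume nor mass: with heavy image noise this exclusion rule
#' itself depresses the measured volume and nonaerated mass of dense lungs.
#'
#' @param ct A [ct_volume()].
#' @param mask A [lung_mask()] aligned to `ct`.
#' @param scheme A [compartment_scheme()].
#' @return An object of class `qct_result`: `total_volume_ml`,
#'   `total_mass_g`, `compartments` (data frame with `mass_g` and
#'   `fraction_pct`), `excluded_mass_g`, `excluded_voxels`, `n_voxels`,
#'   and `undefined_fractions` (TRUE when every voxel was excluded).
#' @export
quantify <- function(ct, mask, scheme = compartment_scheme()) {
  check_aligned(ct, mask)
  if (!any(mask$mask)) stop("mask is empty")
  hu <- ct$data[mask$mask]
  vox_ml <- prod(ct$spacing) / 1000
  n <- length(hu)
  excl <- hu > scheme$exclusion_hu
  n_excl <- sum(excl)
  # excluded voxels still have a (clamped) density; keep their mass so that
  # included + excluded mass conserves the no-exclusion total exactly
  excluded_mass <- vox_ml * sum(tissue_fraction(hu[excl], scheme))

  comp <- scheme$compartments
  comp$mass_g <- 0
  if (n_excl < n) {
    hu_in <- pmax(hu[!excl], scheme$floor_hu)
    w <- (hu_in + 1000) / 1000
    idx <- compartment_index(round_half_away(hu_in), scheme)
    m <- vapply(seq_len(nrow(comp)),
                function(k) sum(w[idx == k]), numeric(1)) * vox_ml
    comp$mass_g <- m
  }
  total_mass <- sum(comp$mass_g)
  undefined <- n_excl == n || total_mass == 0
  comp$fraction_pct <- if (undefined) NA_real_ else 100 * comp$mass_g / total_mass

  structure(list(
    total_volume_ml = (n - n_excl) * vox_ml,
    total_mass_g = total_mass,
    compartments = comp,
    excluded_mass_g = excluded_mass,
    excluded_voxels = n_excl,
    n_voxels = n,
    undefined_fractions = undefined,
    scheme = scheme
  ), class = "qct_result")
}

#' @export
print.qct_result <- function(x, ...) {
  cat("qCT result over", x$n_voxels, "voxels\n")
  cat("  total lung volume:", round(x$total_volume_ml, 1), "ml\n")
  cat("  total tissue mass:", round(x$total_mass_g, 1), "g\n")
  comp <- x$compartments
  for (k in seq_len(nrow(comp))) {
    cat(sprintf("  %-17s %8.1f g  %6.2f %%\n", comp$name[k], comp$mass_g[k],
                comp$fraction_pct[k]))
  }
  if (x$excluded_voxels > 0) {
    cat("  excluded (>", x$scheme$exclusion_hu, "HU):", x$excluded_voxels,
        "voxels,", round(x$excluded_mass_g, 1), "g\n")
  }
  if (x$undefined_fractions) cat("  [fractions undefined: no included mass]\n")
  invisible(x)
}

#' Mass-weighted 50-HU frequency histogram
#'
#' Distributes the lung tissue mass over 50-HU-wide CT-number bins from
#' -1000 HU up to the exclusion bound (24 bins for the default +200 HU
#' bound), expressed as percentages of total tissue mass. Bin edges are
#' aligned with the compartment boundaries. Voxels above the exclusion
#' bound are excluded; voxels below -1000 HU are clamped into the first
#' bin (with zero mass at exactly -1000).
#'
#' @inheritParams quantify
#' @return An object of class `qct_histogram`: data frame `bins` with
#'   integer bin bounds `lo`, `hi` and `fraction_pct`, plus the total mass.
#' @export
histogram_50hu <- function(ct, mask, scheme = compartment_scheme()) {
  check_aligned(ct, mask)
  if (!any(mask$mask)) stop("mask is empty")
  hu <- ct$data[mask$mask]
  hu <- hu[hu <= scheme$exclusion_hu]
  n_bins <- ceiling((scheme$exclusion_hu + 1000) / 50)
  lo <- -1000 + 50 * (seq_len(n_bins) - 1)
  hi <- c(lo[-1] - 1, scheme$exclusion_hu)
  frac <- rep(NA_real_, n_bins)
  total_mass <- 0
  if (length(hu)) {
    hu <- pmax(hu, scheme$floor_hu)
    w <- (hu + 1000) / 1000
    idx <- pmin(floor((round_half_away(hu) + 1000) / 50) + 1, n_bins)
    mass <- vapply(seq_len(n_bins), function(k) sum(w[idx == k]), numeric(1))
    total_mass <- sum(mass)
    if (total_mass > 0) frac <- 100 * mass / total_mass
  }
  structure(list(
    bins = data.frame(lo = lo, hi = hi, fraction_pct = frac),
    total_mass_weight = total_mass,
    scheme = scheme
  ), class = "qct_histogram")
}

#' @export
print.qct_histogram <- function(x, ...) {
  cat("Mass-frequency distribution,", nrow(x$bins), "bins of 50 HU\n")
  b <- x$bins[!is.na(x$bins$fraction_pct) & x$bins$fraction_pct > 0.05, ]
  for (k in seq_len(nrow(b))) {
    cat(sprintf("  [%5d, %4d] %6.2f %%\n", b$lo[k], b$hi[k], b$fraction_pct[k]))
  }
  invisible(x)
}
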