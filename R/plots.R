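#' Bland-Altman plot
#'
#' Scatter of pair differences against pair means with the bias and 95%
#' limits of agreement drawn as horizontal lines.
#'
#' @param ref,alt Paired numeric vectors, as for [bland_altman()].
#' @param ... Passed to [plot()] (e.g. `xlab`, `main`).
#' @return The `bland_altman` result, invisibly.
#' @export
plot_bland_altman <- function(ref, alt, ...) {
  ba <- bland_altman(ref, alt)
  d <- ref - alt
  m <- (ref + alt) / 2
  graphics::plot(m, d, pch = 19,
                 ylim = range(c(d, ba$loa_low, ba$loa_high)),
                 xlab = "pair mean", ylab = "difference (ref - alt)", ...)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}

#' Paired 50-HU histogram comparison plot
#'
#' Grouped bar chart of the mean reference and alternative mass-frequency
#' distributions, with significant bins (per-bin paired test) starred.
#'
#' @param comparison Output of [compare_histograms()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_histogram_comparison <- function(comparison, ...) {
  h <- rbind(comparison$mean_ref, comparison$mean_alt)
  mids <- graphics::barplot(h, beside = TRUE,
                            names.arg = comparison$lo, las = 2,
                            xlab = "CT number bin lower edge (HU)",
                            ylab = "% of tissue mass",
                            legend.text = c("reference", "alternative"), ...)
  sig <- which(comparison$significant)
  if (length(sig)) {
    graphics::text(colMeans(mids)[sig],
                   apply(h, 2, max)[sig] + 0.02 * max(h), "*", cex = 1.4)
  }
  invisible(mids)
}
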