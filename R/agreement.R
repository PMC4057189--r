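#' Bland-Altman agreement analysis of paired measurements
#'
#' Assesses agreement between a reference and an alternative measurement
#' of the same quantity on `n` pairs. Differences are oriented
#' `reference - alternative`. Reports the bias (mean difference), the SD
#' of the differences (n-1 denominator), the 95% limits of agreement
#' `bias +/- 1.96 * SD`, a proportional-bias regression of the difference
#' on the pair mean, the r-squared of the alternative-on-reference
#' regression, and a paired test p-value (see [paired_test()]).
#'
#' @param ref,alt Numeric vectors of paired measurements (equal length,
#'   `n >= 2`).
#' @return An object of class `bland_altman` with fields `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `prop_slope`, `prop_r2`, `prop_p`,
#'   `pair_r2`, `p_paired`, `test`, `degenerate`.
#' @export
bland_altman <- function(ref, alt) {
  ref <- as.numeric(ref); alt <- as.numeric(alt)
  if (length(ref) != length(alt)) stop("`ref` and `alt` lengths differ")
  n <- length(ref)
  if (n < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- ref - alt
  m <- (ref + alt) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  degenerate <- sd_diff == 0
  prop_slope <- prop_r2 <- prop_p <- NA_real_
  if (!degenerate && stats::sd(m) > 0 && n >= 3L) {
    fit <- stats::lm(d ~ m)
    # near-perfect fits arise legitimately (e.g. proportional shifts)
    sm <- suppressWarnings(summary(fit))
    prop_slope <- unname(stats::coef(fit)[2])
    prop_r2 <- sm$r.squared
    prop_p <- sm$coefficients[2, 4]
  }
  pair_r2 <- if (stats::sd(ref) > 0 && stats::sd(alt) > 0) {
    stats::cor(ref, alt)^2
  } else {
    NA_real_
  }
  pt <- paired_test(ref, alt)
  structure(list(
    n = n, bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    prop_slope = prop_slope, prop_r2 = prop_r2, prop_p = prop_p,
    pair_r2 = pair_r2, p_paired = pt$p, test = pt$test,
    degenerate = degenerate
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, LOA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  paired %s p = %.3g; pair r2 = %.3g\n", x$test, x$p_paired,
              x$pair_r2))
  if (!is.na(x$prop_slope)) {
    cat(sprintf("  proportional bias: slope %.3g, r2 %.3g, p %.3g\n",
                x$prop_slope, x$prop_r2, x$prop_p))
  }
  if (x$degenerate) cat("  [degenerate: zero-variance differences]\n")
  invisible(x)
}

#' Paired test with automatic selection
#'
#' Tests whether paired differences are centred on zero. The differences
#' are checked for normality by the Shapiro-Wilk test at
#' `alpha_normality`; if they pass, a paired t-test is used, otherwise the
#' Wilcoxon signed-rank test. With fewer than 3 pairs normality cannot be
#' assessed and the t-test is used. All-zero differences return `p = 1`
#' with a degenerate flag; constant nonzero differences fall back to the
#' signed-rank branch.
#'
#' @param ref,alt Paired numeric vectors.
#' @param alpha_normality Significance level of the normality check.
#' @return List with `p`, `test` (`"t"`, `"wilcoxon"` or `"degenerate"`),
#'   `shapiro_p` and `degenerate`.
#' @export
paired_test <- function(ref, alt, alpha_normality = 0.05) {
  d <- as.numeric(ref) - as.numeric(alt)
  n <- length(d)
  if (n < 2L) stop("paired test needs at least 2 pairs")
  if (all(d == 0)) {
    return(list(p = 1, test = "degenerate", shapiro_p = NA_real_,
                degenerate = TRUE))
  }
  shapiro_p <- NA_real_
  if (stats::sd(d) == 0) {
    # constant nonzero shift: no distributional test possible
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    return(list(p = p, test = "wilcoxon", shapiro_p = NA_real_,
                degenerate = FALSE))
  }
  use_t <- TRUE
  if (n >= 3L && n <= 5000L) {
    shapiro_p <- stats::shapiro.test(d)$p.value
    use_t <- shapiro_p > alpha_normality
  }
  if (use_t) {
    p <- stats::t.test(d)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    test <- "wilcoxon"
  }
  list(p = p, test = test, shapiro_p = shapiro_p, degenerate = FALSE)
}

# measures extracted from a qct_result for agreement tables
qct_measures <- function(res) {
  fr <- res$compartments$fraction_pct
  names(fr) <- res$compartments$name
  c(lung_volume_ml = res$total_volume_ml,
    lung_tissue_mass_g = res$total_mass_g,
    hyperinflated_pct = unname(fr["hyperinflated"]),
    normally_aerated_pct = unname(fr["normally_aerated"]),
    poorly_aerated_pct = unname(fr["poorly_aerated"]),
    nonaerated_pct = unname(fr["nonaerated"]))
}

#' Paired-agreement table over quantitative CT results
#'
#' For a set of reference/alternative result pairs, builds one row per
#' measure (lung volume, tissue mass and the four compartment mass
#' fractions) with the per-arm mean and SD, the paired-test p-value, the
#' r-squared of the pairwise regression, the bias and the 95% limits of
#' agreement - the standard layout for reporting low-dose agreement.
#'
#' @param pairs List of pairs; each element is a list with components
#'   `ref` and `alt`, both `qct_result` objects.
#' @return A data frame of class `agreement_table` with columns `measure`,
#'   `mean_ref`, `sd_ref`, `mean_alt`, `sd_alt`, `p`, `r2`, `bias`,
#'   `loa_low`, `loa_high`, `test`.
#' @export
compare_pairs <- function(pairs) {
  if (length(pairs) < 2L) stop("need at least 2 result pairs")
  ref <- t(vapply(pairs, function(pr) qct_measures(pr$ref), numeric(6)))
  alt <- t(vapply(pairs, function(pr) qct_measures(pr$alt), numeric(6)))
  if (!identical(colnames(ref), colnames(alt))) {
    stop("mismatched result schemas between reference and alternative")
  }
  rows <- lapply(colnames(ref), function(ms) {
    ba <- bland_altman(ref[, ms], alt[, ms])
    data.frame(measure = ms,
               mean_ref = mean(ref[, ms]), sd_ref = stats::sd(ref[, ms]),
               mean_alt = mean(alt[, ms]), sd_alt = stats::sd(alt[, ms]),
               p = ba$p_paired, r2 = ba$pair_r2, bias = ba$bias,
               loa_low = ba$loa_low, loa_high = ba$loa_high, test = ba$test,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_table", class(out))
  out
}

#' Per-bin comparison of paired mass-frequency histograms
#'
#' Applies [paired_test()] to each 50-HU bin of a set of paired
#' histograms and flags bins with `p < 0.05`. No multiple-testing
#' correction is applied across bins (results are reported per bin, as is
#' customary for these frequency-distribution comparisons).
#'
#' @param pairs List of pairs; each element a list with `ref` and `alt`
#'   `qct_histogram` objects on identical bins.
#' @param alpha Flagging threshold.
#' @return Data frame with one row per bin: `lo`, `hi`, `mean_ref`,
#'   `mean_alt`, `mean_diff`, `p`, `significant`, `test`.
#' @export
compare_histograms <- function(pairs, alpha = 0.05) {
  if (length(pairs) < 3L) stop("need at least 3 histogram pairs")
  edges <- pairs[[1]]$ref$bins[, c("lo", "hi")]
  for (pr in pairs) {
    if (!identical(pr$ref$bins$lo, edges$lo) ||
        !identical(pr$alt$bins$lo, edges$lo)) {
      stop("histogram bin edges differ between pairs")
    }
  }
  ref <- t(vapply(pairs, function(pr) pr$ref$bins$fraction_pct,
                  numeric(nrow(edges))))
  alt <- t(vapply(pairs, function(pr) pr$alt$bins$fraction_pct,
                  numeric(nrow(edges))))
  rows <- lapply(seq_len(nrow(edges)), function(k) {
    pt <- paired_test(ref[, k], alt[, k])
    data.frame(lo = edges$lo[k], hi = edges$hi[k],
               mean_ref = mean(ref[, k]), mean_alt = mean(alt[, k]),
               mean_diff = mean(ref[, k] - alt[, k]),
               p = pt$p, significant = pt$p < alpha, test = pt$test,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA across groups with rank fallback
#'
#' Compares group means by one-way analysis of variance. If any group
#' fails Shapiro-Wilk normality at `alpha` or Bartlett's test indicates
#' unequal variances, the pooled values are rank-transformed first.
#' Degenerate inputs follow fixed conventions: all groups constant and
#' equal gives `F = 0, p = 1`; groups constant within but differing
#' between gives `F = Inf, p = 0`.
#'
#' @param groups List of at least 2 numeric vectors, each of length >= 2.
#' @param alpha Level for the normality and equal-variance checks.
#' @return List with `F`, `p`, `rank_transformed`, `method`.
#' @export
group_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 values")
  }
  v <- unlist(groups)
  g <- factor(rep.int(seq_along(groups), vapply(groups, length, integer(1))))
  sds <- vapply(groups, stats::sd, numeric(1))
  if (all(sds == 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) == 0) {
      return(list(F = 0, p = 1, rank_transformed = FALSE,
                  method = "degenerate: identical constant groups"))
    }
    return(list(F = Inf, p = 0, rank_transformed = FALSE,
                method = "degenerate: zero within-group variance"))
  }
  rank_it <- FALSE
  for (gr in groups) {
    if (length(gr) >= 3L && stats::sd(gr) > 0 &&
        stats::shapiro.test(gr)$p.value < alpha) {
      rank_it <- TRUE
      break
    }
  }
  if (!rank_it && all(sds > 0) &&
      stats::bartlett.test(v, g)$p.value < alpha) {
    rank_it <- TRUE
  }
  if (rank_it) v <- rank(v)
  a <- stats::anova(stats::lm(v ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1], rank_transformed = rank_it,
       method = if (rank_it) "one-way ANOVA on ranks" else "one-way ANOVA")
}
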