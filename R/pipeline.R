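#' Configuration of a paired-mAs simulation study
#'
#' Describes a full paired-dose study: for each arm (a condition and an
#' alternative tube current), `n_pairs` phantoms are generated and each is
#' scanned twice in randomized order - once at the 60-mAs reference and
#' once at the alternative mAs - with independent noise draws on the
#' shared ground-truth volume (the digital analogue of rescanning the
#' same subject within one breath-hold). The default arms reproduce the
#' reference protocol's design: 60 vs 140/15/7.5 mAs with 12/18/16
#' healthy and 28/18/17 ARDS pairs.
#'
#' @param arms Data frame with columns `condition` (`"healthy"`/`"ards"`),
#'   `mAs_alt` and `n_pairs` (>= 2); defaults to the reference design.
#' @param mAs_ref Reference tube current; fixed at 60 mAs.
#' @param noise A [noise_model()]; defaults to [default_noise_model()].
#' @param grid_shape,voxel_spacing Phantom grid, passed to [phantom_spec()].
#' @param calib,k Dose calibration coefficients, see [ctdi_vol()] and
#'   [effective_dose()].
#' @param seed Integer master seed driving all randomness.
#' @param out_dir Optional directory; when given, report tables are
#'   written there as CSV/JSON.
#' @return An object of class `study_config`.
#' @export
study_config <- function(arms = NULL, mAs_ref = 60,
                         noise = default_noise_model(),
                         grid_shape = c(72, 72, 48),
                         voxel_spacing = c(3.125, 3.125, 5),
                         calib = 9.2 / 60, k = 0.0204,
                         seed = 1L, out_dir = NULL) {
  if (mAs_ref != 60) stop("the reference tube current is fixed at 60 mAs")
  if (is.null(arms)) {
    des <- reference_study_design()
    arms <- data.frame(
      condition = rep(c("healthy", "ards"), each = nrow(des)),
      mAs_alt = rep(des$mAs_alt, 2),
      n_pairs = c(des$n_baseline, des$n_ards)
    )
  }
  arms <- as.data.frame(arms)
  if (!all(c("condition", "mAs_alt", "n_pairs") %in% names(arms))) {
    stop("`arms` needs columns condition, mAs_alt, n_pairs")
  }
  if (any(!arms$condition %in% c("healthy", "ards"))) {
    stop("arm conditions must be 'healthy' or 'ards'")
  }
  if (any(arms$n_pairs < 2L)) stop("each arm needs n_pairs >= 2")
  if (any(arms$mAs_alt <= 0) || any(arms$mAs_alt == mAs_ref)) {
    stop("`mAs_alt` must be positive and differ from the reference")
  }
  structure(list(arms = arms, mAs_ref = mAs_ref, noise = noise,
                 grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 calib = calib, k = k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

#' Run a paired-mAs simulation study
#'
#' Executes the study described by a [study_config()]: phantom generation,
#' paired scan simulation in randomized order, quantitative analysis of
#' both scans of every pair against the phantom's ground-truth mask, and
#' aggregation into per-arm agreement tables ([compare_pairs()]), per-arm
#' 50-HU histogram comparisons ([compare_histograms()], for arms with at
#' least 3 pairs), and a dose/noise table across the tube-current levels
#' with a [group_anova()] on the per-scan aortic noise estimates. All
#' randomness derives from `config$seed`; identical configurations give
#' identical reports.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`: `arms` (list with
#'   `agreement`, `histograms`, `pairs` per arm), `dose_table`,
#'   `noise_anova`, `log` (per-pair seeds and scan order), `config`.
#' @export
run_paired_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  arms <- config$arms
  total_pairs <- sum(arms$n_pairs)
  plan <- with_seed(config$seed, {
    data.frame(
      seed_phantom = sample.int(.Machine$integer.max - 1L, total_pairs),
      seed_scan1 = sample.int(.Machine$integer.max - 1L, total_pairs),
      seed_scan2 = sample.int(.Machine$integer.max - 1L, total_pairs),
      ref_first = sample(c(TRUE, FALSE), total_pairs, replace = TRUE)
    )
  })

  mAs_levels <- sort(unique(c(config$mAs_ref, arms$mAs_alt)), decreasing = TRUE)
  aorta_sds <- stats::setNames(
    replicate(length(mAs_levels), numeric(0), simplify = FALSE),
    as.character(mAs_levels))
  scan_length_cm <- NULL

  arm_results <- vector("list", nrow(arms))
  log_rows <- vector("list", nrow(arms))
  row0 <- 0L
  for (a in seq_len(nrow(arms))) {
    cond <- arms$condition[a]
    mAs_alt <- arms$mAs_alt[a]
    n_pairs <- arms$n_pairs[a]
    arm_name <- sprintf("%s_60_vs_%g", cond, mAs_alt)
    pairs <- vector("list", n_pairs)
    hpairs <- vector("list", n_pairs)
    alog <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      pl <- plan[row0 + i, ]
      spec <- phantom_spec(condition = cond, grid_shape = config$grid_shape,
                           voxel_spacing = config$voxel_spacing,
                           seed = pl$seed_phantom)
      ph <- make_phantom(spec)
      if (is.null(scan_length_cm)) {
        scan_length_cm <- config$grid_shape[3] * config$voxel_spacing[3] / 10
      }
      order_mAs <- if (pl$ref_first) c(config$mAs_ref, mAs_alt) else
        c(mAs_alt, config$mAs_ref)
      scans <- list(
        simulate_scan(ph, acquisition_settings(order_mAs[1]), config$noise,
                      seed = pl$seed_scan1),
        simulate_scan(ph, acquisition_settings(order_mAs[2]), config$noise,
                      seed = pl$seed_scan2)
      )
      ref_scan <- scans[[if (pl$ref_first) 1L else 2L]]
      alt_scan <- scans[[if (pl$ref_first) 2L else 1L]]
      for (s in scans) {
        lv <- as.character(s$mAs)
        aorta_sds[[lv]] <- c(aorta_sds[[lv]], stats::sd(s$data[ph$aorta_mask]))
      }
      pairs[[i]] <- list(ref = quantify(ref_scan, ph$lung_mask),
                         alt = quantify(alt_scan, ph$lung_mask))
      hpairs[[i]] <- list(ref = histogram_50hu(ref_scan, ph$lung_mask),
                          alt = histogram_50hu(alt_scan, ph$lung_mask))
      alog[[i]] <- data.frame(
        arm = arm_name, pair = i, condition = cond, mAs_alt = mAs_alt,
        first_scan_mAs = order_mAs[1], seed_phantom = pl$seed_phantom,
        seed_scan1 = pl$seed_scan1, seed_scan2 = pl$seed_scan2)
    }
    arm_results[[a]] <- list(
      name = arm_name, condition = cond, mAs_alt = mAs_alt,
      agreement = compare_pairs(pairs),
      histograms = if (n_pairs >= 3L) compare_histograms(hpairs) else NULL,
      pairs = pairs)
    log_rows[[a]] <- do.call(rbind, alog)
    row0 <- row0 + n_pairs
  }
  names(arm_results) <- vapply(arm_results, `[[`, character(1), "name")

  dose_table <- data.frame(
    mAs = mAs_levels,
    ctdi_vol = ctdi_vol(mAs_levels, config$calib),
    dlp = ctdi_vol(mAs_levels, config$calib) * scan_length_cm,
    effective_dose = effective_dose(
      ctdi_vol(mAs_levels, config$calib) * scan_length_cm, config$k),
    noise_hu = vapply(as.character(mAs_levels),
                      function(lv) mean(aorta_sds[[lv]]), numeric(1)),
    n_scans = vapply(as.character(mAs_levels),
                     function(lv) length(aorta_sds[[lv]]), numeric(1))
  )
  noise_anova <- if (all(dose_table$n_scans >= 2)) {
    group_anova(unname(aorta_sds))
  } else {
    NULL
  }

  report <- structure(list(
    arms = arm_results, dose_table = dose_table, noise_anova = noise_anova,
    aorta_sds = aorta_sds, log = do.call(rbind, log_rows), config = config
  ), class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Paired-mAs study:", nrow(x$log), "pairs in", length(x$arms), "arms\n")
  for (arm in x$arms) {
    cat("\n==", arm$name, "==\n")
    tab <- arm$agreement
    for (r in seq_len(nrow(tab))) {
      cat(sprintf("  %-22s bias %8.3f  LOA [%8.3f, %8.3f]  p %.3g\n",
                  tab$measure[r], tab$bias[r], tab$loa_low[r],
                  tab$loa_high[r], tab$p[r]))
    }
  }
  cat("\nDose/noise by mAs:\n")
  print(x$dose_table, row.names = FALSE)
  if (!is.null(x$noise_anova)) {
    cat(sprintf("Noise %s: p = %.3g\n", x$noise_anova$method, x$noise_anova$p))
  }
  invisible(x)
}

# write report tables as CSV + a JSON summary
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in report$arms) {
    utils::write.csv(arm$agreement,
                     file.path(out_dir, paste0("agreement_", arm$name, ".csv")),
                     row.names = FALSE)
    if (!is.null(arm$histograms)) {
      utils::write.csv(arm$histograms,
                       file.path(out_dir, paste0("histograms_", arm$name, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(report$dose_table, file.path(out_dir, "dose_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$log, file.path(out_dir, "scan_log.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = report$config$seed,
    arms = lapply(report$arms, function(arm) {
      list(condition = arm$condition, mAs_alt = arm$mAs_alt,
           n_pairs = length(arm$pairs), agreement = arm$agreement)
    }),
    dose_table = report$dose_table,
    noise_anova_p = if (!is.null(report$noise_anova)) report$noise_anova$p
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
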