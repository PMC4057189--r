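#' Phantom specification
#'
#' Describes a ground-truth digital chest phantom: an elliptical body
#' shell containing two ellipsoidal lung fields and a uniform aortic
#' insert for noise measurement. Lung voxels are assigned CT numbers so
#' that the mass fractions of the four aeration compartments match
#' `target_fractions`. Within each compartment, values are spread evenly
#' over a symmetric range about the compartment mean, so the phantom has
#' mass density near the compartment boundaries - as real lungs do - and
#' image noise produces the boundary shifts seen at low dose.
#'
#' The default compositions are the mean healthy (normally aerated 86.6%)
#' and ARDS (nonaerated 63.5%) compartment splits of the reference
#' protocol; printed percentages are renormalised to sum to exactly 100.
#' ARDS phantoms place the densest tissue preferentially along
#' `gravity_axis` (dependent consolidation); healthy phantoms scatter
#' compartments at random.
#'
#' Within each compartment, CT numbers follow a triangular distribution
#' `(lo, mode, hi)` realised deterministically through midpoint quantiles.
#' A peaked (rather than uniform) shape matters: the mass density sitting
#' near each compartment boundary governs how much mass image noise
#' shifts across it, and the defaults are chosen so noise produces the
#' physiologic low-dose pattern - a normal-to-hyperinflated shift in
#' healthy lungs, and in ARDS a nonaerated-to-poorly-aerated shift plus
#' nonaerated mass pushed above the +200 HU exclusion bound (the ARDS
#' nonaerated distribution reaches +200 HU).
#'
#' @param condition `"healthy"` or `"ards"`; selects the default
#'   composition, HU shapes and the spatial arrangement.
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing Numeric length-3, mm per axis.
#' @param target_fractions Named numeric: mass percentage per compartment
#'   (`hyperinflated`, `normally_aerated`, `poorly_aerated`, `nonaerated`).
#'   Must sum to 100 within 0.5 (printed rounding); renormalised exactly.
#' @param compartment_hu 4 x 3 numeric matrix (rows = compartments,
#'   columns `lo`, `mode`, `hi`) of triangular CT-number distributions;
#'   each row must lie inside its compartment band whenever that
#'   compartment's target is positive. `lo = mode = hi` gives a
#'   single-valued compartment.
#' @param gravity_axis Axis index (1-3) along which ARDS consolidation is
#'   dependent (increasing coordinate = more dependent).
#' @param consolidation_jitter_mm SD of the positional jitter (mm) applied
#'   when ordering ARDS voxels along the gravity axis; sets the width of
#'   the transition zone between compartments.
#' @param aorta_hu,body_hu CT numbers of the aortic insert and of the
#'   soft-tissue body shell.
#' @param seed Integer seed making the phantom deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(condition = c("healthy", "ards"),
                         grid_shape = c(72, 72, 48),
                         voxel_spacing = c(3.125, 3.125, 5),
                         target_fractions = NULL,
                         compartment_hu = NULL,
                         gravity_axis = 2L,
                         consolidation_jitter_mm = 15,
                         aorta_hu = 50, body_hu = 40, seed = 1L) {
  condition <- match.arg(condition)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("`grid_shape` must be three positive voxel counts (>= 8)")
  }
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be three strictly positive mm values")
  }
  comp_names <- c("hyperinflated", "normally_aerated", "poorly_aerated",
                  "nonaerated")
  if (is.null(target_fractions)) {
    target_fractions <- if (condition == "healthy") {
      c(hyperinflated = 0.6, normally_aerated = 86.6,
        poorly_aerated = 11.5, nonaerated = 1.4)
    } else {
      c(hyperinflated = 0.0, normally_aerated = 9.1,
        poorly_aerated = 27.3, nonaerated = 63.5)
    }
  }
  if (is.null(names(target_fractions))) names(target_fractions) <- comp_names
  target_fractions <- target_fractions[comp_names]
  if (anyNA(target_fractions) || any(target_fractions < 0)) {
    stop("`target_fractions` must be nonnegative and named by compartment")
  }
  s <- sum(target_fractions)
  if (abs(s - 100) > 0.5) stop("`target_fractions` must sum to 100 (+/- 0.5)")
  target_fractions <- 100 * target_fractions / s

  if (is.null(compartment_hu)) {
    compartment_hu <- default_compartment_hu(condition)
  }
  compartment_hu <- as.matrix(compartment_hu)
  if (!all(dim(compartment_hu) == c(4L, 3L))) {
    stop("`compartment_hu` must be a 4 x 3 (lo, mode, hi) matrix")
  }
  colnames(compartment_hu) <- c("lo", "mode", "hi")
  rownames(compartment_hu) <- comp_names
  scheme <- compartment_scheme()
  bands <- scheme$compartments
  for (k in 1:4) {
    tri <- compartment_hu[k, ]
    if (tri["lo"] > tri["mode"] || tri["mode"] > tri["hi"]) {
      stop("compartment_hu rows must satisfy lo <= mode <= hi")
    }
    if (target_fractions[k] > 0 &&
        (tri["lo"] < bands$lo[k] || tri["hi"] > bands$hi[k])) {
      stop(sprintf(
        "compartment '%s' has target %.2f%% but HU range [%g, %g] leaves its band [%d, %d]",
        bands$name[k], target_fractions[k], tri["lo"], tri["hi"],
        bands$lo[k], bands$hi[k]))
    }
  }
  if (!gravity_axis %in% 1:3) stop("`gravity_axis` must be 1, 2 or 3")
  structure(list(
    condition = condition, grid_shape = grid_shape,
    voxel_spacing = voxel_spacing, target_fractions = target_fractions,
    compartment_hu = compartment_hu,
    gravity_axis = as.integer(gravity_axis),
    consolidation_jitter_mm = consolidation_jitter_mm,
    aorta_hu = aorta_hu, body_hu = body_hu, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default compartment CT-number distributions
#'
#' Triangular `(lo, mode, hi)` HU distributions per aeration compartment.
#' The healthy normally-aerated distribution peaks at -820 HU and tapers
#' off well before the poorly-aerated boundary (as in a well-aerated
#' lung's peaked histogram), while the ARDS poorly-aerated and nonaerated
#' distributions climb toward the -100 HU boundary and reach +200 HU,
#' reproducing the consolidation-dominated histogram whose upper tail the
#' exclusion bound clips under heavy noise.
#'
#' @param condition `"healthy"` or `"ards"`.
#' @return A 4 x 3 matrix (rows: hyperinflated, normally aerated, poorly
#'   aerated, nonaerated; columns `lo`, `mode`, `hi`).
#' @export
default_compartment_hu <- function(condition = c("healthy", "ards")) {
  condition <- match.arg(condition)
  m <- if (condition == "healthy") {
    rbind(c(-999, -950, -901),
          c(-900, -820, -540),
          c(-495, -400, -120),
          c(-95, 0, 195))
  } else {
    rbind(c(-999, -950, -901),
          c(-900, -800, -501),
          c(-500, -200, -101),
          c(-100, 50, 200))
  }
  dimnames(m) <- list(c("hyperinflated", "normally_aerated",
                        "poorly_aerated", "nonaerated"),
                      c("lo", "mode", "hi"))
  m
}

# midpoint-quantile realisation of a triangular(lo, mode, hi) distribution
triangular_quantiles <- function(n, lo, mode, hi) {
  if (n == 0L) return(numeric(0))
  if (hi == lo) return(rep(mode, n))
  u <- (seq_len(n) - 0.5) / n
  fm <- (mode - lo) / (hi - lo)
  ifelse(u < fm,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

# analytic mean of the triangular distribution
triangular_mean <- function(tri) sum(tri) / 3

# voxel-centre coordinates in mm, centred on the grid
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * spacing[ax])
}

# geometry masks: body shell, two lung ellipsoids, aortic insert.
# Proportions are fixed relative to the field of view; geometry does not
# affect any quantitative contract.
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  co <- grid_coords(d, spec$voxel_spacing)
  fov <- d * spec$voxel_spacing
  X <- array(co[[1]], d)
  Y <- array(rep(co[[2]], each = d[1]), d)
  body <- (X / (0.47 * fov[1]))^2 + (Y / (0.47 * fov[2]))^2 <= 1
  Z <- array(rep(co[[3]], each = d[1] * d[2]), d)
  sl <- c(0.178, 0.302, 0.417) * fov  # lung semi-axes, mm
  cx <- 0.244 * fov[1]
  lung <- ((X - cx) / sl[1])^2 + (Y / sl[2])^2 + (Z / sl[3])^2 <= 1 |
          ((X + cx) / sl[1])^2 + (Y / sl[2])^2 + (Z / sl[3])^2 <= 1
  lung <- lung & body
  # elongated paraspinal aortic insert between the lung fields
  ao_c <- c(0, 0.2 * fov[2])
  ao_s <- c(0.06, 0.227) * fov[1:2]
  aorta <- ((X - ao_c[1]) / ao_s[1])^2 + ((Y - ao_c[2]) / ao_s[2])^2 <= 1
  aorta <- aorta & body & !lung
  list(body = body, lung = lung, aorta = aorta)
}

#' Generate a ground-truth chest phantom
#'
#' Builds the noise-free HU volume described by a [phantom_spec()], its
#' true lung and aorta masks, and the exact quantitative result computed
#' on the noise-free volume. The construction is deterministic for a given
#' spec (including its seed). Compartment voxel counts are chosen by
#' largest-remainder allocation of `target / mean-density` weights, so the
#' noise-free mass fractions match the targets to well within 0.5
#' percentage points.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: `truth` (a [ct_volume()]),
#'   `lung_mask` (a [lung_mask()]), `aorta_mask` (logical array),
#'   `true_result` (a `qct_result`), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  d <- spec$grid_shape
  n_lung <- sum(geo$lung)
  if (n_lung < 100L) stop("grid too small: lung fields under 100 voxels")

  # voxel counts per compartment: mass fraction targets divided by the
  # mean voxel density of each compartment, largest-remainder rounding
  w_mean <- (apply(spec$compartment_hu, 1, triangular_mean) + 1000) / 1000
  raw <- spec$target_fractions / w_mean
  prop <- raw / sum(raw)
  counts <- floor(prop * n_lung)
  rem <- prop * n_lung - counts
  short <- n_lung - sum(counts)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }

  values <- unlist(lapply(1:4, function(k) {
    triangular_quantiles(counts[k], spec$compartment_hu[k, "lo"],
                         spec$compartment_hu[k, "mode"],
                         spec$compartment_hu[k, "hi"])
  }))
  comp_of <- rep.int(1:4, counts)

  lung_idx <- which(geo$lung)
  assigned <- with_seed(spec$seed, {
    if (spec$condition == "ards") {
      gco <- grid_coords(d, spec$voxel_spacing)[[spec$gravity_axis]]
      gpos <- gco[arrayInd(lung_idx, d)[, spec$gravity_axis]]
      score <- gpos + stats::rnorm(n_lung, 0, spec$consolidation_jitter_mm)
      ord <- order(score)  # least dense (hyperinflated) least dependent
    } else {
      ord <- sample.int(n_lung)
    }
    out <- numeric(n_lung)
    # shuffle HU values within each compartment block
    for (k in 1:4) {
      blk <- which(comp_of == k)
      if (length(blk)) out[ord[blk]] <- values[blk][sample.int(length(blk))]
    }
    out
  })

  vol <- array(-1000, d)
  vol[geo$body] <- spec$body_hu
  vol[geo$aorta] <- spec$aorta_hu
  vol[lung_idx] <- assigned

  truth <- ct_volume(vol, spec$voxel_spacing)
  lmask <- lung_mask(geo$lung, spec$voxel_spacing, source = "truth")
  stopifnot(!any(geo$lung & geo$aorta))
  true_result <- quantify(truth, lmask)
  dev <- abs(true_result$compartments$fraction_pct - spec$target_fractions)
  if (any(dev > 0.5)) {
    stop("internal error: noise-free fractions deviate from targets by > 0.5")
  }
  structure(list(truth = truth, lung_mask = lmask, aorta_mask = geo$aorta,
                 true_result = true_result, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Chest phantom (", x$spec$condition, "), grid ",
      paste(x$spec$grid_shape, collapse = " x "), ", lung ",
      round(x$true_result$total_volume_ml), " ml\n", sep = "")
  print(x$true_result)
  invisible(x)
}

#' Simulate a CT scan of a phantom at a given tube current
#'
#' Adds zero-mean Gaussian noise with SD `noise_sigma(acq$mAs, noise)` to
#' every voxel of the phantom's noise-free volume (lung, body and aorta
#' alike). Noise is independent per voxel; reconstruction-filter
#' correlation is not modelled, but `smooth_fwhm_mm > 0` applies an
#' isotropic Gaussian smoothing to the noise field (rescaled to preserve
#' the per-voxel SD) as a crude stand-in for filter correlation.
#'
#' @param phantom A [make_phantom()] result.
#' @param acq An [acquisition_settings()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draw.
#' @param smooth_fwhm_mm Full width at half maximum (mm) of optional noise
#'   smoothing; 0 (default) disables it.
#' @return A [ct_volume()] with `mAs` and `sigma_hu` recorded.
#' @export
simulate_scan <- function(phantom, acq, noise, seed = 1L, smooth_fwhm_mm = 0) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_settings"),
            inherits(noise, "noise_model"))
  sigma <- noise_sigma(acq$mAs, noise)
  vol <- phantom$truth$data
  if (sigma > 0) {
    eps <- with_seed(seed, array(stats::rnorm(length(vol), 0, sigma), dim(vol)))
    if (smooth_fwhm_mm > 0) {
      eps <- smooth_gaussian3(eps, smooth_fwhm_mm / 2.3548,
                              phantom$truth$spacing)
      s <- stats::sd(eps)
      if (s > 0) eps <- eps * (sigma / s)
    }
    vol <- vol + eps
  }
  ct_volume(vol, phantom$truth$spacing, mAs = acq$mAs, sigma_hu = sigma)
}

# separable Gaussian smoothing via shifted-array accumulation
smooth_gaussian3 <- function(a, sigma_mm, spacing) {
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(-r:r, sd = sv)
    k <- k / sum(k)
    acc <- a * k[r + 1]
    for (j in 1:r) {
      acc <- acc + k[r + 1 + j] * (shift3(a, ax, j) + shift3(a, ax, -j))
    }
    a <- acc
  }
  a
}
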