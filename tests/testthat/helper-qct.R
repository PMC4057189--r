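# shared fixtures, all generated in code

# a ct_volume with every voxel at `hu` (or a supplied array)
uniform_ct <- function(hu, dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  ct_volume(array(hu, dim), spacing)
}

full_mask <- function(ct, source = "manual") {
  lung_mask(array(TRUE, dim(ct$data)), ct$spacing, source = source)
}

# a degenerate "phantom" whose whole grid is lung at a single CT number;
# used where large voxel counts are needed without chest geometry
uniform_phantom <- function(hu, dim = c(100, 100, 100), spacing = c(1, 1, 1)) {
  truth <- ct_volume(array(hu, dim), spacing)
  mask <- lung_mask(array(TRUE, dim), spacing, source = "truth")
  structure(list(truth = truth, lung_mask = mask,
                 aorta_mask = array(FALSE, dim),
                 true_result = quantify(truth, mask), spec = NULL),
            class = "phantom")
}

# analytic oracle: expected 50-HU mass-fraction histogram of truth values
# `t` convolved with Gaussian(0, sigma), under the same rounding, clamping
# and exclusion rules as histogram_50hu. Independent closed form:
# E[(Y+1000) 1(L<Y<U)] = (t+1000)(Phi(zU)-Phi(zL)) - sigma(phi(zU)-phi(zL))
convolved_histogram_oracle <- function(t_values, sigma,
                                       scheme = compartment_scheme()) {
  n_bins <- ceiling((scheme$exclusion_hu + 1000) / 50)
  lo <- -1000 + 50 * (seq_len(n_bins) - 1)
  hi <- c(lo[-1] - 1, scheme$exclusion_hu)
  L <- lo - 0.5
  L[1] <- -1000          # below -1000 the clamp zeroes the mass
  U <- hi + 0.5
  U[n_bins] <- scheme$exclusion_hu  # raw values above the bound are excluded
  mass <- vapply(seq_len(n_bins), function(k) {
    zL <- (L[k] - t_values) / sigma
    zU <- (U[k] - t_values) / sigma
    sum((t_values + 1000) * (pnorm(zU) - pnorm(zL)) -
          sigma * (dnorm(zU) - dnorm(zL))) / 1000
  }, numeric(1))
  100 * mass / sum(mass)
}

# lookup-only noise model holding a fixed sigma at 60 mAs
fixed_sigma_model <- function(sigma) {
  noise_model(lookup = data.frame(mAs = 60, sigma = sigma))
}
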