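# densitometry: tissue fraction, compartment quantification, histograms

test_that("tissue fraction interpolates linearly between gas and tissue", {
  expect_equal(tissue_fraction(-1000), 0)
  expect_equal(tissue_fraction(0), 1)
  expect_equal(tissue_fraction(-300), 0.7)
  # clamping outside the analysed range
  expect_equal(tissue_fraction(-1500), 0)
  expect_equal(tissue_fraction(500), 1.2)
  expect_equal(tissue_fraction(200), 1.2)
})

test_that("compartment scheme covers [-1000, +200] contiguously", {
  sch <- compartment_scheme()
  comp <- sch$compartments
  expect_identical(comp$lo, c(-1000, -900, -500, -100))
  expect_identical(comp$hi, c(-901, -501, -101, 200))
  # raised exclusion bound extends the nonaerated ceiling
  sch5 <- compartment_scheme(exclusion_hu = 500)
  expect_equal(sch5$compartments$hi[4], 500)
})

test_that("uniform volume quantifies in closed form", {
  # 512,000 voxels of 0.625 x 0.625 x 5 mm at -300 HU:
  # volume = 512000 * 1.953125 mm3 = 1000 ml, mass = 1000 * 0.7 = 700 g
  ct <- uniform_ct(-300, dim = c(80, 80, 80), spacing = c(0.625, 0.625, 5))
  res <- quantify(ct, full_mask(ct))
  expect_equal(res$total_volume_ml, 1000)
  expect_equal(res$total_mass_g, 700)
  expect_equal(res$compartments$fraction_pct,
               c(0, 0, 100, 0))
  expect_equal(res$excluded_voxels, 0L)
})

test_that("mass weighting sets compartment fractions, not voxel counts", {
  # half the mask at -700 HU (w = 0.30), half at -50 HU (w = 0.95):
  # nonaerated fraction = 0.95 / (0.95 + 0.30) = 76%
  a <- array(-700, c(10, 10, 2))
  a[, , 2] <- -50
  ct <- ct_volume(a, c(1, 1, 1))
  res <- quantify(ct, full_mask(ct))
  expect_equal(res$compartments$fraction_pct[4], 76)
  expect_equal(res$compartments$fraction_pct[2], 24)
})

test_that("voxels above the exclusion bound yield an empty flagged result", {
  ct <- uniform_ct(300, dim = c(6, 6, 6))
  res <- quantify(ct, full_mask(ct))
  expect_equal(res$total_volume_ml, 0)
  expect_equal(res$total_mass_g, 0)
  expect_equal(res$excluded_voxels, res$n_voxels)
  expect_true(res$undefined_fractions)
  expect_true(all(is.na(res$compartments$fraction_pct)))
})

test_that("compartment membership rounds CT numbers half away from zero", {
  # -900.4 rounds to -900 (normally aerated); -900.6 to -901 (hyperinflated)
  a <- array(c(-900.4, -900.6, -100.4, -100.6, -500.4, -500.6, 199.6, -999),
             c(2, 2, 2))
  ct <- ct_volume(a, c(1, 1, 1))
  res <- quantify(ct, full_mask(ct))
  expect_equal(res$excluded_voxels, 0L)
  # hyperinflated: -900.6, -999 ; normal: -900.4, -500.6 ; poor: -500.4,
  # -100.6 ; non: -100.4, 199.6
  w <- (c(-900.6, -999, -900.4, -500.6, -500.4, -100.6, -100.4, 199.6) +
          1000) / 1000
  expect_equal(res$compartments$mass_g,
               1e-3 * c(sum(w[1:2]), sum(w[3:4]), sum(w[5:6]), sum(w[7:8])))
})

test_that("mass is conserved across the exclusion split", {
  set.seed(11)
  a <- array(runif(4000, -1100, 600), c(20, 20, 10))
  ct <- ct_volume(a, c(2, 2, 5))
  res <- quantify(ct, full_mask(ct))
  vox_ml <- prod(ct$spacing) / 1000
  total_no_exclusion <- vox_ml * sum(tissue_fraction(a))
  expect_equal(sum(res$compartments$mass_g) + res$excluded_mass_g,
               total_no_exclusion)
  expect_equal(res$total_volume_ml,
               (res$n_voxels - res$excluded_voxels) * vox_ml)
  expect_equal(sum(res$compartments$fraction_pct), 100)
})

test_that("fractions are invariant to voxel-volume rescaling", {
  set.seed(12)
  a <- array(runif(2000, -1000, 200), c(10, 10, 20))
  r1 <- quantify(ct_volume(a, c(1, 1, 1)), lung_mask(array(TRUE, dim(a)), c(1, 1, 1)))
  r2 <- quantify(ct_volume(a, c(0.625, 0.625, 5)),
                 lung_mask(array(TRUE, dim(a)), c(0.625, 0.625, 5)))
  expect_equal(r1$compartments$fraction_pct, r2$compartments$fraction_pct)
  expect_equal(r2$total_mass_g / r1$total_mass_g, prod(c(0.625, 0.625, 5)))
})

test_that("misaligned or empty masks are rejected", {
  ct <- uniform_ct(-500, dim = c(6, 6, 6))
  expect_error(quantify(ct, lung_mask(array(TRUE, c(5, 6, 6)), c(1, 1, 1))),
               "grid shapes")
  expect_error(quantify(ct, lung_mask(array(FALSE, c(6, 6, 6)), c(1, 1, 1))),
               "empty")
})

test_that("histogram puts a single-valued lung in its 50-HU bin", {
  ct <- uniform_ct(-300, dim = c(10, 10, 10))
  h <- histogram_50hu(ct, full_mask(ct))
  expect_equal(nrow(h$bins), 24L)
  expect_equal(sum(h$bins$fraction_pct), 100)
  hit <- h$bins$fraction_pct > 0
  expect_equal(h$bins$lo[hit], -300)
  expect_equal(h$bins$hi[hit], -251)
  expect_equal(h$bins$fraction_pct[hit], 100)
})

test_that("histogram bins align with compartment boundaries and sum to 100", {
  set.seed(13)
  a <- array(runif(8000, -1050, 250), c(20, 20, 20))
  ct <- ct_volume(a, c(1, 1, 1))
  h <- histogram_50hu(ct, full_mask(ct))
  expect_equal(nrow(h$bins), 24L)
  expect_equal(h$bins$lo, seq(-1000, 150, by = 50))
  expect_equal(sum(h$bins$fraction_pct), 100)
  # compartment masses equal the summed masses of their constituent bins
  res <- quantify(ct, full_mask(ct))
  agg <- vapply(seq_len(4), function(k) {
    sch <- compartment_scheme()$compartments
    sum(h$bins$fraction_pct[h$bins$lo >= sch$lo[k] & h$bins$hi <= sch$hi[k]])
  }, numeric(1))
  expect_equal(agg, res$compartments$fraction_pct, tolerance = 1e-10)
})

test_that("noisy uniform lung matches the Gaussian-convolved histogram", {
  ph <- uniform_phantom(-300, dim = c(100, 100, 100))
  sc <- simulate_scan(ph, acquisition_settings(60), fixed_sigma_model(74),
                      seed = 21)
  h <- histogram_50hu(sc, ph$lung_mask)
  oracle <- convolved_histogram_oracle(-300, 74)
  expect_lt(max(abs(h$bins$fraction_pct - oracle)), 0.2)
})
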