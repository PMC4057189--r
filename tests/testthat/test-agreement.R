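# Bland-Altman, paired tests, agreement tables, group ANOVA

test_that("identical series give zero bias and collapsed limits", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)
  expect_true(ba$degenerate)
  expect_equal(ba$p_paired, 1)
})

test_that("hand-computed example matches the 1.96 convention", {
  # diffs (1, 2, 3): bias 2, sd 1, limits 2 -/+ 1.96
  ba <- bland_altman(c(10, 12, 14), c(9, 10, 11))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 0.04)
  expect_equal(ba$loa_high, 3.96)
})

test_that("bland_altman agrees with a brute-force recomputation", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    ref <- rnorm(n, 50, 10)
    alt <- ref + rnorm(n, 1, 2)
    ba <- bland_altman(ref, alt)
    d <- ref - alt
    bias <- sum(d) / n
    sdd <- sqrt(sum((d - bias)^2) / (n - 1))
    expect_equal(ba$bias, bias)
    expect_equal(ba$sd_diff, sdd)
    expect_equal(ba$loa_low, bias - 1.96 * sdd)
    expect_equal(ba$loa_high, bias + 1.96 * sdd)
    # midpoint identity holds exactly
    expect_equal((ba$loa_low + ba$loa_high) / 2, ba$bias)
  }
})

test_that("swapping arms negates the bias and mirrors the limits", {
  set.seed(32)
  ref <- rnorm(15, 100, 20); alt <- rnorm(15, 95, 18)
  a <- bland_altman(ref, alt)
  b <- bland_altman(alt, ref)
  expect_equal(b$bias, -a$bias)
  expect_equal(b$loa_low, -a$loa_high)
  expect_equal(b$loa_high, -a$loa_low)
  expect_equal(b$p_paired, a$p_paired)
})

test_that("scaling both arms scales bias and limits, not the slope", {
  set.seed(33)
  ref <- rnorm(12, 10, 2); alt <- ref + rnorm(12, 0.5, 0.4) + 0.05 * ref
  a <- bland_altman(ref, alt)
  b <- bland_altman(10 * ref, 10 * alt)
  expect_equal(b$bias, 10 * a$bias)
  expect_equal(b$loa_low, 10 * a$loa_low)
  expect_equal(b$loa_high, 10 * a$loa_high)
  expect_equal(b$prop_slope, a$prop_slope)
  expect_equal(b$pair_r2, a$pair_r2)
})

test_that("paired test takes the t branch and matches the closed form", {
  # the heavily tied vector fails Shapiro-Wilk at 0.05, so relax the
  # normality gate to exercise the t branch on the textbook example
  d <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2)
  pt <- paired_test(rep(10, 10) + d, rep(10, 10), alpha_normality = 1e-4)
  expect_identical(pt$test, "t")
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(pt$p, 2 * stats::pt(-abs(tstat), 9))
  # smooth symmetric differences pass the gate at the default level
  d2 <- c(-0.8, 1.4, 0.3, -1.1, 0.9, 2.1, -0.2, 1.2, 0.5, -0.6)
  pt2 <- paired_test(d2, rep(0, 10))
  expect_identical(pt2$test, "t")
  expect_equal(pt2$p, stats::t.test(d2)$p.value)
})

test_that("skewed differences select the signed-rank branch", {
  d <- c(0.01, 0.02, 0.01, 0.03, 0.02, 0.01, 9, 11, 14, 0.02, 0.01, 0.03)
  expect_lt(stats::shapiro.test(d)$p.value, 0.05)
  pt <- paired_test(d + 5, rep(5, length(d)))
  expect_identical(pt$test, "wilcoxon")
})

test_that("all-zero differences are flagged degenerate with p = 1", {
  pt <- paired_test(c(4, 4, 4, 4), c(4, 4, 4, 4))
  expect_equal(pt$p, 1)
  expect_true(pt$degenerate)
})

test_that("agreement tables carry the standard measures and columns", {
  ph <- make_phantom(phantom_spec("healthy", grid_shape = c(32, 32, 24),
                                  seed = 20))
  nm <- fixed_sigma_model(16)
  pairs <- lapply(1:4, function(i) {
    r <- quantify(simulate_scan(ph, acquisition_settings(60), nm, seed = i),
                  ph$lung_mask)
    a <- quantify(simulate_scan(ph, acquisition_settings(60), nm, seed = 100 + i),
                  ph$lung_mask)
    list(ref = r, alt = a)
  })
  tab <- compare_pairs(pairs)
  expect_identical(tab$measure,
                   c("lung_volume_ml", "lung_tissue_mass_g",
                     "hyperinflated_pct", "normally_aerated_pct",
                     "poorly_aerated_pct", "nonaerated_pct"))
  expect_true(all(c("mean_ref", "sd_ref", "mean_alt", "sd_alt", "p", "r2",
                    "bias", "loa_low", "loa_high") %in% names(tab)))
  expect_true(all(tab$loa_low <= tab$bias & tab$bias <= tab$loa_high))
  # identical pairs collapse to zero bias, p flagged 1
  same <- lapply(pairs, function(pr) list(ref = pr$ref, alt = pr$ref))
  tab0 <- compare_pairs(same)
  expect_true(all(tab0$bias == 0))
  expect_true(all(tab0$p == 1))
})

test_that("histogram comparison flags nothing for identical pairs and is
           antisymmetric under arm swapping", {
  ph <- make_phantom(phantom_spec("ards", grid_shape = c(32, 32, 24),
                                  seed = 21))
  nm <- fixed_sigma_model(30)
  hp <- lapply(1:5, function(i) {
    r <- histogram_50hu(simulate_scan(ph, acquisition_settings(60), nm,
                                      seed = i), ph$lung_mask)
    a <- histogram_50hu(simulate_scan(ph, acquisition_settings(60), nm,
                                      seed = 50 + i), ph$lung_mask)
    list(ref = r, alt = a)
  })
  same <- lapply(hp, function(pr) list(ref = pr$ref, alt = pr$ref))
  cmp0 <- compare_histograms(same)
  expect_equal(sum(cmp0$significant), 0L)
  cmp <- compare_histograms(hp)
  swapped <- compare_histograms(lapply(hp, function(pr)
    list(ref = pr$alt, alt = pr$ref)))
  expect_equal(swapped$mean_diff, -cmp$mean_diff)
  expect_equal(swapped$p, cmp$p)
})

test_that("group ANOVA handles degenerate and two-group cases", {
  expect_error(group_anova(list(c(1, 2))), "2 groups")
  g0 <- group_anova(list(c(3, 3, 3), c(3, 3, 3)))
  expect_equal(g0$F, 0)
  expect_equal(g0$p, 1)
  gI <- group_anova(list(c(3, 3, 3), c(5, 5, 5)))
  expect_equal(gI$F, Inf)
  expect_equal(gI$p, 0)
  # with two groups the F statistic equals the squared pooled t
  a <- c(4.1, 5.2, 6.0, 5.5, 4.8, 5.1)
  b <- c(6.1, 7.0, 6.5, 7.4, 6.9, 6.6)
  res <- group_anova(list(a, b))
  expect_false(res$rank_transformed)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
})

test_that("reference-calibrated noise groups separate decisively", {
  tab <- reference_noise_table()
  hits <- 0L
  set.seed(77)
  for (r in 1:200) {
    groups <- lapply(seq_len(nrow(tab)), function(i)
      rnorm(10, tab$sigma[i], tab$sigma_sd[i]))
    if (group_anova(groups)$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})
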