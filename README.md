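# qctlung

Quantitative CT (qCT) lung densitometry and low-dose agreement analysis.

Serial quantitative CT can characterise lung aeration in ARDS and guide
mechanical ventilation, but repeated scanning accumulates radiation dose.
Dose scales linearly with the tube current–time product (mAs), and lowering
mAs raises image noise — which perturbs the voxel-level density
measurements qCT is built on. `qctlung` implements the full methodology for
asking *how low the dose can go before quantitative results change*:

* **Densitometry** (`quantify()`, `histogram_50hu()`): every lung voxel is
  a gas/tissue mixture with tissue fraction `(HU + 1000)/1000`; the package
  computes total lung volume, tissue mass, the mass split over the four
  aeration compartments — hyperinflated (−1000..−901 HU), normally aerated
  (−900..−501), poorly aerated (−500..−101), nonaerated (−100..+200) — and
  the 50-HU mass-frequency histogram. Voxels above +200 HU are excluded
  (configurable), voxels below −1000 HU clamped.
* **Digital chest phantoms** (`make_phantom()`, `simulate_scan()`):
  seeded ground-truth phantoms with healthy or ARDS compartment
  compositions, dependent consolidation along the gravity axis, a uniform
  aortic insert for noise measurement, and an mAs-dependent Gaussian noise
  model calibrated to measured scanner noise (10.0/15.9/37.5/73.8 HU at
  140/60/15/7.5 mAs).
* **Lung segmentation** (`segment_lungs_auto()`): threshold + connected
  components + closing/hole-filling, accurate for high-contrast healthy
  lungs, with an explicit warning when consolidation makes a manual mask
  necessary.
* **Agreement statistics** (`bland_altman()`, `compare_pairs()`,
  `compare_histograms()`, `group_anova()`): Bland–Altman bias and 1.96
  limits of agreement on reference-minus-alternative differences,
  automatic paired t / Wilcoxon selection, per-bin histogram tests,
  one-way ANOVA with rank fallback.
* **Dosimetry** (`ctdi_vol()`, `effective_dose()`, `dose_reduction()`,
  `estimate_noise()`): CTDIvol linear in mAs, DLP, effective dose by the
  DLP method (E = DLP × k), and aortic-ROI noise estimation.
* **Pipeline** (`run_paired_study()`): the whole paired 60-mAs-reference
  study — simulate, quantify, aggregate agreement/histogram/dose tables —
  fully reproducible from one seed.

## Worked example

```r
library(qctlung)

ph <- make_phantom(phantom_spec("ards", seed = 5))
scan60  <- simulate_scan(ph, acquisition_settings(60),  default_noise_model(), seed = 1)
scan7.5 <- simulate_scan(ph, acquisition_settings(7.5), default_noise_model(), seed = 2)
quantify(scan7.5, ph$lung_mask)
```

```
qCT result over 46712 voxels
  total lung volume: 2220.4 ml
  total tissue mass: 1652.6 g
  hyperinflated          2.2 g    0.13 %
  normally_aerated     154.5 g    9.35 %
  poorly_aerated       488.9 g   29.58 %
  nonaerated          1006.9 g   60.93 %
  excluded (> 200 HU): 1238 voxels, 72.5 g
```

Against the noise-free truth (0.0 / 9.1 / 27.3 / 63.6 % and 2280.9 ml),
the 7.5-mAs scan has shifted nonaerated mass into the poorly aerated band
and pushed 1238 voxels above the +200 HU exclusion bound, shrinking the
measured volume — the two mechanisms that degrade ultra-low-dose qCT.
At 60 mAs (`quantify(scan60, ph$lung_mask)`) the fractions stay within
0.1 point of truth. Dose side:

```r
dose_reduction(7.4, 2.0)   # 60 -> 15 mAs: 73 (% effective-dose reduction)
dose_reduction(7.4, 0.9)   # 60 -> 7.5 mAs: 88
```

A command-line wrapper for simulate/segment/analyze/dose lives at
`inst/scripts/qct.R`.

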