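# radstab

Reproducibility of handcrafted radiomic features (HRFs) across in-plane
CT resolutions — with and without resampling and ComBat harmonization.

## What this is for

Radiomic features are statistics of the sampled image, so two scans of the
same object reconstructed at different in-plane pixel spacings yield
different feature values. Anyone pooling CT radiomics across scanners or
protocols faces three questions: which features survive a change of
in-plane resolution as-is, whether resampling every scan to a new unified
in-plane resolution (NUIR) with a given interpolation method rescues more
of them, and what ComBat batch harmonization contributes. `radstab`
answers these on a controlled synthetic phantom and provides the same
machinery for real NIfTI/DICOM data with supplied ROI masks.

The package implements, from scratch and fully tested:

- a **digital texture phantom**: one fixed 10-layer scene (≈ −900 to
  +700 HU) imaged by two virtual scanner models at seven pixel spacings
  (0.39–0.98 mm, slice thickness 1.25 mm) — 14 scans of one object;
- **in-plane resampling** with ten interpolation methods: `NN`, `Linear`,
  `BSpline`, `Gaussian`, `LabelGaussian` (masks), and the Hamming, Cosine,
  Welch, Lanczos and Blackman windowed sincs (`HWS`, `CWS`, `WWS`, `LWS`,
  `BWS`), kernels `k(x) = w(x)·sinc(x)` with half-width m = 3;
- **91 handcrafted features** per ROI (18 first-order; 22 GLCM, 16 GLRLM,
  16 GLSZM, 14 GLDM, 5 NGTDM) after fixed-bin-width discretization
  (25 HU), texture matrices accumulated in C++ and checked exactly against
  naive reference implementations;
- **parametric ComBat**: `Y = α + Xβ + γᵢ + δᵢε` per feature, empirical-
  Bayes posteriors `γ*`, `δ*`, harmonized values `σ(Z − γ*)/δ* + α + Xβ`,
  applied pairwise (two scans = two batches) after a near-zero-variance
  filter; verified against the published implementation to 1e-4;
- **concordance analysis**: Lin's CCC
  `ρ_c = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` per feature over ROI-matched
  scan pairs, reproducible iff CCC > 0.9, 21 pairs per scanner model,
  all-pairs intersection, and greedy Spearman de-duplication (|ρ| > 0.90).

Four approaches are compared, as in resolution-harmonization studies:
(i) original features; (ii) original + pairwise ComBat; (iii) resampled to
a NUIR with one method; (iv) resampled + pairwise ComBat.

## Worked example

```r
library(radstab)

dataset <- make_dataset(base_seed = 101)          # 14 seeded scans
rep_i   <- run_approach(scenario_config("i", "Discovery-STE"), dataset)
rep_iii <- run_approach(scenario_config("iii", "Discovery-STE",
                                        im = "CWS", nuir_mm = 0.98), dataset)
rep_i
#> <run_report> approach (i), Discovery-STE: 21 pairs, counts 22-81 (median 51), intersection 18
rep_iii
#> <run_report> approach (iii), Discovery-STE, CWS @ 0.98 mm: 21 pairs, counts 42-88 (median 68), intersection 32
render_tables(rep_i)[1:2, 1:2]
#>           SYN-1-001    SYN-1-002
#> SYN-1-002 "73 (80.2%)" ""
#> SYN-1-003 "50 (54.9%)" "61 (67.0%)"
```

Read: on the original scans, between 22 and 81 of the 91 features are
concordant (CCC > 0.9) per scan pair — fewer the larger the spacing
difference — and 18 features survive every pair. Resampling all seven
scans to 0.98 mm with the cosine windowed sinc lifts the per-pair counts
and nearly doubles the always-reproducible set (18 → 32). The
`analysis/01…05` scripts run this narrative end to end and write the
tables (scan manifest, feature CSV, lower-triangular count matrices,
ComBat increments, interpolation sweep) under `results/`.

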