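# mrisynth

Cross-contrast brain MRI synthesis with a radiomic evaluation schema.

Brain MRI is acquired in several contrasts — T2-weighted (T2W) images show
fluid bright, FLAIR suppresses it — and when one contrast is missing or
degraded, a generative model can translate the other into it. The hard part
is judging the result: pixel metrics (MAE, MSE, PSNR) measure intensity
agreement but not whether the *texture statistics* that quantitative imaging
relies on survive translation. This package provides both sides of that
problem for researchers working on medical image synthesis:

* **Translation models.** A CycleGAN-style unpaired model (two generators
  `G_A2B`, `G_B2A` with 9-residual-block architecture, two patch
  discriminators) and a semi-supervised dual cycle-consistent variant whose
  conditional discriminators score (source, candidate) pairs and whose
  supervised objective adds voxel-wise L1, gradient-difference, perceptual
  and structural (1 − SSIM) losses with unit weights:

      L_sup = L_adv + L_cyc + L_voxel + L_gradient + L_perceptual + L_structural

  The CycleGAN objective is `λ_GAN (L_GAN(G_A2B, D_B) + L_GAN(G_B2A, D_A)) +
  λ_cyc L_cyc` with defaults λ_cyc = 10, λ_GAN = 1, trained with Adam at
  learning rate 2·10⁻⁴ (constant, then linear decay to 0) and a 3:1
  generator:discriminator update ratio. Networks and hand-derived
  backpropagation are implemented in R with C++ convolution kernels; every
  backward pass is verified against finite differences in the test suite.

* **Radiomic evaluation.** Images are min-max normalized, discretized to 20
  gray levels over the masked range, and summarized by 23 texture features:
  8 from the gray-level co-occurrence matrix (radius 1, four offsets pooled),
  7 from the run-length matrix, 8 from the size-zone matrix. For each
  feature, real and synthetic distributions are compared with a
  normality-gated test — D'Agostino–Pearson K² on both groups, then Welch's
  t-test if both pass, otherwise Mann–Whitney U with a Hodges–Lehmann
  interval — and a feature is flagged exactly when the 95% CI of the
  difference excludes 0.

* **Fidelity metrics and a phantom generator.** `fidelity()` implements
  MAE, MSE and PSNR = 10·log₁₀(MAX²/MSE); `generate_phantom_dataset()`
  produces seeded, aligned pseudo-T2W/FLAIR slice pairs with a known
  tissue-dependent contrast remapping, and `degrade()` makes corrupted
  copies with a tunable level, so the whole pipeline is testable without
  patient data.

## Worked example

Score degraded copies of phantom slices against the originals:

```r
library(mrisynth)

pair <- generate_phantom_pair(64, tissue_model(seed = 7))
fidelity(pair$image_B, degrade(pair$image_B, 0.5, seed = 1))
#> <fidelity> MAE 0.0256053  MSE 0.00154244  PSNR 27.29 dB  (n = 4096, MAX = 0.9094)

ds <- generate_phantom_dataset(12, size = 32, base_seed = 1)
feats_real  <- t(sapply(ds, function(p) extract_features(p$image_B, p$mask)))
feats_synth <- t(sapply(seq_along(ds), function(i)
  extract_features(degrade(ds[[i]]$image_B, 0.8, seed = i), ds[[i]]$mask)))
build_report(feats_real, feats_synth)
#> Radiomic comparison report (alpha = 0.05, n = 12 real / 12 synthetic)
#> 16 of 23 features significantly different
#>
#>    family feature            mean_real        mean_synth       test_used ci
#> 1  GLCM   Auto Correlation   131.5 ± 17       115.7 ± 9.3      t  [-25.26, 56.88]
#> 2  GLCM   Cluster Prominence 1.626e+04 ± 2900 4452 ± 510       t  [5299, 1.832e+04] *
#> ...
```

The MAE of 0.026 on a [0, 1] intensity scale says the corrupted copies are
numerically close, yet 16 of 23 texture features differ significantly —
the schema detects texture damage that pixel metrics underplay. For an
identical pair of image sets the report flags 0 of 23 features.

A one-command demonstration — generate phantoms, train a toy CycleGAN,
translate held-out slices, and produce `fidelity.csv`, `features_*.csv` and
`report.csv`:

```r
run_full_demo("demo_out", n_pairs = 30, size = 32, epochs = 5, seed = 1)
```

The same steps are scriptable from a shell via `inst/scripts/synth`
(subcommands `generate`, `train`, `translate`, `features`, `fidelity`,
`compare`, `demo`).

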