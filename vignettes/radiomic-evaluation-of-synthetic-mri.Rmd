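---
title: "Radiomic evaluation of synthetic MRI: models, features, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic evaluation of synthetic MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisynth)
```

## The problem this package addresses

Structural brain MRI is usually acquired in several contrasts.  T2-weighted
(T2W) and FLAIR images show the same anatomy under different tissue
weightings: on T2W, fluid (CSF, ventricles) is bright; on FLAIR the fluid
signal is suppressed while lesions remain conspicuous.  When one contrast is
missing or motion-degraded, a generative model can translate the available
contrast into the missing one.  The scientific question is then: *how do we
decide whether a synthetic image is good?*

Pixel-agreement metrics (MAE, MSE, PSNR) measure intensity fidelity but say
little about whether the *texture statistics* that radiomic analyses rely on
are preserved.  This package implements both views:

1. cycle-consistent adversarial translation models between two MRI-like
   contrasts (an unpaired CycleGAN-style model and a semi-supervised dual
   cycle-consistent variant with four extra aligned losses), and
2. an evaluation schema that extracts 23 standard texture features (8 GLCM,
   7 GLRLM, 8 GLSZM) from real and synthetic images and tests, feature by
   feature, whether the two distributions differ.

A synthesis method passes the radiomic evaluation when few or no features
differ significantly between real and synthetic groups.

## The phantom generator

Real paired T2W/FLAIR data cannot ship with a package, so all tests and
demonstrations run on a seeded phantom: an elliptical "brain" with nested
elliptical regions — outer tissue, a white-matter-like band, a central
fluid-like region, and optional lesion blobs — rendered in two contrasts by
per-class mean intensities plus independent Gaussian noise
(`tissue_model()`, `generate_phantom_pair()`).

The defaults encode the qualitative physics of the two contrasts: the
fluid-like class is bright in domain A (0.90) and dark in domain B (0.10),
mimicking fluid attenuation, while lesions brighten in domain B (0.85 vs
0.70).  The cross-contrast mapping is therefore a deterministic,
tissue-dependent intensity remapping — exactly the structure a translation
network can learn — and the acquisition noise (sigma = 0.02 in intensity
units, drawn independently per domain) is the simplest model of
scanner-to-scan variation.  Geometry (ellipse axes, rotation, lesion count
and placement) is randomized per slice from the slice seed, so a dataset has
anatomical variety while remaining bit-reproducible.

What the phantom does **not** emulate: MRI acquisition physics (k-space
sampling, bias fields, partial-volume effects), 3D structure, registration
error, and pathology heterogeneity.  Passing tests on phantoms therefore
demonstrates the correctness of the algorithms and the sensitivity of the
evaluation schema, not clinical performance on real scans.

`degrade(image, level, seed)` produces controlled "synthetic-quality"
surrogates by blending in a smoothed copy and adding noise, both scaled by
`level`; `level = 0` is the exact identity.  It gives the evaluation schema
a dial with known monotone ground truth.

## Feature extraction

All texture analysis runs on a `quantize()`d image: intensities are min-max
normalized, then mapped to integer gray levels 1..B over the *masked* range
with a fixed number of equal-width bins.  The extraction defaults are 20
bins, co-occurrence radius 1, "combined" offsets, and 8-connected zones.
Two conventions deserve comment:

* **Bin count vs bin width.**  The extraction parameter is a fixed *number*
  of bins (20) whose width is derived per slice from the in-mask intensity
  range.  With per-slice min-max normalization to [0, 1] beforehand, a
  fixed bin count and a fixed bin width of 1/20 coincide, which is why the
  two descriptions of the discretization are interchangeable here.
* **Masked-range discretization.**  Minimum and maximum are taken over the
  mask only, so background pixels can never stretch the bin grid.

The three matrices are built per slice (2D), matching the 2D slice inputs of
the translation models:

* **GLCM** — in-mask pixel pairs at displacement (0,1), (1,0), (1,1),
  (1,−1), symmetrized (both orders counted), pooled over the four offsets
  *before* normalization, giving one merged probability matrix rather than
  per-offset feature averages.  Features: auto correlation, cluster
  prominence, cluster shade, contrast, correlation, energy, entropy (log2,
  with 0·log 0 = 0), homogeneity in the inverse-difference form
  1/(1+|i−j|).  For a constant image the marginal variance vanishes and
  correlation is defined as 0, flagged on the result.
* **GLRLM** — maximal runs of equal level along the same four directions,
  with mask gaps breaking runs; counts accumulate over directions, so
  `sum(j * r(i,j))` equals (in-mask pixels) × (directions).
* **GLSZM** — 8-connected components of equal-level in-mask pixels (the
  common default for 2D zone growth); zones partition the mask exactly.

Gray levels are indexed from 1 so that every low-gray-level emphasis term
(1/i²) is finite.  With combined offsets the whole feature vector is
invariant under 90° rotation of the image, and pixels outside the mask
provably never influence any matrix — both properties are asserted in the
test suite, and every matrix and feature is validated against an
independent brute-force enumerator to 1e-10 on a hundred random images.

## Fidelity metrics

`fidelity()` computes MAE, MSE and PSNR = 10·log10(MAX²/MSE) over the
evaluated pixels.  MAX is the largest value over *both* images of the pair,
which makes all three metrics symmetric in their arguments; PSNR is +Inf
exactly when MSE = 0, and such pairs are excluded from (and counted next
to) the across-pair PSNR summary.  Metrics run on whole images by default —
the defining sums range over all voxels — with an optional mask restriction
for brain-only scoring.  Across-pair summaries report mean and *population*
standard deviation, avoiding a degrees-of-freedom convention in a
"mean ± spread" display.

## The statistical comparison

For each of the 23 features, `compare_feature()` applies a normality-gated
two-sample comparison of real versus synthetic values:

* Normality is assessed per group by the D'Agostino–Pearson omnibus test
  (K² = z²(skewness) + z²(kurtosis) against chi-squared with 2 df),
  implemented in the package and verified against an independent reference
  implementation to full precision.  The omnibus statistic needs n ≥ 8;
  smaller samples fall back to the nonparametric path, as does a
  zero-variance sample (treated as "not normal").
* If **both** groups pass at the chosen alpha — the literal reading of the
  gate — an unpaired Welch t-test supplies the 95% CI of the mean
  difference (real − synthetic).  Welch is the safe default absent any
  variance-homogeneity check.
* Otherwise the Mann–Whitney U test is used, with the Hodges–Lehmann
  estimate of the location difference and its distribution-free CI.  If the
  interval inversion fails under heavy ties, a manual CI from the sorted
  pairwise differences (normal-approximation rank indices) takes over.

Significance is *defined* as "the CI of the difference excludes 0"; for the
t path this coincides with p < alpha and the test suite asserts that
consistency.  The tests are unpaired even though slices are aligned, since
the schema compares group distributions (means ± SE per group); no
multiple-testing correction is applied across the 23 features — each row is
reported on its own, and the headline count of significant features should
be read with that in mind.  Both choices are configurable points of
departure for stricter analyses.  Under the null both paths are calibrated:
with 50 samples per group the rejection rate at alpha = 0.05 sits in
[0.03, 0.07] over 2000 replicates for either path.

## Translation models

Both models use the same generator: 7×7 convolution → two stride-2
downsampling convolutions → residual blocks → two nearest-neighbor
upsample + convolution stages → 7×7 output convolution, instance
normalization throughout, sigmoid output so generated images live in
[0, 1] like their inputs (matching the [0, 1] tensor convention of the
data).  The reference depth is 9 residual blocks at 256×256; desk-scale
runs shrink width and depth, not the architecture shape.

The patch discriminator scores local patches with strided convolutions,
instance normalization and leaky ReLU.  The dual cycle-consistent model's
discriminator is *conditional*: it consumes the (source, candidate) pair as
a 2-channel input, so its verdict depends on whether the candidate matches
the source anatomy.

Losses:

* adversarial, in the log (cross-entropy) form with probability clamping
  (a least-squares switch is provided);
* cycle consistency: L1 of both round trips, weight lambda_cyc = 10 against
  lambda_GAN = 1;
* for the supervised model, four aligned terms with unit weights —
  voxel-wise L1, gradient difference (L1 between finite-difference gradient
  magnitudes along rows and columns), perceptual (L1 between intermediate
  discriminator feature maps — chosen over a pretrained feature network so
  the package has no external-weight dependency), and structural
  (1 − mean SSIM, 11×11 Gaussian window, standard constants).

Training follows the reference schedule: Adam (beta1 = 0.5, beta2 = 0.999,
weight init normal(0, 0.02), no image-history buffer), batch size 2,
learning rate 2e-4 held for the first half then decayed linearly to exactly
0, and per step 3 generator updates followed by 1 discriminator update —
the literal reading of a 3:1 generator:discriminator iteration ratio.  The
semi-supervised model alternates one supervised and one unsupervised step
across batches (the alternation ratio is configurable; an even split is the
neutral default since no ratio is prescribed).  All backward passes are
derived by hand and checked against central finite differences in the test
suite; training aborts with a diagnostic if any loss goes non-finite.

## Numerical and scale choices

* Convolution forward/backward is an im2col gather plus GEMM, with the hot
  loops in C++; everything else is vectorized R.
* Probability clamping at 1e-7 keeps the log losses finite for saturated
  discriminator scores.
* Desk-scale test runs use 32×32 slices, 4 base channels and 1 residual
  block for about fifty training pairs and thirty epochs — small enough for
  a laptop CPU, large enough that a trained model reliably beats an
  untrained one on held-out slices; the statistical checks use 50 slices
  per group and 2000-replicate nulls.  Full-scale settings (256×256,
  64 channels, 9 blocks, 400 epochs) remain the configuration defaults.
* Phantom lesion count is 0–2 per slice; lesion radii 5–10% of the image
  side; brain mask fraction lands in (0.1, 0.9) by construction.

## Known limitations

* 2D only; no volumetric features or 3D generators.
* The phantom's contrast change is piecewise-constant with Gaussian noise;
  real cross-contrast relationships include spatially varying effects the
  generator family here does not model.
* The GLSZM gray-level nonuniformity is reported unnormalized
  (sum of squared level counts over total zones); toolkits differ on this
  normalization, so absolute values are comparable only within one
  convention.
* The GLCM correlation is the Pearson-style moment form with a
  0-by-convention for degenerate images; published values computed with
  other variants can differ in scale.
* No multiple-testing correction and no paired-test mode in this version
  (see above).
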