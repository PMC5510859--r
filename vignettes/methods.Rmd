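---
title: "Methods: ADC texture analysis and the synthetic phantom cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADC texture analysis and the synthetic phantom cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxtex)
```

## The analysis model

`myxtex` implements a three-stage analysis of diffusion-weighted MRI (DWI) of
myxoid-containing soft-tissue tumors: (1) voxelwise apparent diffusion
coefficient (ADC) mapping, (2) extraction of thirteen texture features from
the tumor ROI, (3) a cohort statistical layer comparing benign and malignant
groups. The scientific premise is that benign and malignant myxoid tumors
differ less in their *marginal* ADC distribution than in its *spatial
arrangement* — benign (mostly neurogenic) tumors carry a fibrous center with
a myxoid periphery and a rough internal texture, malignant myxoid tumors are
spatially homogeneous — so local (co-occurrence) statistics should
discriminate where the mean ADC does not.

### ADC fitting

The signal model is mono-exponential, `S(b) = S0 exp(-b·ADC)`, sampled at
b = 0, 400, 800 s/mm². `fit_adc()` estimates ADC per voxel as minus the
least-squares slope of `ln S` against `b`, jointly over all b-values — the
standard reading of "exponential fitting over three b-values". Numerical
policies:

* voxels with non-positive signal at some b drop those points and fit the
  remainder if at least two points survive; otherwise the voxel is `NA`
  (undefined) and excluded downstream — background and fully attenuated
  voxels must not abort a cohort run;
* negative fitted slopes (possible under noise) clamp to ADC = 0 by default
  (`clamp_negative = FALSE` preserves the raw slope);
* the fit is unweighted in the log domain. A weighted or two-point variant
  could be substituted; the unweighted three-point log-linear fit is the
  simplest defensible choice and is recorded in the run manifest.

Assumptions: no perfusion/IVIM bi-exponential component, no kurtosis term, no
motion or eddy-current correction — all deliberately out of scope.

### Texture features

Global features (mean, SD, skewness, kurtosis) are computed on the **raw**
ADC values in the ROI; only the regional/local features use the quantized
map. This ordering mirrors the analysis pipeline the package reproduces:
histogram first, then resampling "for regional and local texture analysis".
Kurtosis is non-excess (`m4/m2²`, Gaussian → 3) and SD uses the n−1
denominator; both conventions are fixed by the observation that published
benign-group kurtosis sits at the Gaussian value of ~3.7, far from 0.7, which
an excess convention would give.

Quantization is equal-width binning of the per-ROI `[min, max]` range into
L = 64 levels, `level = 1 + floor(L(x−min)/(max−min))` with the maximum
clamped to L. Equal-width min–max binning is the dominant radiomics
convention consistent with a stated 1..64 range; a constant ROI maps to
level 1. Note the consequence exercised throughout the tests: min–max
normalization makes all level-space features invariant to affine rescaling
of the ADC values but *sensitive to outliers*, which stretch the range and
compress the bulk.

The GLSZM counts maximal connected components ("zones") of equal level.
Connectivity is 26 (faces, edges, corners) by default, 6 selectable —
unspecified in the source description; 26 is the common radiomics default.
Zone labelling is delegated to `igraph::components()` on the equal-level
adjacency graph; tests verify it against an explicit flood-fill oracle.
The two regional features are quadratic-over-linear functionals of the zone
table (`glszm_features()`); both have floor 1 and scale linearly under zone
duplication, and size-zone variability grows with ROI size — which is why
the covariate-adjusted analysis treats tumor volume as a confounder.

The GLCM accumulates ordered level pairs over the 13 unique 3D offsets at
1-voxel distance (the 26-neighbourhood modulo sign), symmetrizes, normalizes
each direction to sum 1, then averages the directions (equal weight per
direction, matching "averaged each GLCM direction"; directions without valid
pairs are skipped and the average renormalized). Offsets are measured in
index space: with 5 mm slices against 1.25 mm in-plane pixels a
physical-distance GLCM would be a different analysis than the voxel-distance
one described. The seven Haralick features follow the standard formulas
(see `?glcm_features`); entropy uses the natural logarithm by default with
base 2 selectable, since the log base is not fixed by the source and both
conventions circulate. Correlation follows the standard Haralick
normalization, which yields values spanning roughly (−1, 1); published
values of 0.007–0.014 for this analysis suggest a non-standard in-house
normalization that we deliberately do not attempt to reverse-engineer.

### Statistics

* Normality: one-sample KS against a normal with estimated moments is
  anti-conservative, so `ks_normality()` applies the Lilliefors correction
  (`nortest::lillie.test`).
* Group means: pooled-variance Student t-test (`var_equal = FALSE` gives
  Welch).
* Sex ratios: Pearson chi-square without Yates correction — the uncorrected
  test reproduces the published p = 0.289 for the 23 (12F:11M) vs
  17 (6F:11M) table, which fixes the convention.
* ANCOVA: OLS of `feature ~ group + age + sex + volume`; the adjusted p is
  the partial t-test of the group coefficient. Rank-deficient designs (e.g.
  a single-sex cohort) raise an error naming the collinear column.
* ROC: empirical AUC (Mann–Whitney with half credit for ties), oriented so
  AUC ≥ 0.5; the reported direction is the positive-call rule (`>` or `≤`
  threshold). The operating threshold maximizes Youden's J over observed
  values, ties broken toward higher specificity (a deterministic rule is
  needed; specificity was chosen because the clinical cost of a false
  positive here is an unnecessary biopsy). Sensitivity/specificity carry
  Clopper–Pearson exact CIs. The AUC carries a DeLong CI and z-test against
  0.5, plus an auxiliary "binomial exact" CI (Clopper–Pearson on the winning
  fraction of case–control pairs) because the original analysis reports
  binomial-exact intervals; DeLong is the default since the pairwise
  comparisons require its covariance structure anyway, and the choice is
  logged in the manifest.
* Pairwise AUCs: paired DeLong tests; the Bonferroni multiplier is the
  number of pairs actually performed. Both raw and adjusted p-values are
  reported, since published pairwise tables of this kind are ambiguous about
  which is shown.
* AUC discriminatory-power bins: 0.9–1 excellent, 0.8–0.9 good, 0.7–0.8
  fair, 0.6–0.7 poor, 0.5–0.6 failure (lower bound inclusive).

A calibration caveat the tests document explicitly: at n = 40 the paired
DeLong null distribution is discrete (AUC differences move in steps of
1/(23·17)) and the z-test is conservative — null rejection runs well below
nominal and the p-values are not KS-uniform. The inferentially relevant
property, rejection never exceeding the nominal level, holds and is tested.

## The phantom cohort: what it emulates

No image data are publicly deposited for this tumor entity, so the package
generates a synthetic cohort with the statistical structure the analysis
assumes. Design (all defaults frozen in `phantom_spec()`/`cohort_spec()`):

* **Benign archetype**: concentric two-compartment ellipsoid — low-ADC core
  (1.40×10⁻³ mm²/s) inside 0.794 of the radius (half the volume), high-ADC
  rim (2.70×10⁻³), volume-weighted mean ≈ 2.05×10⁻³ — plus Gaussian jitter
  of SD 0.22×10⁻³ with 1 mm correlation length (spatially rough). The
  concentric geometry encodes the fibrous-center/myxoid-periphery histology.
* **Malignant archetype**: uniform 1.914×10⁻³ plus Gaussian jitter of SD
  0.33×10⁻³ with 8 mm correlation length — wide but slowly varying
  diffusivity. The means follow the published group means of mean ADC.
* The jitter field is smoothed white noise (FFT convolution with a Gaussian
  kernel, periodic boundary), **mean-centered** and rescaled to the target
  SD — the jitter is pure fluctuation; tumor-level offsets are a separate,
  explicitly controlled dial. The correlation length is the key texture
  knob: it separates the classes' spatial arrangement while leaving their
  marginal spreads similar, exactly the contrast the published feature
  table shows (group SDs of ADC nearly equal, local features differing
  ~2-fold).
* **Signal/noise**: `S0 = 1000`, Rician noise (magnitude of a
  complex-Gaussian-noised signal; physically correct at low SNR, Gaussian in
  the high-SNR limit) with SNR 60, drawn independently per b-value volume.
  Outside the tumor the noise-free magnitude is 0, so the background is
  Rayleigh-distributed.
* **Geometry**: 1.25 × 1.25 × 5 mm voxels. Slice thickness matches the
  acquisition the analysis targets; in-plane resolution is set at twice the
  acquisition pixel so that a full 40-subject cohort simulates in well under
  a minute while ROI voxel counts (≈2,000 for a median benign tumor,
  ≈18,000 for a median malignant one) remain in the clinically observed
  range. Ellipsoid semi-axes use fixed ratios 1 : 0.8 : 0.7 (arbitrary but
  deterministic, configurable).
* **Cohort structure**: 23 benign / 17 malignant; ages normal (53.0 ± 12.7 /
  60.8 ± 13.4 y) truncated at 18; sex Bernoulli (12/23, 6/17 female);
  volumes log-normal moment-matched to 15.630 ± 14.803 / 139.355 ± 179.174
  cm³ (SDs ≳ means rule out a normal law on positive support), truncated to
  [0.5, 1000] cm³ on physical grounds.
* **Between-subject variability** — the published table reports
  between-subject SDs of mean ADC of ~0.5/0.4 ×10⁻³, so each subject draws:
  a level shift (normal, SD 0.5×10⁻³ benign / 0.4×10⁻³ malignant, truncated
  at ±2 SD), a texture-scale multiplier (log-normal, σ_log = 0.3, clipped to
  [0.5, 2]) applied to the jitter SD and the benign core–rim half-gap, and a
  smoothness multiplier (log-normal, σ_log = 0.6, clipped to [0.25, 4]) on
  the correlation length. Without these, a fixed-parameter cohort separates
  almost perfectly on several features at once, which no real cohort does;
  the smoothness spread in particular lets the classes overlap partially on
  correlation-type features, as the published AUCs (0.85–0.92, not 1.0)
  indicate they should.

The phantom defaults are calibrated to reproduce the *direction* of the
published group differences (malignant: higher kurtosis, energy, correlation,
homogeneity; lower contrast, variance; contrast the leading local
discriminator), not their magnitudes — per-tumor texture ground truth does
not exist, so magnitude matching would be overfitting to a table.

What the phantom does **not** emulate — and what passing tests therefore do
not demonstrate about real data: scanner artifacts (ghosting, distortion,
partial-volume averaging at tumor edges), perfusion/IVIM signal, manual-ROI
delineation variability, histologic subtypes beyond the two archetypes, and
any non-ellipsoidal morphology. Results on the phantom validate the
*machinery* (feature definitions, statistics, end-to-end plumbing) and the
qualitative heterogeneity signature, nothing more.

## Determinism and problem sizes

Every stochastic component is seeded: the cohort seed drives covariates and
per-subject phantom seeds, so a cohort is reproducible subject-by-subject
regardless of processing order, and `run_pipeline()` output files are
byte-identical across runs modulo manifest timestamps. Tests run the
complete pipeline on 40-subject cohorts across 20 seeds, Monte-Carlo
calibration checks at 2,000 replicates, and oracle-equivalence sweeps over
200 random small ROIs; the whole suite completes in a few minutes on one
core.

## Known limitations

* The mono-exponential ADC model underestimates diffusivity in strongly
  perfused tissue; with b = 0 included, a perfusion fraction would inflate
  the fitted slope.
* Min–max quantization couples all level-space features to the two most
  extreme ROI voxels; fixed-bin-width quantization (not implemented, as it
  departs from the 1..64 contract) would decouple them.
* GLCM offsets ignore voxel anisotropy by construction; through-plane
  "1-voxel" steps span 4× the in-plane distance.
* The DeLong pairwise test is conservative at n = 40 (see above); Bonferroni
  on top of it is doubly conservative.
* `classify_auc()` labels describe the point estimate only, not its CI.
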