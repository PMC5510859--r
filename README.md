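# myxtex — DWI texture analysis for myxoid-containing soft-tissue tumors

Benign and malignant myxoid-containing soft-tissue tumors overlap heavily on
conventional MRI: both are dominated by water-rich myxoid matrix, so even the
mean apparent diffusion coefficient (ADC) fails to separate them. What does
differ is **spatial arrangement**: many benign myxoid tumors (predominantly
neurogenic) carry a fibrous center with a myxoid periphery and a rough internal
texture, while malignant myxoid tumors tend to be spatially homogeneous on the
ADC map. `myxtex` quantifies that difference and provides everything needed to
reproduce the analysis end-to-end, for radiologists and imaging scientists
working on radiomics of soft-tissue tumors.

## What it computes

**ADC mapping.** From DWI volumes at b = 0/400/800 s/mm², the voxelwise ADC is
the least-squares slope of the log-linear decay

    ln S(b) = ln S0 − b · ADC,

fit over all b-values with positive signal (voxels with fewer than two usable
points are flagged undefined; negative slopes clamp to 0). Tumor volume is the
ROI voxel count times the voxel volume.

**Thirteen texture features** from the in-ROI ADC values:

* *Global* (raw ADC histogram): mean, SD (n−1), skewness `m3/m2^1.5`,
  non-excess kurtosis `m4/m2²` (Gaussian → 3).
* *Regional* (grey-level size-zone matrix, GLSZM, after resampling the ROI to
  64 grey levels): with `M(m,n)` the number of 26-connected zones of level `m`
  and size `n` and `NZ` the total zone count,
  intensity variability `= Σ_m (Σ_n M)² / NZ`,
  size-zone variability `= Σ_n (Σ_m M)² / NZ`.
* *Local* (grey-level co-occurrence matrix, GLCM): pair counts over all 13
  unique 3D directions at 1-voxel distance, symmetrized, normalized per
  direction and averaged into a rotation-invariant `p(i,j)`; Haralick
  features energy `Σp²`, entropy `−Σp ln p`, correlation
  `(Σ ij p − μ²)/σ²`, contrast `Σ(i−j)²p`, homogeneity `Σp/(1+|i−j|)`,
  variance `Σ(i−μ)²p`, maximum probability `max p`.

**Cohort statistics.** Lilliefors-corrected Kolmogorov–Smirnov normality,
uncorrected Pearson chi-square for sex ratios, pooled Student t-tests, ANCOVA
adjustment for age/sex/volume (OLS, partial t of the group coefficient), ROC
analysis with the Youden-optimal cutoff (J = sensitivity + specificity − 1,
ties broken toward specificity), DeLong AUC confidence intervals, and pairwise
DeLong AUC comparisons with Bonferroni correction.

**Synthetic phantom cohort.** Because no public image set accompanies this
tumor entity, `myxtex` ships a Rician-noise DWI phantom generator whose two
archetypes encode the histologic contrast above — benign: concentric low-ADC
core / high-ADC rim plus short-correlation jitter; malignant: uniform ADC
modulated by a long-correlation smooth field — with per-subject variation of
level, texture scale, smoothness, age, sex and log-normal tumor volume
matched to the published cohort description (23 benign vs 17 malignant).

## Worked example

```r
library(myxtex)

res <- run_pipeline(run_config("simulate", out_dir = "run1", seed = 1))
res$roc[, c("feature", "auc", "direction", "threshold",
            "sensitivity", "specificity", "power")]
```

```
      feature    auc direction threshold sensitivity specificity     power
1        mean 0.7749        <=  0.001929       88.24       56.52      fair
2    kurtosis 0.9463         >  2.450468       94.12       91.30 excellent
3 correlation 0.9514         >  0.608894       94.12      100.00 excellent
4    contrast 0.9949        <= 59.334822       94.12      100.00 excellent
5 homogeneity 0.9565         >  0.268043       76.47      100.00 excellent
```

Reading: on this simulated 40-subject cohort, GLCM contrast is the strongest
discriminator — a tumor whose contrast falls at or below ≈59 is called
malignant with 94% sensitivity and 100% specificity, and its AUC of 0.99 sits
in the "excellent" (0.9–1) discriminatory-power bin. The group table shows the
same signature seen clinically: malignant tumors have higher kurtosis, energy,
correlation and homogeneity, and lower contrast and variance,

```r
dplyr::select(res$group_comparison, feature, mean_benign, mean_malignant,
              p_unadjusted, p_adjusted)
#>        feature mean_benign mean_malignant p_unadjusted p_adjusted
#> 4     kurtosis    1.79e+00       2.92e+00     7.73e-11   2.13e-04
#> 10    contrast    2.40e+02       3.72e+01     1.93e-10   3.44e-04
#> 11 homogeneity    2.10e-01       3.09e-01     7.12e-09   1.30e-03
#> ...
```

while the mean ADC alone separates the groups far less well (AUC 0.77) —
the motivation for texture analysis in the first place. All outputs
(`features.csv`, `group_comparison.csv`, `roc.csv`, `auc_pairwise.csv`,
`manifest.json`, optional per-case panels and NIfTI volumes) are written under
`out_dir`.

A shell entry point wrapping the same functions lives at
`inst/cli/myxtex.R` with verbs `simulate`, `adc`, `features`, `stats`, `run`
and `report`.

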