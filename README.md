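# retispec

Bimodal retinal image analysis for Alzheimer's disease (AD)
classification: snapshot mosaic **hyperspectral retinal imaging** (16
bands, 460–620 nm) combined with **OCT retinal nerve fiber layer (RNFL)
thickness**, evaluated with nested leave-one-out cross-validation
(LOOCV).

The package is aimed at researchers studying retinal biomarkers of
neurodegeneration who need a complete, testable reference pipeline: a
synthetic retinal phantom and cohort generator with known ground truth,
the image preprocessing chain (demosaicing, flat-field reflectance,
saturation QC, vessel masking), anatomical ROI spectral features, the
cohort statistics battery, and a from-scratch linear discriminant
classifier with honest (nested) performance estimation.

## The method in brief

Each eye contributes four rectangular regions of interest (S1, S2
superior; I1, I2 inferior) placed relative to the optic-disc–fovea
axis: height 40 px, width `round(0.35·D)` for OD–fovea distance `D`.
Vessel pixels are removed; each ROI's 16-band mean spectrum is reduced
to 14 features by dropping the edge bands and dividing by its own mean.
In AD, reflectance is expected to drop at short wavelengths consistent
with Rayleigh scattering by amyloid aggregates — the synthetic generator
attenuates AD retinas by `1 − a·load·(460/λ)⁴`.

ROIs whose group mean spectra separate by more than ±1 SEM at some
wavelength enter model selection. Candidate configurations are each
screened ROI's spectra with and without five RNFL features (14 or 19
features). Classification is linear discriminant analysis with pooled
covariance `Σ` (divisor n−2), ridge `ε = 10⁻⁶·tr(Σ)/p`, and posterior

δ_k(x) = xᵀ(Σ+εI)⁻¹μ_k − ½ μ_kᵀ(Σ+εI)⁻¹μ_k + log π_k .

Nested LOOCV selects the configuration by inner-loop AUC inside every
outer fold and reports the outer AUC over held-out probabilities with a
DeLong 95% CI — an estimate free of selection bias (on label-permuted
null cohorts it averages ≈0.49, where naive single-level selection
averages ≈0.61).

## Worked example

```r
library(retispec)

# Table statistics straight from printed summaries
pooled_t_test_summary(71.9, 6.6, 17, 68.6, 8.4, 22)
#> pooled t: statistic = 1.332, df = 37, p = 0.1911
chi_square_2x2(matrix(c(15, 12, 2, 10), 2))   # phakic yes/no by group
#> Pearson chi-square: statistic = 5.11, df = 1, p = 0.02379

# Full synthetic study at the native sensor scale (a few minutes)
spec   <- cohort_spec(n_ad = 17, n_ctrl = 22, seed = 7)
report <- run_full(spec, camera_model())
print(report)
#> Study report: 17 AD / 22 CTRL subjects
#>   SEM screen: S1, S2, I1, I2
#>   outcome: completed
#>   outer AUC 1.000, CI [1.000, 1.000]
report$stats_table[c(1, 10, 12), c("parameter", "ad", "ctrl", "p", "p_adjusted")]
#>        parameter           ad         ctrl       p p_adjusted
#> 1    Age (years)   71.3 ± 7.1  68.4 ± 10.2 0.32451         NA
#> 10 RNFL_AVG (um)   88.4 ± 9.9   92.9 ± 5.8 0.01846     0.0923
#> 12 RNFL_INF (um) 105.7 ± 10.6 115.9 ± 10.4 0.00434     0.0217
print(report$cv)
#> Nested LOOCV over 39 folds
#>   outer AUC 1.000, 95% CI [1.000, 1.000] (DeLong)
#>   configuration selections: S1 38/39, S2 1/39, ...
```

Reading the output: the simulated cohort reproduces the demographic
profile it was asked for (age difference non-significant; inferior RNFL
thinning significant after Bonferroni); all four ROIs pass the SEM
screen because the default spectral effect (`scatter_amplitude = 0.1`)
is strong relative to ROI-averaged noise, and the nested LOOCV cleanly
separates the groups. The synthetic AUC demonstrates pipeline
correctness, not clinical difficulty — real cohorts contain optics and
biology the phantoms deliberately omit (see the methods vignette).

Individual stages are available directly: `generate_phantom()`,
`render_raw_mosaic()`, `demosaic()`, `to_relative_reflectance()`,
`segment_vessels()`, `place_rois()`, `standardize_spectrum()`,
`sem_screen()`, `fit_lda()`, `nested_loocv()`. `run_simulate()` writes
a study to disk (16-bit TIFF frames, PNG masks, CSV tables, JSON
manifest) and `run_full(input_dir = ...)` analyzes it back, or use the
thin CLI at `inst/cli/retispec`.

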