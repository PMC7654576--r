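---
title: "Bimodal retinal classification: models, geometry and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal retinal classification: models, geometry and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retispec)
```

## The problem

Alzheimer's disease (AD) alters the retina in at least two measurable
ways: the retinal nerve fiber layer (RNFL) thins as ganglion-cell axons
degenerate, and the tissue's reflectance spectrum shifts at short
wavelengths, a change compatible with additional Rayleigh scattering by
small soluble amyloid-beta aggregates.  `retispec` implements a complete
analysis pipeline that combines both signals: snapshot hyperspectral
retinal imaging (16 bands, 460--620 nm) supplies four region-of-interest
reflectance spectra per eye, optical coherence tomography supplies five
RNFL thickness values (global average plus four quadrants), and a linear
discriminant classifier evaluated by nested leave-one-out
cross-validation (LOOCV) turns them into a per-subject AD probability.

Because no patient data ship with the package, a first-class synthetic
module generates ground-truthed retinal phantoms and cohorts with the
statistical structure the analysis assumes.  Every downstream stage is
therefore exercisable, and testable against known truth, without any
clinical material.

## The camera and preprocessing model

The simulated sensor is a snapshot mosaic camera: a repeating 4x4 grid
of pixel-sized spectral filters on a CMOS sensor of 1088 x 2048
photosites, so one exposure captures 16 spectral bands at 1/16 spatial
resolution (a 272 x 512 x 16 cube).  Band centers default to
`465 + 10 b` nm for `b = 0..15`, partitioning the 460--620 nm range into
sixteen 10-nm bands.  The band-to-offset bijection inside the 4x4
super-pixel is `b -> (b div 4, b mod 4)`; the physical filter layout of
real sensors is proprietary, and any fixed bijection is equivalent for
the pipeline because demosaicing (`demosaic()`) is pure subsampling with
no interpolation.

Conversion to relative reflectance is a dark/white flat-field:

    R = (DN - dark) / (white_b - dark)

clipped below at zero, since read noise inevitably produces small
negative numerators.  Acquisition practice drives the one quality rule
we model: the flash is raised to the highest intensity that avoids
saturation outside the optic nerve head (ONH), so `check_saturation()`
flags a frame unusable when more than 0.1% of photosites outside an
ONH-centered disc sit at the 16-bit ceiling.  The threshold is a
configurable parameter; the underlying rule is stated only qualitatively
in the imaging literature.

Spectral-response (filter crosstalk) correction is deliberately not
implemented; it would slot in between demosaicing and flat-fielding and
is noted as a config extension point.

## Vessel segmentation

Blood strongly absorbs between 540 and 580 nm, so vessels are dark,
tubular structures on the mean of the bands in that window.
`segment_vessels()` divides that hemoglobin image by a heavily smoothed
copy of itself (making the detector exactly invariant to global
intensity scaling), inverts it, and applies a multiscale ridge filter --
the scale-normalized most-negative Hessian eigenvalue, maximized over
scales of 1.5, 2.5 and 3.5 px, matched to vessel half-widths of 1-3 px
at cube resolution.  A fixed-quantile threshold keeps the top 11% of
ridge responses, and connected components smaller than 50 px are
discarded.  All parameters are exposed; the defaults were chosen so
that, on default phantoms at native scale, pixel recall against the
generator's truth exceeds 0.8 with precision above 0.7 (measured at
about 0.92 and 0.77 in the test suite).  Detection beyond that level
barely matters downstream: replacing the detected mask by the dilated
ground-truth mask changes ROI mean spectra by less than 1%.

## ROI geometry

Four rectangles (S1, S2 superior; I1, I2 inferior) are placed in a frame
rotated so the +u axis runs from the optic-disc (OD) center to the
fovea.  Left eyes are mirrored horizontally first, which keeps
"superior" anatomically superior regardless of laterality.  All four
rectangles are horizontally centered at the OD--fovea midpoint, are
40 px tall, and are `round(0.35 D)` wide, where `D` is the OD--fovea
distance -- the width scales with `D` precisely so the ROIs never
overlap.  Across the distances the phantom generator produces
(`D` between about 102 and 146 px at native scale) the widths span
36--51 px, inside the canonical 32--52 px range.

The vertical offsets are the one genuinely open geometric choice.  The
published layout fixes only the height, the width rule, and
non-overlap.  We place the near edges of S1/I1 at `0.15 D` from the
axis and those of S2/I2 at `0.55 D`.  Two constraints pin this down:
the gap between near and far rectangles, `0.4 D`, must exceed the 40-px
height (true for `D >= 100`), and the far rectangle's outer edge,
`0.55 D + 40`, must stay inside the 136-px half-height of a native
macula-centered capture for the largest plausible `D` (at `D = 146`,
`0.55 D + 40 = 120`).  Larger offsets -- for instance near/far at
0.35/0.85 of `D` -- satisfy non-overlap but push S2/I2 outside the
native frame for every `D` in the canonical width range, so they cannot
have been the operative layout at this sensor geometry.  Both offsets
remain parameters of `place_rois()`, which validates disjointness and
image containment and raises a geometry error otherwise.

Rasterization uses 0-based pixel coordinates (origin top-left),
half-open integer bounds, and floor-rounding of transformed coordinates;
ROI membership is thereby equivariant under exact rigid transformations
of the landmarks, up to raster rounding, and mirroring a right-eye
capture and relabeling it "left" reproduces identical ROI spectra.

## Spectral standardization and features

Each ROI's 16-band mean spectrum (vessel pixels excluded) is reduced to
14 features by dropping the first and last bands -- the edge bands of a
mosaic sensor carry the most filter roll-off noise -- and dividing the
remaining 14 values by their own mean.  This per-spectrum intensity
normalization removes brightness differences between captures (flash
energy, media opacity) while preserving spectral shape; it is exactly
scale-invariant and idempotent.  Only the output length (14) is fixed by
convention; the reduction mechanism is this package's choice.

Classifier configurations pair each screened ROI with and without the
five RNFL features, appended in the order AVG, SUP, NAS, INF, TEM, for
feature vectors of length 14 or 19.

## Cohort statistics

`cohort_table()` reproduces the standard demographics battery: pooled
(not Welch) two-sample t-tests for continuous variables -- pooled
reproduces the published age comparison (p = 0.191 from the rounded
summaries against a printed 0.193) where Welch matches less well --
Mann-Whitney for the ordinal MMSE (exact null distribution when
`n1 n2 <= 400` and tie-free, tie-corrected normal approximation
otherwise; both variants are available since the original software's
choice is unstated), and Pearson chi-square *without* continuity
correction for dichotomous variables, which reproduces the printed eye
(0.408) and phakia (0.024) p-values where the Yates-corrected statistic
does not.  RNFL parameters are adjusted for age, gender and scan quality
by ordinary least squares (group coefficient, `df = n - 5`) and
Bonferroni-corrected with family size m = 5, the five RNFL parameters;
with the published raw p-values this keeps exactly the average and
inferior RNFL significant at 0.05.

ROIs enter model selection only if the two groups' mean spectra, with
+/-1 standard-error-of-the-mean intervals, fail to overlap at one or
more wavelengths (`sem_screen()`).  The multiplier is 1 because the rule
is stated in terms of SEM intervals, not confidence intervals.  By
default the screen runs once on the full cohort, replicating the
published procedure; `strict_screening = TRUE` re-runs it inside every
outer training fold, which removes the screen's own selection leakage at
the cost of fidelity to the original design.

## Classifier and nested cross-validation

The classifier is two-class linear discriminant analysis, written from
first principles: class means, pooled within-class covariance with
divisor `n - 2`, empirical priors, and posterior probabilities by
softmax over the Gaussian discriminants.  The single departure from the
textbook estimator is a diagonal ridge `eps = 1e-6 trace(Sigma)/p`,
which keeps 19-feature fits on 37-sample training folds well posed; the
test suite verifies posteriors match an independent reference
implementation to 1e-6 once the ridge is scaled out.  Features are
z-scored per training fold by default (statistics computed on the
training fold only, applied to the held-out subject) so that
micrometer-scale RNFL features cannot dominate the pooled covariance;
this and the selection criterion below are flags, since the original
analysis does not state either.

Model selection and evaluation are nested: the outer loop holds out one
subject at a time; the inner loop runs a full LOOCV per candidate
configuration on the remaining subjects and selects the configuration
with the highest inner AUC (ties break toward fewer features, then a
fixed configuration order).  The selected configuration is refit on the
whole outer training set to score the held-out subject.  The outer AUC
over held-out probabilities is an unbiased performance estimate because
no selection ever sees the evaluated subject.  The package also provides
the biased alternative (`single_level_selection_auc()`) purely to
demonstrate the inflation: on label-permuted null cohorts of n = 39 the
nested estimate averages ~0.49 while post-hoc best-of-four selection
averages ~0.61.

AUC is computed by explicit pair counting (ties count one half), which
makes it identical to the Mann-Whitney U statistic divided by
`n_pos n_neg`.  Confidence intervals use DeLong's structural-component
variance with a Wald interval clipped to [0, 1]; a stratified percentile
bootstrap is available as an alternative (`ci = "bootstrap"`), and the
two produce interval widths within about 15% of each other on simulated
score sets.  The inner LOOCV hot loop is implemented in compiled code
(RcppArmadillo) with a pure-R reference path; a test pins the two to
machine precision.

## What the synthetic data emulate -- and what they do not

`generate_cohort()` draws demographics, clinical covariates and RNFL
thickness from group-specific distributions whose defaults match the
published cohort profile of 17 AD patients and 22 controls (age
71.9 +/- 6.6 vs 68.6 +/- 8.4 y, MMSE 17.6 +/- 5.5 vs 29.3 +/- 0.9, RNFL
average 84.8 +/- 7.5 vs 92.1 +/- 7.3 um, and so on).  Continuous
variables are clipped to their legal ranges, so a variable whose
distribution hugs a bound (control MMSE at the 30-point ceiling) has the
mean of the clipped law rather than the nominal one.  Control sex
proportions use 12/22 males; the printed male/female counts for controls
do not sum to the stated group size, and no reconciliation is attempted.
The scan-quality index (mean 52 vs 60, SD 12 vs 10, AD worse) is a
simulation choice with no published counterpart; it exists so the
covariate-adjusted regression has a real confounder to remove.

`generate_phantom()` builds a reflectance cube from a smooth
logistic-in-wavelength background (rising toward red, slope 45 nm),
low-frequency spatial gain, a bright OD, a darker macula, and a vessel
tree rasterized as smooth random walks (5--15% areal coverage,
hemoglobin-like absorption: 25% broadband darkening plus a 45% dip of
Gaussian profile centered at 560 nm, SD 18 nm).  AD retinas are
attenuated per band by `1 - a * load * (460/lambda)^4` -- a Rayleigh
scattering loss, maximal below 550 nm -- where `load` is a latent
per-subject severity, LogNormal(0, 0.25) for AD and zero for controls
(and identically zero for everyone when `a = 0`, so a null study is
exactly null).  The base-spectrum slope was fixed at 45 nm so that the
AD-minus-control difference magnitude decays monotonically with
wavelength; a steeper red rise makes the product
`base(lambda) lambda^-4` locally non-monotone near 530 nm.

The effect strength `a` (default 0.1) is a free simulation parameter,
not an estimate: no reflectance-scale magnitude for the AD spectral
effect has been published.  With the default per-pixel noise SD of 0.02
relative-reflectance units, ROI averaging over ~10^3 pixels makes the
default effect strongly separable (synthetic outer AUCs near 1), so the
synthetic study demonstrates pipeline correctness, not the clinical
difficulty of the task; passing tests on phantoms says nothing about
real-data AUC.  The phantoms also omit, by design: optical point-spread,
media opacities and cataract, flash intensity bracketing, eye-movement
artifacts, vignetting, and inter-capture registration.  These are the
main reasons real cohorts are harder than phantoms.

## Problem sizes and numerical choices

The test suite and the acceptance script use: native-scale
(272 x 512 x 16) phantoms wherever imaging accuracy is itself under
test (vessel recall/precision, ROI fit, the end-to-end synthetic study
of 39 subjects), small cameras (down to 16 x 24) for structural and
round-trip checks, 100 label-permuted cohorts of n = 39 for the null
calibration of nested LOOCV, and 3 x 39 outer folds for selection
consistency.  Degenerate situations are handled explicitly: single-class
training folds are skipped with a warning rather than failing a run;
constant features get unit scale in z-scoring; a screen that selects no
ROI stops the pipeline with an explicit outcome rather than an error;
negative reflectances clip to zero; equal-AUC ties in selection resolve
deterministically (fewer features, then fixed order).

## Known limitations

* The standardization formula, the vessel-removal procedure, and the
  exact ROI vertical offsets of the original analysis are unpublished;
  this package's choices are documented above and exposed as parameters,
  but they are reconstructions, not reproductions.
* The published real-data headline (outer AUC 0.74, CI 0.60--0.89) is
  not reproducible here because the patient data are not deposited; the
  package deliberately makes no attempt to match it.
* DeLong's variance is asymptotic; at n = 39 its Wald interval can clip
  at the [0, 1] boundary for near-separable scores.  The bootstrap
  alternative behaves better there.
* The Mann-Whitney exact path and the chi-square are delegated to R's
  stats primitives; only their selection logic (exactness rule, no
  continuity correction) is this package's.
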