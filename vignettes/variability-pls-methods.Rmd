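---
title: "Methods: BOLD signal variability and PLS brain-behavior mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BOLD signal variability and PLS brain-behavior mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varpls)
```

## The scientific question

Emotion dysregulation — the tendency of affect to shift rapidly and escape
goal-directed control — cuts across diagnostic categories: it is prominent in
bipolar disorder (BD), borderline personality disorder (BPD) and
attention-deficit/hyperactivity disorder (ADHD), and varies continuously in
the general population. `varpls` implements a dimensional (transdiagnostic)
analysis that asks: *which spatial pattern of moment-to-moment BOLD signal
variability covaries, across all individuals regardless of diagnosis, with a
behavioral profile of emotion dysregulation?*

The imaging feature is **BOLD signal variability**: the standard deviation of
each voxel's preprocessed resting-state time-course. The behavioral side is a
three-column matrix of clinical scales: affective lability (ALS, the average
of six subscale scores), depression (MADRS, a clinician-rated sum score) and
mania (YMRS, likewise). The statistical engine is **PLS correlation**: the
SVD of the brain-behavior cross-correlation matrix, yielding paired latent
components that maximize covariance between the two blocks.

## The per-participant variability pipeline

For one participant with a T x V time-course matrix, repetition time TR and
T x 6 rigid-body motion parameters, `extract_variability()` applies, in this
fixed order:

1. **Nuisance regression** (`nuisance_regress()`): per-voxel least squares on
   an intercept, the six motion parameters, and any supplied WM/CSF mean
   signals. Residuals are orthogonal to the design.
2. **Band-pass filter** (`bandpass_filter()`): an ideal frequency-domain
   filter retaining Fourier coefficients with frequency in [0.01, 0.10] Hz
   (DC always removed). The hard cut is deliberate: it makes the
   SD-equals-ALFF identity below *exact* rather than approximate.
3. **Framewise displacement** (`framewise_displacement()`): backward
   differences of the six parameters, rotations converted to arc length on a
   50 mm sphere, summed in absolute value; FD of the first frame is 0.
4. **Scrubbing** (`scrub_mask()`): frames with FD strictly above 0.5 mm are
   removed together with 1 frame before and 2 after, clipped at run
   boundaries.
5. **Duration gate** (`min_duration_ok()`): participants retaining less than
   240 s of data are excluded (inclusive comparison at exactly 240 s).
6. **Variability** (`variability_sd()`): per-voxel *population* SD (divide by
   n) over kept frames only. Kept frames are not re-filtered; scrubbing only
   selects the frames entering the SD.
7. **Z-scoring** (`zscore_map()`): the map is centered and scaled to mean 0,
   SD 1 across in-mask voxels within the participant.

Two identities anchor the numerics and are asserted by tests:

* **Parseval**: for any band-passed series, `variability_sd()` equals
  `alff()` (root of summed squared in-band Fourier amplitudes divided by T)
  to 1e-8. This is why the population-SD convention is used — the sample-SD
  variant would break the identity by a factor sqrt(n/(n-1)). The choice is
  immaterial downstream because the within-participant z-scoring removes any
  per-participant scale.
* **Scale equivariance**: `variability_sd(c*X) = c*variability_sd(X)`, and
  the z-scored map is invariant to any global rescaling of the participant's
  data.

The analysis mask is built by thresholding a gray-matter probability map at
>= 50% and subtracting an exclusion mask (`build_analysis_mask()`); mask
construction upstream of that (segmentation, template building, smoothing) is
out of scope — masks are consumed ready-made.

Two readings of the FD definition circulate: with and without temporal
differencing of the parameters. The default is the differenced (Power-style)
form, which is the convention the 0.5 mm threshold presumes; the
no-differencing variant is available as `literal = TRUE` for sensitivity
checks.

Mean FD used later as a confound is computed over **all** frames, not only
kept ones: a participant's propensity to move is the confound of interest,
and scrubbing would censor exactly the frames that carry it.

## Deconfounding

Before the PLS, the stacked N x V map matrix is residualized on age, sex,
scanner and mean FD (`encode_confounds()` + `residualize()`): sex as one
indicator, scanner as treatment-coded indicators against the
lexicographically first level (four scanner levels by default), numeric
columns as-is, intercept always included. Residuals are used without adding
means back; the PLS standardization absorbs location and scale.

The behavior matrix is **not** residualized by default — the deconfounding
target is the imaging data. A `deconfound_behavior` flag in
`analysis_config()` enables symmetric residualization for sensitivity
analyses.

## PLS correlation

With X (N x V, deconfounded maps) and Y (N x 3, clinical scales), both
column-standardized (population SD), `pls_fit()` decomposes

    R = t(Y_z) %*% X_z / (N - 1),   R = U D t(V)

Component k pairs behavior salience `U[,k]` with brain salience `V[,k]`
(both unit norm); `d_k^2 / sum(d^2)` is the fraction of brain-behavior
covariance it explains; participant scores are `Lx = X_z V` and
`Ly = Y_z U`. Standardizing both blocks (so R is a correlation-type matrix)
follows the convention of the published PLS toolbox lineage; the pooled
sample, not each group, defines the standardization. The SVD sign ambiguity
is fixed per component by making the largest-magnitude behavior-salience
entry positive, flipping brain salience and both score vectors jointly.

**Loadings** are Pearson correlations between original variables and latent
scores. "Original" is ambiguous for the imaging block (pre- or
post-deconfounding); the default correlates the matrix that actually entered
the PLS (post-deconfounding), with `loadings_source = "original"` selecting
the raw maps instead.

## Group-restricted inference

Both resampling schemes deliberately respect the diagnostic group structure
so that latent components are not driven by group differences:

* **Permutation** (`permutation_test()`): behavior rows are shuffled only
  within each diagnostic group (1000 permutations by default); X is
  untouched. Each permuted singular structure is procrustes-aligned to the
  observed one — the orthogonal rotation minimizing the Frobenius distance
  between behavior-salience bases, with null singular values taken as column
  norms of the rotated, singular-value-weighted basis. P-values use the
  add-one rule `p = (1 + #{null >= observed}) / (1 + n_perm)`, so the
  smallest attainable p is `1/(n_perm + 1)`.
* **Bootstrap** (`bootstrap_test()`): each replicate resamples every group
  with replacement to its own size, rows drawn jointly from X and Y (1000
  replicates by default), refits the PLS with standardization recomputed on
  the replicate, aligns to the observed structure, and recomputes loadings.
  The reliability z of a loading is the observed loading divided by its
  bootstrap SD; `|z| >= 3` (roughly a 99% confidence statement) flags strong
  contributors.

Alignment uses the full orthogonal rotation by default; a sign-flip-only
mode (`procrustes = FALSE` / `method = "sign"`) is provided because the
precise alignment convention differs between published implementations.

One parent seed deterministically spawns per-replicate child seeds, so
results are reproducible and independent of replicate execution order.

### A note on calibration

Procrustes alignment makes each null singular value a convex mixture of the
permuted spectrum, which shrinks the null for the first component slightly
below its raw (unaligned) counterpart; the first-component p-value is
therefore mildly liberal in small samples. The package's calibration test
(1200 null datasets with strong group offsets in both blocks) checks that
the within-group scheme neutralizes group structure at close to the nominal
5% level. The sign-flip alignment mode, whose observed and null statistics are
exactly exchangeable under the within-group null, is the conservative
fallback when exact calibration matters more than rotational stability.

## The synthetic cohort generator

The generator exists so the whole pipeline can be exercised, calibrated and
benchmarked with known ground truth.

* `generate_cohort()` draws the four-group cohort (HC 64, BD 63, ADHD 20,
  BPD 19) with **moment-matched sampling**: within each group, normal draws
  are affinely rescaled so the realized group mean and population SD equal
  the specified values *exactly* — the defaults being the published
  demographic and clinical profile of the 166-participant analyzed sample
  (e.g. BPD ALS 1.80 (0.46), HC ALS 0.42 (0.40), ADHD YMRS identically 0).
  The population-SD convention is forced by the two-point case: a group of
  n = 2 with mean 5 and SD 1 must realize {4, 6}. No truncation at zero is
  applied by default (truncation would bias the realized means); a
  `clip_at_zero` mode exists but is off everywhere. Group sizes follow the
  final analyzed sample as described in the recruitment-flow text, which the
  per-group sex and scanner counts corroborate. Sex and scanner are
  allocated as deterministic counts (largest-remainder rounding) in shuffled
  order; age and mean FD are moment-matched like the scales.
* `synthetic_truth()` plants a ground-truth latent component: a unit-norm
  brain salience on a contiguous support (10% of voxels by default, half
  positive half negative — mimicking paired regional increases and decreases
  of variability) and a unit-norm behavior salience loading ALS and MADRS
  heavily and YMRS barely (0.70, 0.70, 0.10 before normalization), mirroring
  the loading pattern a dysregulation component exhibits.
* `generate_variability_maps()` builds
  `X = latent %*% t(v_true) * scale + offsets + noise`, where `latent` is the
  standardized projection of the behavior matrix onto the true behavior
  salience and `scale` is set so the planted component carries exactly
  `effect_size` of the average per-entry variance (default 0.5). With
  `effect_size = 0` the matrix is pure noise plus offsets — the null used
  for calibration.
* `generate_bold_run()` synthesizes band-limited Gaussian time-courses in
  the frequency domain, so the per-voxel SD equals the requested target
  exactly, plus motion traces whose baseline FD is bounded well below
  0.5 mm and whose requested spike frames each get a persistent 0.7 mm
  translation step (a step, not a pulse, so the FD excursion occurs at
  exactly the spiked frame). Frame 1 cannot carry a spike since FD there is
  0 by definition.

What the generator does **not** emulate: spatial autocorrelation of real
BOLD volumes, physiological noise spectra, scanner-specific artifacts beyond
additive offsets, non-Gaussian score distributions, or heavy-tailed motion.
Passing recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to real fMRI
noise. One further consequence of Gaussian moment matching worth knowing:
with the published group spreads, a few simulated patients land above the
euthymia gates (MADRS > 15 or YMRS > 7), so the pipeline's clinical gate
excludes a handful of synthetic participants — realistic behavior, and the
participant-flow accounting makes it visible.

## The post-hoc battery

`posthoc_battery()` mirrors the standard follow-up: pooled-variance t-tests
of brain and behavior scores between every group pair (one FDR family), and
Pearson correlations with continuous severity measures plus t-tests against
binary medication flags (a second family), each family corrected by
Benjamini-Hochberg at q = 0.05. The pooled-variance form is the default
(Welch by flag). Families follow the natural table groupings —
demographics/scores together, severity/medication together; missing data are
handled per test with `n_used` reported.

## Problem sizes and numerical choices

* Recovery benchmarks run at N = 166, V = 2000, effect size 0.5, 20 seeds,
  1000 permutations — the planted salience is recovered with |r| >= 0.9 on
  both sides and the first component's permutation p sits at its floor
  1/1001. Calibration runs 1200 null datasets at V = 200 with 200
  permutations; bootstrap power runs 20 seeds at V = 500 with 500
  replicates. These sizes were chosen to make the full suite comfortably
  runnable on a laptop core while keeping the Monte Carlo error of each
  assertion far below its margin.
* Rank deficiency in any regression design is an error naming the offending
  columns, not a silent drop. Constant columns cannot be standardized and
  are an error at the PLS surface; inside bootstrap replicates (where a
  resample can flatten a column) they are tolerated and the affected
  loading is recorded as missing for that replicate.
* A bootstrap loading SD of exactly zero yields z = Inf with the loading's
  sign (flagged if the loading is nonzero), and NA when the loading is also
  zero.
* Clinical gates are strict inequalities: exclusion iff MADRS > 15 or
  YMRS > 7.
* All comparisons at thresholds are as stated: FD strictly greater than
  0.5 mm; gray-matter probability >= 0.5; retained duration >= 240 s.

## Known limitations

* The spatial preprocessing that precedes this package (realignment,
  normalization, segmentation, smoothing, template construction) is out of
  scope; inputs are assumed registered to a common grid, and grid mismatches
  are errors, never resampled away.
* The permutation p of the first component is mildly liberal under the
  rotation alignment (see the calibration note above).
* WM/CSF nuisance signals are accepted as supplied regressors; their
  extraction from tissue masks is not implemented.
* No PLS-regression variant, sparse PLS, cross-validated prediction,
  split-half stability, or site-harmonization beyond linear scanner
  indicators.
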