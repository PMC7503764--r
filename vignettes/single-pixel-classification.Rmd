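---
title: "Single-pixel classification of MALDI-MSI data: models and design choices"
author: "pixelMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-pixel classification of MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mass spectrometry imaging (MSI) of a tissue microarray yields one
MALDI-TOF spectrum of tryptic peptides per raster position ("pixel") of
each ~1 mm tissue core. Clinical material such as fine-needle aspirates is
small and heterogeneous, so classification must work at the level of
individual spectra that represent small clusters of cells — not at the
level of a bulk lysate. This package implements a complete pipeline for
that *single-pixel* strategy over seven thyroid tissue classes (NT, FA,
PTC-CV, PTC-FV, FTC, ATC, MTC), from raw spectra to a per-core diagnosis,
together with heterogeneity (similarity) analysis, effect-size screening
of discriminatory spectral components, and mass-tolerance peptide
annotation.

## Data model and containers

`MSISpectra` (channels × pixels) and `AbundanceMatrix` (components ×
pixels) extend `SummarizedExperiment`; the m/z axis and component
parameters live in `rowData`, pixel metadata (`pixel_id`, `core_id`,
`patient_id`, `roi_label`, coordinates, outlier flag) in `colData`. Every
pixel belongs to exactly one core and every core to one patient — the
hierarchy on which cross-validation stratifies.

## Preprocessing

The chain runs in a fixed order: baseline subtraction → TIC outlier
flagging → alignment → TIC normalization (mass-channel unification is the
import step, `unifyMassChannels()`, linear interpolation with
out-of-range channels set to 0).

* **Baseline** (`subtractBaseline`): a smoothed rolling minimum — the
  windowed minimum over `windowDa` (default 50 Da, wide relative to peak
  widths of a few Da in the tryptic peptide range, narrow relative to
  baseline curvature), smoothed by a moving average of the same width,
  subtracted and clipped at zero. Parameter-light and standard for
  MALDI-TOF peptide spectra.
* **TIC outliers** (`flagTICOutliers`): total ion current distributions
  over pixels are right-skewed and heavy-tailed, so plain Tukey fences
  over-flag. We use the medcouple-adjusted boxplot: with MC ≥ 0 the fences
  are [Q1 − 1.5·e^(−4·MC)·IQR, Q3 + 1.5·e^(3·MC)·IQR] (coefficients −3/4
  for MC < 0). The medcouple itself is the exact O(n²) kernel-median
  definition with the sign kernel for ties, validated against an
  independent implementation. Flagged pixels stay in the container but are
  excluded from every downstream fit and from classification. Flags are
  OR-ed across passes, which keeps the chain idempotent.
* **Alignment** (`alignToReference`): per spectrum (or per core, as the
  generator plants per-core shifts) the integer channel lag within
  ±`shiftMax` (default 10) maximizing the FFT cross-correlation with the
  channel-wise average of non-outlier spectra is applied, vacated channels
  zero-filled. Because the reference is built from the data, a global
  translation of the whole dataset is unidentifiable; the median lag is
  therefore subtracted so that alignment never translates the dataset as a
  whole. Ties prefer the smallest absolute lag.
* **TIC normalization** (`normalizeTIC`): every spectrum is scaled to the
  mean pre-normalization TIC of non-outlier pixels. Any positive constant
  would do — downstream Z-scoring removes the scale — but the mean keeps
  intensities on a familiar scale.

## Spectral components

`fitSpectrumGMM` models the average spectrum as a Gaussian mixture,
segment-wise:

* channels below `valleyFrac` (0.5%) of the spectrum maximum delimit
  segments; each segment is extended up to 4 channels into its valleys
  (never past half-way to a neighbor) so peak tails are not truncated;
* segments longer than `maxSegLen` (80 channels) are split recursively at
  their lowest internal valley, but only where that valley is genuinely
  deep (below half of both flanking maxima) — a lone wide peak is never
  sliced through its flank;
* within a segment, weighted EM fits a mixture to the spectrum treated as
  an unnormalized density, channel positions weighted by intensity. The
  number of components is chosen by a BIC sweep (up to
  `maxComponentsPerSegment` = 8, early stop after two consecutive rises)
  with the segment's total intensity as the effective count — the average
  spectrum is a very high signal-to-noise measurement and intensities act
  as pseudo-counts (TIC normalization upstream standardizes their scale).
  Component widths are floored at 0.8 channel spacings: anything narrower
  is unidentifiable on the sampled axis.

Pruning removes components below the `ampQuantile` (5%) amplitude
quantile or wider than `sigmaMaxDa` (10 Da, baseline remnants). Merging
groups components closer than 1.0 × max(σ) by transitive closure — the
rule threshold is a free design choice meant to capture "the same
spectrum peak" — and represents each group at its dominant (highest
amplitude) member's m/z; a merged component's abundance is the sum over
members.

Abundances (`estimateAbundances`) are inner products of each spectrum
with unit-area Gaussian kernels, Σ s(m)·g(m)·Δm, i.e. on a peak-area
scale. Unit area vs unit height is immaterial downstream: Z-scoring
(classification) and within-comparison use (similarity, effect sizes)
cancel any per-component scale. For a spectrum containing a peak of area
A with matching width, the abundance is A/(2σ√π) — tests use this
analytic value.

`fitIntensityClasses` fits a 1-D Gaussian mixture (mclust, unequal
variances, default 5 classes) to log10 mean abundances; thresholds sit at
posterior-equality crossings between adjacent mean-ordered classes, with
the midpoint as fallback when one class dominates an interval. The top
class is the "most abundant components" feature subset; every analysis
accepts `features = "all"` or `"top"`.

## Similarity

The similarity index is the normalized dot product of two abundance
vectors (the spectral contrast angle is its arccosine — a monotone
transform, so either form orders pairs identically). `groupSimilarity`
evaluates all intra- or inter-class pixel pairs when their number is
within `maxPairs` (default 10⁶), otherwise a seeded uniform subsample —
an unbiased estimator of the same CDF, unavoidable once pair populations
reach billions. Summaries are the empirical CDF and its median
(CDF = 0.5).

## Classification

* **Standardization**: Z-scores with means/SDs from training pixels only
  (per fold); zero-variance features are dropped and recorded.
* **Ensemble**: one linear soft-margin SVM per unordered class pair
  (21 for 7 classes), `e1071::svm`, cost C = 1, class weights inversely
  proportional to class frequency. C and the weighting are unstated
  territory; both are exposed as parameters.
* **Univocal rule**: a pixel gets class C iff all 6 binaries featuring C
  vote C. At most one class can satisfy this (two winners would both have
  to win their mutual match); the exhaustive 2²¹-pattern enumeration in
  the acceptance suite verifies the implementation against the direct
  definition. Everything else is NOT_CLASSIFIED.
* **Core decision**: most frequent of the eight pixel outcomes;
  NOT_CLASSIFIED modal → NOT_DIAGNOSTIC. Ties prefer any tissue class
  over NOT_CLASSIFIED, then the canonical order NT, FA, PTC-CV, PTC-FV,
  FTC, ATC, MTC. The same canonical order breaks ties in patient-class
  assignment.
* **Cross-validation**: patients are assigned a class by the majority of
  their cores, stratified into k = 5 folds (seeded within-class shuffle,
  round-robin deal), and all cores/pixels inherit the patient's fold —
  no patient ever appears in both training and validation of a fold.
  Validation decisions are pooled across folds into one core decision
  table. TIC-outlier pixels take part in neither training nor
  classification.
* **Strategies**: `"single-pixel"` (train and classify pixels, majority
  over the core), `"mean-spectrum"` (train and classify per-core mean
  abundance vectors) and `"hybrid"` (pixel-trained binaries applied to
  core means) share the fold plan and the univocal rule.
* **Quality indices**: one-vs-rest sensitivity/precision/accuracy per
  class, the 7 × 8 confusion matrix, overall and diagnosed-only correct
  fractions, and the not-diagnostic fraction.

## Effect sizes and PCA

Cohen's d uses the pooled-SD form; categories use |d| with ≥ 0.5 / ≥ 0.8 /
≥ 1.2 for medium / large / very large — boundary values enter the higher
class. No multiple-testing correction is applied: the point of an effect
size is precisely its independence of the enormous pixel counts, where
any t-test would declare everything significant. Signed d values are kept
in the records. Super-group comparisons pool pixels before computing d.
The exploratory PCA scales with log10(x + 1) (wide dynamic range without
discarding covariance structure), centers per feature, and uses the
singular value decomposition; a seeded per-core pixel subsample supports
overview plots.

## Annotation

A component at m/z m matches every peptide whose listed mass is within
±tol·m (default 0.05%). The peptide list's `mass` column is declared to be
on the scale compared with MSI m/z — singly protonated [M+H]⁺ for MALDI —
pushing the mass-convention decision to the data file, where it belongs.
Matches are not unique; all are returned ordered by relative error. The
bundled `synthetic_peptides.csv` is a synthetic stand-in list for
interface demonstration only.

## The synthetic generator

`generateDataset(synthConfig(...))` emulates the structure the analysis
assumes: 7 ROI classes × patients × ~3 cores × pixels; Gaussian peptide
peaks on a 700–3700 Da axis (default 4000 channels, 200 peaks) with
widths growing linearly in m/z (default 2 Da at m/z 2000 — at least two
channels everywhere, as on a resolvable TOF axis); log-normal base peak
areas (so intensity-class structure emerges); a per-(patient, peak)
log-normal random effect (patientSd = 0.15) emulating inter-individual
profile differences — deliberately per-peak, since a single global factor
would be removed exactly by TIC normalization; per-pixel area noise with
CV = 0.3 scaled by a per-ROI heterogeneity multiplier (NT 0.6 lowest …
ATC 1.6 highest, reproducing the homogeneous-normal / heterogeneous-
anaplastic ordering); a smooth baseline (sum of wide Gaussians), additive
truncated Gaussian noise, a log-normal per-pixel TIC factor, a small
fraction of aberrant-TIC pixels, and a balanced multiset of per-core
integer channel shifts (balanced so the planted drift is centered on the
calibrated axis and exactly recoverable).

Effects are planted on the abundance (peak-area) scale: each of
`nDiscriminative` signature peaks (default 70, dealt round-robin to the 7
ROIs, hence 20 planted components per class pair) is upregulated in its
ROI by a multiplicative offset solved analytically from the within-class
variance so that the pooled-SD Cohen's d is `targetD` (default 1.5)
against the noisiest opposing class — and therefore at least that against
every other. The exact per-pair analytic d values are stored in the
`GroundTruth`, along with true peak parameters, per-pixel true areas,
injected outliers and shifts. The defaults — 2 patients per ROI, 3 cores
per patient, 50 pixels per core — are the study conditions used
throughout the tests and the acceptance script; per-ROI spectral
parameters have no published values and are documented free choices.

What the generator does **not** emulate: isotope envelopes, detector
saturation, MALDI matrix clusters, spatial autocorrelation within a core,
mass-dependent intensity response, or FFPE chemistry. Passing
parameter-recovery tests therefore demonstrates the correctness of the
machinery under the stated generative model, not clinical performance on
real tissue.

## Numerical choices and degenerate inputs

* EM: relative log-likelihood tolerance 10⁻⁶, ≤ 200 iterations,
  convergence failure keeps the best model with a warning; components
  with vanishing weight are dropped.
* The GMM reconstruction-quality warning threshold is 5% integrated
  absolute error; on the synthetic defaults the retained model captures
  ~95% of total intensity.
* Zero-TIC pixels are flagged and skipped by normalization (warning);
  all-outlier datasets, all-zero spectra, empty cores and missing classes
  raise explicit errors.
* All stochastic steps (generator, fold shuffles, pair subsamples,
  per-core PCA subsamples) take explicit seeds and restore the caller's
  RNG state.

## Problem sizes in the test suite

The suite runs the full pipeline on the default 2100-pixel configuration
(and a zero-effect and a doubled-heterogeneity variant), effect-size and
similarity checks on noise-free ground-truth abundances at 500 pixels per
ROI, and the exhaustive 2²¹ vote-pattern enumeration; the whole suite
completes in well under five minutes on one CPU. These sizes are the
package's chosen study-scale conditions: large enough for the planted
structure to be estimable, small enough to iterate on.

## Known limitations

* The segment-wise EM + BIC peak detector is this package's own
  formulation of Gaussian-mixture spectrum modeling; other published
  variants differ in segmentation and model-size selection, so component
  counts are comparable only in order of magnitude.
* Raw abundance scales depend on the unit-area kernel convention; compare
  abundances only within this package's output.
* The O(n²) medcouple is fine for thousands of pixels per dataset but
  would need the O(n log n) algorithm for very large cohorts flagged in
  one pass.
* With fewer patients per class than folds, the patient-stratified
  partition is necessarily uneven (the implementation warns and
  proceeds); the mean-spectrum strategy then trains some binaries on very
  few core means, which is the main driver of its weaker core-level
  accuracy on small cohorts.
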