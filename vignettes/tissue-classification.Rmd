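---
title: "Methods: spectral preprocessing and tissue classification with an optical needle probe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral preprocessing and tissue classification with an optical needle probe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A core biopsy needle with two embedded optical fibers can record broadband
diffuse reflectance from the tissue directly in front of its tip. Because
different tissues absorb and scatter light differently -- hemoglobin
dominates below 600 nm, deoxyhemoglobin produces a dip near 760 nm, lipids
and water absorb above 900 nm -- the spectral shape at the tip carries
enough information to recognize the tissue in real time while the needle
advances. `needlespec` implements the full processing chain for this
setting: calibration of raw spectrometer counts, smoothing, normalization,
band restriction, four feature representations, SVM and KNN multiclass
classifiers with stratified cross-validation and subject-independent
holdout, per-class performance statistics, and a simulated 2 Hz streaming
classifier. Eight classes are distinguished: laboratory ambient light (the
needle outside tissue) plus blood, fat, heart, kidney, liver, lung and
muscle.

## The processing model

Raw spectra live on a fixed grid of 1044 points linearly spaced over
348--1129 nm (`canonical_grid()`). A nominal 0.7 nm optical resolution and
the 1044-point count cannot both hold on that range; the point count wins
because every downstream vector length derives from it.

Each raw spectrum $I_{\mathrm{raw}}(\lambda)$ is converted to relative
intensity against a white-standard measurement $I_{\mathrm{std}}$ and a
dark/instrument-noise measurement $I_{\mathrm{nse}}$:

$$ I(\lambda) \;=\; \frac{I_{\mathrm{raw}}(\lambda) - I_{\mathrm{nse}}(\lambda)}
        {I_{\mathrm{std}}(\lambda) - I_{\mathrm{nse}}(\lambda)} $$

A zero denominator at any retained wavelength is a hard error that names
the offending wavelengths. The calibrated curve is a reflectance-like
ratio; we deliberately do **not** convert it to $-\log_{10}$ absorbance by
default, since the ratio is what the calibration defines, but
`preprocess_config(log_absorbance = TRUE)` applies the transform for users
who prefer optical density.

The chain then applies, in this order:

1. **Moving-average smoothing**, window 10 samples, centered with
   truncated windows at the edges (edge handling is not prescribed
   anywhere, so the least-surprising symmetric-truncation rule is used;
   for even windows the extra sample falls on the right). Window 10
   suppresses the high-frequency detector noise while leaving the
   broad tissue features, whose widths are tens of nm, intact.
2. **Per-spectrum min--max normalization** to $[0,1]$. Recorded
   intensities vary strongly with probe coupling and tissue contact, so
   classification must rest on shape, not level. The minimum and maximum
   are taken over the full pre-restriction spectrum (normalization is
   applied before band restriction in the chain's definition); a constant
   spectrum has no shape and raises an error rather than returning NaNs.
3. **Band restriction** to 450--1000 nm (closed interval). Below 450 nm
   the halogen source emits little; above 1000 nm the silicon detector
   loses sensitivity; neither region separates the classes. On the
   canonical grid this keeps 734 points. Printed descriptions of this
   kind of pipeline quote 732, 742 and (after 2:1 decimation) 366 points
   for the restricted representation -- three mutually inconsistent
   numbers. The package therefore treats the configured band as the only
   authority and records the resulting length in the provenance field
   rather than asserting any fixed count.

## Feature schemes

Four representations feed the classifiers (`feature_scheme()`):

* **full** -- every `decimation`-th point of the restricted spectrum.
  The default decimation of 2 gives 367 features, matching the intent of
  a roughly-366-feature final model while staying derived from the grid.
* **band** -- values inside 470--520 nm and 550--890 nm concatenated.
  The first band covers the wide reflectance peak at the blue-green end;
  the second covers the step rise near 600 nm and the 760 nm dip.
  Overlapping bands duplicate values by design.
* **point** -- the spectrum at 25 fixed wavelengths
  (`point_wavelengths()`), chosen near edges and local extrema.
* **slope** -- 24 finite-difference gradients over fixed segments
  (`slope_segments()`), in units of normalized intensity per nm.
  Endpoint values are read at single nearest grid points, not local
  averages: the spectrum is already smoothed with window 10, so an extra
  average would double-smooth. The gradient, not its arctangent, is the
  feature (an `angle_degrees` option applies `atan` for users who think
  in tangent-line angles; the two are monotonically equivalent). Slopes
  are exactly invariant to additive offsets and scale linearly with the
  spectrum -- the property that makes them robust to residual intensity
  variation within a class.

Nearest-grid lookup (`wavelength_index()`) breaks exact midpoint ties
toward the lower index, a fixed arbitrary rule so results never depend on
floating-point noise. Slope denominators use the nominal segment lengths
from the table, not the realized grid differences, so a tabulated segment
means the same thing on any grid; on a linear spectrum the slopes are then
approximate (not exact) to about one grid step per endpoint.

## Classifiers

`tissue_classifier()` fits either model family:

* **SVM**: one-vs-rest binary margins with a linear kernel and cost
  $C = 1$ (libsvm via e1071). The margin scale of an SVM depends on the
  feature scale, and the four schemes differ by orders of magnitude
  (slopes are $\sim 10^{-3}$ per nm), so feature columns are standardized
  inside the fit and the same transform is applied at prediction;
  near-constant columns get a unit divisor. The per-class decision values
  are turned into scores by a softmax -- a fixed monotone map, so the
  argmax is unchanged. Gaussian and second-degree polynomial kernels are
  available (`svm_kernel = "rbf"` / `"poly2"`) but the linear kernel is
  the default for this family of smooth, high-dimensional, nearly
  linearly separable spectra.
* **KNN**: $k = 3$, Euclidean by default; Manhattan and Mahalanobis
  metrics are provided (the Mahalanobis covariance is ridged with
  $10^{-6}$ of its mean diagonal so it stays invertible when features
  outnumber samples). Scores are neighbor vote fractions. A 1/1/1 vote
  tie is resolved by the class of the single nearest neighbor -- the most
  informative of the three.

**Combination.** Ensembles average the members' normalized score vectors
(`combine_models()`); the prediction is the argmax, with exact ties broken
toward the earlier class in `class_order`. Averaging scores (rather than
majority voting) is used because it is the minimal numeric interpretation
of "summing and averaging" classifier outputs that is well defined for
both SVM and KNN; voting is recoverable by rounding scores to indicators.
A single-member ensemble delegates to the member, so it is the member,
tie-breaks included.

**Cross-validation.** `stratified_kfold()` spreads every class across the
$k$ folds so per-class validation counts differ by at most one, and
assigns the remainder samples to the currently smallest folds so overall
fold sizes also differ by at most one. On the 1317-spectrum training
design (85--247 per class), fivefold splits give validation folds of
263--264. Model-selection CV is class-stratified on pooled spectra;
subject independence is enforced only at the final holdout
(`subject_holdout_split()`), mirroring the usual protocol in which a
subject-independent streaming test follows pooled model selection. For a
stricter protocol, group the folds by subject before calling
`cross_validate()`.

## Performance statistics

`per_class_metrics()` computes one-vs-rest sensitivity, specificity,
precision and F1 per class, unweighted macro averages over **all eight
classes including ambient**, and overall accuracy. Precision of a class
that is never predicted is defined as 0 and the class is flagged --
silently dropping such classes would inflate the macro average. Reports
round half away from zero to 3 decimals (the convention of published
tables); JSON reports keep full precision. The bundled
`reference_confusion()` matrix -- a 286-sample, two-subject real-time
validation session -- is the worked example: its published per-class table
and macro row reproduce exactly from the raw counts under these
conventions, which is also how the ambient column's internally
inconsistent printed total was resolved (per-row entries are
authoritative).

## Streaming protocol

`make_session()` orders spectra into contiguous class periods at a fixed
sampling period (default 0.5 s, i.e. 2 Hz) in a configurable measurement
order; the conventional order measures blood last because it contaminates
the needle. `stream_classify()` processes each spectrum independently in
arrival order through preprocess, featurize, predict. Tissue changes are
not synchronized with the clock, so one sample on each side of every
internal period boundary is excluded from the summary by default (the
exact number excluded in practice is a protocol detail; it is a parameter,
`boundary_exclusion`). A failing sample (e.g. a saturated, constant
spectrum) is flagged and the stream continues. Per-sample latency is
recorded for information only -- it is hardware-dependent and never part
of any assertion.

## The synthetic generator

No probe recordings are distributed, so `generate_dataset()` creates
datasets with the statistical structure the pipeline assumes:

* **Class archetypes** (`default_archetypes()`): smooth reference
  reflectance shapes built from Gaussian bumps/dips, a logistic step near
  600 nm and a linear baseline, parameterized in
  `inst/extdata/archetypes.csv`. All classes share the 760 nm dip and the
  600 nm step with class-specific magnitudes; blood carries additional
  peaks above 900 nm; fat and muscle are deliberately the most similar
  pair (the hardest confusion in practice). The amplitudes are
  qualitative, hand-designed stand-ins -- nothing is fitted to measured
  tissue, and no radiative-transfer physics is simulated.
* **Counts model**: `dark + (standard - dark) * scale * gain_s(lambda) *
  R_class(lambda) + noise`, with a flat white standard (40000 counts) and
  constant dark (1800 counts), so calibration recovers
  `scale * gain * reflectance` exactly and clean intensities are strictly
  positive.
* **Subject effect**: each subject draws a smooth multiplicative gain,
  `exp` of a random degree-2 Chebyshev polynomial with coefficient sd
  `subject_effect_scale` (default 0.08). A *smooth* perturbation is
  essential: a constant gain would be erased by min--max normalization,
  whereas a smooth spectral tilt survives it -- exactly the kind of
  inter-animal variation that makes subject-held-out accuracy lower than
  pooled-CV accuracy.
* **Intensity variation**: a per-spectrum uniform scale on
  `intensity_range` (default 0.5--2), emulating strongly varying probe
  coupling; normalization must remove it.
* **Noise**: i.i.d. Gaussian per wavelength on the calibrated scale
  (default sd 0.02) -- precisely the disturbance the window-10 moving
  average is designed to suppress.
* **class_separation** scales archetype differences around their mean:
  at 0 all classes coincide and any classifier must fall to 1/8 chance
  accuracy; at 1 the designed shapes are used. This dial exists for
  validation, not simulation realism.

Defaults (8 subjects, 20 spectra per class per subject) give per-class
totals comparable to a small multi-animal ex vivo study. What passing
tests on these data show is that the pipeline recovers class structure of
the assumed form under subject effects and noise; they cannot show
robustness to features real probe data would add -- wavelength-correlated
noise, needle contamination carry-over, heterogeneous organs, or spectral
shapes unlike the archetypes.

## Test problem sizes

The package's own test suite exercises the recovery properties at sizes
chosen to make the checks sharp but quick: 6 subjects with 6 spectra per
class per subject (288 spectra) for the eight-classifier CV recovery and
the chance-level collapse, and 10 seeds of an 8-subject design (6 train /
2 held out, 4 spectra per class per subject) for the direction of the
pooled-vs-holdout gap. The acceptance script uses 8 subjects with 6
spectra per class per subject.

## Known limitations

* Archetypes are qualitative; absolute accuracies on synthetic data say
  nothing about accuracies on real tissue.
* Pooled (non-subject-grouped) model-selection CV is optimistic by
  construction; the subject-held-out stream is the honest number.
* The Mahalanobis KNN metric is ridge-regularized and degrades gracefully
  but is not meaningful when features vastly outnumber samples.
* Min--max normalization is brittle to single-point outliers (a cosmic
  ray sets the maximum); spike removal is out of scope.
* One calibration pair is shared per dataset; drift between calibration
  and measurement is not modeled.
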