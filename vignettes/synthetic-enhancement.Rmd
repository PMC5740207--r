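---
title: "Synthetic gadolinium enhancement: models, phantom and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic gadolinium enhancement: models, phantom and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthlge)
```

## The signal models

Two closed forms carry the whole pipeline.

**MOLLI apparent recovery.** A Look-Locker-type acquisition samples the
inversion-recovery curve under repeated readouts, so the magnetization
relaxes with an *apparent* time constant T1\* toward a reduced steady
state. The standard three-parameter description is

$$ S(t) = A - B\,e^{-t/T_1^*}, $$

with the Look-Locker correction recovering the true relaxation time,
$T_1 = T_1^*\,(B/A - 1)$. For an ideal inversion ($B = 2A$) the correction
is the identity, $T_1 = T_1^*$. `fit_molli()` fits this model by
Levenberg-Marquardt least squares (`minpack.lm`); because the scanner
stores magnitudes, the sign of the earliest samples is ambiguous, and the
fit restores polarity by exhaustively sign-flipping the $m$ earliest
samples for $m = 0,\dots,n-1$ and keeping the lowest-residual hypothesis.
With 9 samples this is cheap and exact; phase-sensitive reconstruction is
deliberately out of scope.

**Full-recovery IR synthesis.** Once a T1 map exists, a phase-sensitive IR
image at any inversion time is

$$ S(\mathrm{TI}) = 1 - 2\,e^{-\mathrm{TI}/T_1} $$

for unit equilibrium magnetization (`ir_signal()`). The signal nulls at
$\mathrm{TI} = T_1 \ln 2$ and is larger for shorter T1 at display TIs, which
is exactly why gadolinium-rich scar is hyperintense on a
myocardium-nulled image. Incomplete recovery between inversions is not
modeled: synthesis operates on the fitted map, where the full-recovery
form is the standard choice. The package's normalized scale (signed values
in $[-1, 1]$) replaces whatever window/level encoding a scanner would
apply.

## Acquisition timing

`sampling_scheme()` encodes MOLLI block structure. The default 4(1)3(1)2
scheme acquires 9 images in 11 heartbeats; the $k$-th inversion block uses
inversion delay $100 + 80k$ ms and successive images within a block are one
heart period apart (fixed RR interval, default 857 ms; beat-to-beat
variability is not modeled). Whether the 80-ms increment applies in
acquisition order or after TI sorting is ambiguous in routine protocol
descriptions; this package fixes block delays at {100, 180, 260} ms and
returns the TI list sorted with block provenance attached
(`effective_tis()`).

## The phantom

`make_lv_phantom()` draws each short-axis slice as a concentric annulus:
blood pool inside the endocardial radius (default 15 mm), myocardium out to
the epicardial radius (default 25 mm), background beyond; 1.65 mm pixels
and 8 mm slices match the clinical protocol that motivates the defaults.
Scar wedges are specified by slice, angular start/span and transmurality,
growing from the endocardium outward — the subendocardial pattern of
ischaemic scar. Ground-truth mass is the exact wedge-pixel count times
pixel volume times 1.05 g/ml (the quantification literature reports scar
"volume" in grams; the conversion uses standard myocardial density, and the
factor is configurable).

Post-contrast T1 defaults — myocardium 500 ms, scar 300 ms, blood 350 ms —
are literature-informed placeholders chosen so that scar is hyperintense at
a conventional display TI of ~300-350 ms; early post-contrast patient
values are not standardized and the study population's values are unknown.
Background T1 (1000 ms) only matters for making background pixels fittable.

Angles are measured counterclockwise from the ray through the reference
point placed below the inferior wall, matching how segment numbering is
anchored clinically. All pixel coordinates are 1-based (row, col) matrix
indices — the natural R convention; nothing downstream depends on an
0-based export format.

What the phantom does **not** emulate: anatomy beyond a circular annulus,
cardiac or respiratory motion, k-space/SSFP readout effects, partial-volume
edges, surface-coil shading, or papillary muscles. Passing tests therefore
demonstrate the correctness of the *analysis chain* — fitting, synthesis,
thresholding, bookkeeping, statistics — not robustness to the full
messiness of clinical images.

**Noise model.** MOLLI simulation adds zero-mean Gaussian noise to the
signed signal and then takes the magnitude — a Rician-like model, the
standard behaviour of magnitude MR images. Quantification-stage images get
additive Gaussian noise on the signed PSIR values.

## Scar quantification choices

* **Threshold**: scar = annulus pixels *strictly greater* than
  ROI mean + 5·SD; ties are non-scar. The SD uses the $n-1$ denominator.
* **Reference ROI**: at least 100 pixels of normal myocardium.
  `auto_reference_roi()` emulates the reader by accumulating the dimmest
  AHA segments until 100 pixels are reached — on a nulled image remote
  myocardium is dark.
* **Subsegment positivity**: one supra-threshold pixel suffices
  (configurable via `min_call_pixels`); no per-subsegment rule is
  standardized, and the single-pixel rule makes calls consistent with
  per-segment pixel counts by construction.
* **No island filtering by default**: none is described for the reference
  analysis software; a 4-connected minimum-island filter is available
  behind `min_island` for sensitivity analyses.
* Mass additivity (segment masses sum to slice mass, slices to patient) is
  exact by construction and asserted in tests.

## The cohort generator

`make_cohort()` reproduces the structure the accuracy statistics assume:
214 patients, 23 scar-positive, 28 subsegments each (so 5,992 in total;
191 × 28 = 5,348 from scar-free patients). Positive patients carry 1-3
wedges (the study population averaged ~1.7 enhancement areas per positive
patient). Both quantification channels derive from the same ground truth;
each receives independent Gaussian reader jitter on the per-patient mass
(default SD 0.11 g, chosen so the SD of between-channel differences,
jitter·√2 ≈ 0.16 g, sits at the scale reported for ESGE-vs-LGE
quantification). The optional discordance pattern plants one false-negative
patient (a single-subsegment scar the index channel misses) and one
false-positive patient (3 index-only subsegments), yielding the patient
contingency TP 22 / FN 1 / FP 1 / TN 190 — sensitivity 96%, NPV 99.5%,
prevalence 10.7%. `run_study()` excludes patients discordant at the patient
level from quantitative agreement, so the quantitative set is the 22
concordant positives in that pattern.

## Statistics

Accuracy metrics come with Clopper-Pearson exact binomial intervals
(`stats::binom.test`); published clinical CIs often use other methods, so
point estimates, not bounds, are the comparable surface. Display rounding
follows the field's convention: integer percent for sensitivity and
specificity, one decimal for PPV/NPV and prevalence. The ICC is the
two-way random, absolute-agreement, single-measures flavor, ICC(2,1),
computed from the mean-squares decomposition with the McGraw-Wong F-based
interval — implemented here directly and validated in tests against a
variance-component simulation. Wilcoxon zero differences are dropped
(Wilcoxon's original rule, as `stats::wilcox.test` does). Degenerate inputs
(zero denominators, constant vectors, all-zero differences) are reported as
undefined (`NA`), never silently as 0.

## Numerical choices

* Optimizer: `nlsLM` with initialization A = max|S|, B = 2A and a T1\*
  start ladder at {1, 0.5, 2, 0.25} × median TI — the LM step can hit a
  singular gradient from a single unlucky start; bounds T1\* ∈ (1, 5000) ms.
  Convergence failure is reported in the fit object (`converged = FALSE`),
  never thrown.
* Pipeline determinism: one root seed, split per stage by a fixed hash, so
  a re-run is byte-identical and an interrupted run resumes from completed
  stage artifacts.
* Problem sizes: the phantom defaults to 128-pixel slices; tests and the
  acceptance script use 32-64-pixel phantoms and single slices where the
  property under test does not depend on resolution, keeping the suite fast
  while the geometry tests still see several hundred annulus pixels.

## Known limitations

* The phantom's circular geometry makes segment pixel counts nearly equal;
  real ventricles do not, and ROI placement on real images is a reader
  choice this package only emulates.
* Per-subsegment masses in the cohort generator are exact pixel counts, not
  re-thresholded images; the imaging chain (simulate → fit → synthesize →
  quantify) is exercised per-phantom in `run_pipeline()` rather than per
  cohort patient, for tractability.
* Only 5 slices are modeled, so total-LV infarct volume is out of scope,
  as it is for the 5-slice clinical protocol itself.
* Correlation and ICC values from the synthetic cohort depend on the
  generator's mass spread and jitter; they are reported as computed, not
  tuned to match any published value.
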