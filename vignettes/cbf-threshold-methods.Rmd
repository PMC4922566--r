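---
title: "Deriving an absolute CBF threshold for infarction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving an absolute CBF threshold for infarction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfcore)
```

## The problem

When a cerebral artery is occluded, tissue below a critical perfusion level
progresses to infarction while surrounding hypoperfused tissue (penumbra and
oligemia) can survive. CT perfusion (CTP) produces quantitative cerebral
blood flow (CBF) maps in mL·min⁻¹·100g⁻¹, and a fixed CBF cutoff is the
simplest rule for delineating the irreversibly damaged core during the acute
phase. `cbfcore` implements a pipeline for deriving such a cutoff from a
controlled large-animal experiment: focal ischemia is induced with
endothelin-1 (ET-1), perfusion is followed with serial CTP over three hours,
and tissue fate is read out contemporaneously with a PET ligand
(a fluorinated flumazenil analogue) whose cortical uptake marks intact
GABA-A receptors — an uptake defect marks infarcted grey matter. Because
flow and outcome are measured in the same session, the derived threshold is
not confounded by later infarct expansion.

## Per-subject procedure

All volumes are assumed co-registered on one grid (registration is done
upstream; the pipeline never resamples). For one subject:

1. **Median CBF map.** The serial CBF maps are reduced per pixel to their
   temporal median. The median damps transient reperfusion: a pixel's value
   is unchanged when up to `floor((n-1)/2)` of its largest time-point values
   are perturbed upward. The pre-injection baseline scan (`time_min <= 0`)
   is excluded by default — a normal-flow point in a seven-element median
   would bias infarct CBF upward. Whether the original analysis included it
   is not determinable, so `include_baseline = TRUE` is available.
2. **PET defect segmentation.** Within the affected cortical ROI, pixels
   with PET signal strictly below `mean - 2·SD` of the contralateral ROI are
   infarct; the rest are non-infarct (penumbra/oligemia). The contralateral
   statistic is pooled over all slices of the ROI; per-slice statistics are
   available (`per_slice_stats`) for sensitivity analysis, without any claim
   about the original procedure.
3. **Grey/white matter.** The PET ligand binds cortex, so pixels below
   40 HU on the average CT image (white matter, background) are excluded.
4. **Vessel exclusion.** Pixels with blood volume strictly above the
   affected-ROI `mean + 2·SD` (computed on the raw ROI, before any other
   exclusion) or with median CBF strictly above 100 mL·min⁻¹·100g⁻¹ are
   treated as vessels and removed from both classes.
5. **Class table and balancing.** Retained pixels form a table of
   (median CBF, label). The non-infarct class is typically much larger, so
   every infarct row's weight is multiplied by the ratio of class totals.
   This equalizes class mass — the continuous analogue of scaling histogram
   bin counts — without changing within-class relative frequencies, so the
   ROC analysis is provably unaffected while the logistic fit is no longer
   dominated by the large class. A literal binned mode
   (`balance_classes(bin_width = 1)`) is provided as well.
6. **Logistic regression.** `P(infarct | CBF) = plogis(b0 + b1·CBF)` is fit
   by weighted maximum likelihood (IRLS). The CBF at 75% predicted
   probability is one per-subject summary.
7. **ROC analysis.** A cutoff sweep over the observed CBF values (positive
   call: `CBF <= t`) yields sensitivity, specificity and trapezoidal AUC;
   the optimal operating point maximizes Youden's J, and the CBF there is
   the subject's infarction threshold.

Per-subject thresholds are then aggregated with `summarize_cohort()`, which
always reports mean, sample SD and SE explicitly because "mean ± x"
conventions are ambiguous.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `pet_k` | 2 | contralateral SDs | PET defect depth |
| `hu_min` | 40 | HU | grey/white cutoff |
| `bv_k` | 2 | affected-ROI SDs | BV vessel rule |
| `cbf_vessel_cap` | 100 | mL·min⁻¹·100g⁻¹ | median-CBF vessel rule |
| `min_defect_fraction` | 0.05 | — | minimum infarct fraction of affected grey matter for a subject to count as having a defect |
| `p` in `probability_crossing()` | 0.75 | — | probability level summarizing the logistic curve |

`min_defect_fraction` deserves a note: the defect call in the original
procedure was visual. The `mean − 2·SD` rule labels ~2.3% of defect-free
tissue "infarct" by chance alone, so analyzability cannot be `infarct mask
non-empty`. The default 0.05 sits well above the chance rate and well below
the ~13% observed on phantoms with a true defect.

## The synthetic study

No animal data are distributed, so `generate_study()` builds a phantom with
the experiment's statistical structure and a known answer:

* two-hemisphere cylindrical slab: a grey-matter ribbon (45 ± 1.5 HU)
  around a white-matter core (35 ± 1.5 HU), air background;
* baseline grey-matter CBF field 50 ± 8 mL·min⁻¹·100g⁻¹ held across time,
  with additive per-time-point noise (SD 4);
* a ~1.5 mL spherical infarct whose relative CBF follows the observed
  course — 56% of baseline at 10 and 30 min, 40% from 60 min to 180 min;
* affected-side non-infarct grey matter (oligemia) at 62% of baseline;
* a PET field of 100 ± 5 with the infarct mean shifted down 4 SD;
* 2% of cortical pixels as vessels (BV 3× parenchymal mean, CBF 150).

Absolute baseline CBF is not reported for this model; 50 is consistent with
the reported post-injection infarct-region flow near 15–20 at ~40% rCBF.
The oligemia fraction, CBF noise and infarct radius are not reported either;
they were fixed once so that the phantom reproduces the experiment's
discrimination regime — per-subject AUC ≈ 0.84, within the reported
0.75–0.89 band — and its ~1.5 mL infarct volume, and they are not meant to
be tuned per analysis.

The ground truth carries the exact masks and the *population optimum* of the
derived threshold: the CBF at which the two classes' median-CBF densities
cross, which is where Youden's J is maximized regardless of class mass.
Those densities are not Gaussian (each pixel's value is a median over a
56%/40% time course plus noise), so the optimum is computed numerically from
the generative law: a deterministic 10⁵-draw Monte-Carlo sample of class
medians, with the argmax of the ECDF difference located as the vertex of a
local quadratic fit (stable to ~0.01 mL·min⁻¹·100g⁻¹, unlike a raw argmax
or a kernel-density crossing, which carry noise and smoothing bias).

`simulate_monitoring()` reproduces the experiment's on-line re-dosing rule
(second ET-1 dose when infarct-region CBF rises strictly above
~20 mL·min⁻¹·100g⁻¹) and can construct wear-off trajectories for phantoms;
it does not feed the default generator.

### What the phantom does and does not emulate

It reproduces the pieces the statistics consume: class-conditional CBF
distributions with realistic overlap, a deep PET defect against a clean
contralateral reference, HU-separable tissue classes, vessel outliers, and
strictly increasing acquisition times. It does **not** emulate anatomy,
partial-volume mixing at tissue borders, spatially correlated deconvolution
noise, PET resolution effects, or motion. Passing recovery tests therefore
demonstrates correctness of the estimator under the modelled statistical
structure, not robustness to every artefact of real CTP/PET data.

## Numerical choices

* "Less than" and "greater than" in every rule are strict, exactly as
  stated; equality stays in the retained class (a 40.0 HU pixel is grey
  matter; BV exactly at threshold is parenchyma).
* Even-count medians are the midpoint of the central pair; non-finite
  pixels are dropped per pixel with a reported count; ROI statistics use
  the sample (n − 1) SD, with SD 0 for single-pixel ROIs.
* IRLS stops at relative log-likelihood change < 1e-10 or coefficient step
  < 1e-8, max 100 iterations; complete separation (fitted probabilities
  collapsing onto the labels) is reported as `converged = FALSE` with the
  last iterate.
* ROC positives are `CBF <= t`, making every threshold attainable at a data
  value; Youden ties break toward the lower CBF. Weights enter the curve
  only through within-class ratios (normalized by the class maximum), so
  class balancing leaves the curve bit-identical for the uniform weights the
  pipeline produces.
* The logistic fit uses raw per-pixel values by default (lossless); the
  binned mode mirrors the histogram formulation.

## Design decisions made where the design was open

* **Optimality criterion.** "Optimal operating point" is implemented as the
  Youden maximum, with closest-to-(0, 1) as a selectable alternative;
  results always name the criterion used.
* **Pooled ROI statistics.** Whether reference statistics were pooled over
  slices or computed per slice is unknowable; pooling is stabler for small
  per-slice ROIs and is the default, with the per-slice variant exposed.
* **Baseline scan.** Excluded from the median by default (see above), with
  a flag to include it; both behaviours are first-class.
* **Defect call.** Fraction-based analyzability rule (see above).

## Problem sizes

The test suite exercises full 64 × 64 × 8 study-regime phantoms for
end-to-end recovery (120 subjects across 20 cohorts) and 48 × 48 × 6
phantoms for unit-level checks; the analytic logistic oracle uses 10⁵
pixels per class. These sizes give Monte-Carlo error well below every
tolerance asserted while keeping a full run comfortably interactive.

## Known limitations

* Thresholds are for one ischemia duration (~3 h); the threshold for
  infarction is strongly time-dependent and nothing here models that
  dependence.
* No confidence intervals on per-subject thresholds are produced, matching
  the original report; the cohort SE quantifies only between-subject spread.
* The pipeline assumes registration quality is good enough that pixel
  indices correspond across modalities; misregistration propagates silently.
* Per-subject results depend on hand-drawn ROIs; the phantom's mirrored
  ROIs are idealized.
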