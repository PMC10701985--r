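---
title: "Methods: the ctqa decision layer for chest-CT quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ctqa decision layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqa)
```

## Scope and model

`ctqa` is the deterministic decision layer of a no-reference quality
assessment pipeline for chest CT examinations. Upstream, trained models
locate regions of interest: an object detector emits labelled,
confidence-scored bounding boxes; a semantic segmenter emits 3-channel
masks for the tracheal carina, the body contour and the lung contour.
This package deliberately contains no learning: backends are pluggable
behind the `detect()`/`segmentROI()` generics, and a scripted mock
backend replays fixture outputs so every decision rule can be tested in
isolation and end to end. Eight sub-parts are assessed per patient and
combined by a points rubric into two binary accept/reject decisions.

Multi-view routing assigns each sub-part the scan planes it draws on:
inspiration sub-parts (tracheal carina, bronchial beam, rib) use the
axial and sagittal stacks, with the carina image selected from the
axial stack; body centring uses the axial stack; scan-baseline
alignment, arms position and radiation protection use the coronal
plane; artifact detection uses the axial plane. The routing map is a
configuration entry (`defaultRouting()`), because within a real
examination the assignment of images to tasks is a site convention, not
a property of the algorithms.

## The four algorithms

**Pixel threshold (PT).** The carina mask encodes morphology by colour:
white for convex (good inspiration), green for flat, red for concave.
Per pixel, white requires all three channels in [200, 255]; the two
colour conditions (G ∈ [150, 255], R ∈ [150, 255]) overlap, both with
white and with each other, so an evaluation order is needed. We test
white first — it is the strictest condition — and resolve the green/red
overlap by the larger of the two channels, green winning exact ties.
Morphology is the argmax of the three counts. Count ties break toward
the lower-scoring morphology (concave < flat < convex): ambiguous
evidence is penalized, never rewarded. A mask with zero classifiable
pixels is an error ("no mask content"), which the pipeline converts to
the worst category.

**Neural statistics (NS).** For bronchial-beam and rib clarity a single
slice is unreliable; the NS tally emulates a reader reviewing the whole
stack. Every detection box that survives the confidence filter is
counted by category across all routed series — box counts, not image
counts, so an image with two "fuzzy" boxes contributes two. The final
category is the count argmax, ties again toward the lower score.
Confidence weighting was considered and rejected: the tally is meant to
count independent sightings, and weighting would couple the decision to
backend calibration.

**Region measurement.** The body-contour mask is converted to grayscale
(unweighted channel mean — the masks are synthetic colours, so luma
weighting has no justification) and binarized at intensity 5
(foreground iff intensity ≥ 5). The decision compares the Euclidean
distance between the foreground centroid and the image centre with a
50-pixel radius: inside iff distance < radius. The strict comparator
follows the decision formula; because the surrounding prose of the
source method is phrased inclusively, the comparator is configurable
(`ctqaConfig(comparator = "le")`), with `"lt"` the default. The
centring slice is the axial image with the largest body area — the most
representative cross-section — since nothing in the method fixes a
slice.

**Distance measurement.** The lung mask is binarized the same way and
tightly boxed. Signed distances to the overlay baselines are
`D_start = y_boxtop − y_startline` and `D_end = y_endline − y_boxbottom`,
and a baseline is accurately placed iff `0 ≤ D ≤ T` with T = 15 px.
Applying the tolerance to the raw signed value would label a negative
distance — the baseline *inside* the lung extent, i.e. truncated
anatomy — as accurate; we therefore require non-negativity as well.
This is the one place the implementation tightens the literal decision
formula, and it is deliberate.

## Thresholds and parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `minScore` | 0.70 | confidence | detection filter; strictly greater-than |
| `radius` | 50 | px | centring circle |
| `tolerance` | 15 | px | baseline alignment band |
| `binarizeThreshold` | 5 | intensity | mask foreground cut (≥) |
| PT white range | [200, 255] | intensity | all channels |
| PT colour range | [150, 255] | intensity | G or R channel |

All live in one `ctqaConfig()` object; the defaults are the study
values and are what the test suite and the acceptance script freeze.

## Scoring and decisions

The rubric is a data table (`defaultRubric()`, YAML-serializable):
carina 10/5/0 (convex/flat/concave); bronchial beam 15/10/5/0
(visible/fuzzy/double shadow/curly); rib 15/10/5/0
(visible/corrugation/double shadow/multiple shadows); scan baseline
10/5/0 (both/one/none correct); radiation protection 10/5/0
(both/one/none); artifact 10/5/0 (none/foreign matter/radial artifact);
arms and body position 5/0. Inspiration = carina + beam + rib, max 40;
overall total max 80. A task is acceptable iff its score strictly
exceeds half its maximum (> 20, > 40) — a score of exactly 20 or 40 is
inacceptable.

Degenerate inputs never abort a patient: a missing plane, missing
baselines, an unfound carina or an empty tally downgrade the affected
sub-part to its worst category with a warning. The rationale is
monotone: an unevaluable sub-part must not inflate quality. The same
worst-first logic resolves contradictory evidence (an arms-raised and
an arms-not-raised box in one series scores not-raised; a series with
both foreign matter and radial artifacts scores radial artifact).

## Metrics

Patient-level comparisons use the standard 2×2 tally with "acceptable"
as the positive class, and precision, sensitivity, specificity and F1.
A metric with a zero denominator is reported as undefined (`NA`) and
excluded from macro averages — coercing 0/0 to 0 would bias the
subclass means. Detector evaluation uses greedy one-to-one box matching
in descending confidence order at IoU strictly greater than 0.70, with
per-label TP/FP/FN; true negatives are undefined for detection, so
specificity is only reported for patient-level decisions. The 0.70
figure appears in the source method both as a confidence cutoff and as
an IoU cutoff; at inference there is no ground truth, so the runtime
filter is a confidence cutoff, and IoU matching lives only in the
evaluation utilities. Both knobs are separate and configurable.

## Synthetic fixtures

The generator produces everything the pipeline consumes, under a seed:

- **Carina masks** paint disjoint pixel sets near (227,227,227),
  (20,200,20) and (200,20,20) with uniform channel noise clamped (half
  width ≤ 27) so no pixel can cross a classification threshold; the
  expected morphology is the argmax of the painted counts.
- **Geometry images** place an odd-extent body rectangle whose centroid
  is exactly the image centre plus a requested offset, and a lung block
  whose bounding-box rows realise requested signed baseline distances
  exactly; images are 161×161 px (odd, so the centre is an integer
  pixel).
- **Detection streams** emit per-category box counts above the cutoff
  plus sub-cutoff distractors the filter must remove.
- **Patients** (`genPatient()`) combine all of the above across three
  planes for a target category per sub-part, sampled uniformly by
  `randomFixtureSpec(seed)`.

Ground truth is derived analytically from the generation parameters at
generation time — never by running the pipeline — so closed-loop tests
(pipeline report equals implied truth) cannot be circular. Category
sampling is uniform per sub-part, which intentionally over-represents
poor quality relative to a clinical population; the fixtures probe
decision correctness, not prevalence. What the fixtures do *not*
emulate: real CT appearance, backend errors (the mock is perfect),
anti-aliased mask edges, or anatomically plausible geometry.
Consequently, passing tests demonstrate that the decision layer is
correct *given* backend outputs; they say nothing about detector or
segmenter accuracy on real data.

## Numerical and design notes

- Pixel coordinates are 0-based, top-left origin, y downward; boxes are
  half-open. Image indices within a series are 1-based (R convention).
- Carina selection ties (equal confidence) go to the lowest image
  index, stably under box reordering.
- The problem sizes in the suite — 161×161 fixtures, series of 2–3
  images, 100 closed-loop seeds, 50-instance oracle comparisons, the
  full 5184-combination rubric enumeration — were chosen as the
  smallest sizes that exercise every branch and boundary of the
  decision rules.
- DICOM handling is narrowed to what the decision layer needs: series
  load from PNG/TIFF and baselines from either a JSON sidecar
  (`{"y_start": r1, "y_end": r2}`) or an overlay bitmap in which the
  two baseline rows are the only non-zero pixels (each maximal run of
  rows is one segment; exactly two must exist). Pixel spacing, HU
  calibration and multi-frame files are out of scope.

## Known limitations

Real detector/segmenter adapters are seams, not implementations; no
claim is made about end-to-end accuracy on clinical data. The rubric
and thresholds are fixed to one site's criteria, though both are
configuration. The generator's uniform category sampling is not a
clinical prior. Sub-pixel mask effects are outside the PT model.
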