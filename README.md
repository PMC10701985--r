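# ctqa — rubric-based no-reference quality assessment for chest CT

Chest CT image quality is routinely judged by radiologists before a scan is
accepted for diagnosis: was inspiration adequate, was the patient positioned
and aligned correctly, were radiation-protective products worn, are there
artifacts? Doing this by eye is slow and subject to fatigue and inter-observer
variability. `ctqa` implements the *decision layer* of an automated multi-view,
multi-task assessment pipeline for this problem: it consumes the outputs of
pluggable detection/segmentation backends (labelled bounding boxes with
confidences, 3-channel region masks) and turns them into per-sub-part
categories, rubric points, and binary accept/reject decisions. It ships a
deterministic scripted mock backend and a seeded synthetic fixture generator,
so the entire pipeline is testable without trained models or patient data.

## The algorithms

Eight sub-parts are scored per patient from three scan planes (axial,
sagittal, coronal). Four deterministic algorithms drive them:

- **Pixel threshold (PT)** — tracheal carina morphology. The carina
  segmentation mask encodes morphology by colour. Each pixel is classified as
  *white* iff R, G, B ∈ [200, 255], else *green* if G ∈ [150, 255] (G ≥ R),
  else *red* if R ∈ [150, 255]. The morphology is the argmax of the three
  counts: white → convex (adequate inspiration), green → flat, red → concave.
- **Neural statistics (NS)** — bronchial-beam and rib clarity. Every filtered
  detection box across the whole series is tallied by category;
  `FinalCategory = argmax(CategoryCount)`. Mimics a radiologist reviewing many
  slices instead of trusting one.
- **Region measurement** — body centring. The body-contour mask is binarized
  (`B(x,y) = 1 iff I(x,y) ≥ 5`), its centroid `(x_b, y_b)` compared with the
  image centre `(x_g, y_g)`:
  `Distance = sqrt((x_b − x_g)² + (y_b − y_g)²)`; *inside* iff
  `Distance < radius` (radius = 50 px).
- **Distance measurement** — scan-baseline alignment. The lung mask's tight
  bounding box is compared with the overlay baselines:
  `D_start = y_boxtop − y_startline`, `D_end = y_endline − y_boxbottom`;
  a baseline is *accurate* iff `0 ≤ D ≤ T` (T = 15 px).

Detections enter the decision layer only after a strict confidence filter
(confidence > 0.70). Categories map to points through a data-driven rubric
(carina 10/5/0; bronchial beam and rib 15/10/5/0; scan baseline, radiation
protection and artifact 10/5/0; arms and body position 5/0). The inspiration
score (carina + beam + rib, max 40) and the overall total (max 80) yield
binary decisions: acceptable iff the score strictly exceeds half the maximum
(> 20, > 40). Classification metrics (precision, sensitivity, specificity,
F1, macro-averaged over subclasses) and greedy IoU > 0.70 box matching are
included for backend evaluation.

## Worked example

```r
library(ctqa)
fx  <- genPatient(randomFixtureSpec(5))      # seeded synthetic patient
rep <- evaluatePatient(fx$series, fx$detector, fx$segmenter)
rep
```

```
QualityReport for 'synth-5'
  tracheal_carina      flat                5
  bronchial_beam       double_shadow       5
  rib                  visible            15
  scan_baseline        none_correct        0
  body_position        inside              5
  arms_position        raised              5
  radiation_protection both               10
  artifact             no_exist           10
  inspiration: 25/40 (acceptable)
  overall:     55/80 (acceptable)
```

Each row is one sub-part with its assessed category and rubric points. Here
the carina mask was majority-green (flat, 5/10), the beam tally's argmax was
"double shadow" (5/15), and neither baseline fell within 15 px of the lung
box (0/10); the inspiration score 25 > 20 and the total 55 > 40, so both
decisions are *acceptable*. The same pipeline runs from the shell over an
on-disk fixture:

```sh
Rscript inst/exec/ctqa synth --seed 5 --out fix/
Rscript inst/exec/ctqa evaluate --input fix/ --out report.json
```

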