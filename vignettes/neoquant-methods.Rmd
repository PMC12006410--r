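---
title: "Quadrant-based neointima quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-based neointima quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After percutaneous coronary intervention (PCI), a stented artery heals by
growing a neointimal layer over the metal struts. The maturity of that
tissue predicts outcome: uniform *homogeneous* neointima is a benign
endpoint, while *heterogeneous* backscattering and frank
*neoatherosclerosis* (foam cells, fibroatheroma, calcification inside the
neointima) are associated with late stent failure. Intravascular optical
coherence tomography (OCT) resolves these patterns in vivo, but manual
frame-by-frame reading is slow and reader-dependent.

`neoquant` automates the standard quadrant scoring workflow on an OCT
pullback:

1. **Segmentation** — every frame is segmented pixelwise into background,
   lumen, neointima and stent struts.
2. **Geometry** — the lumen centroid anchors a partition of the frame into
   four 90° quadrants, clockwise from 12 o'clock (Q1 spans 12–3 o'clock).
   Each quadrant is cropped to its bounding box, out-of-quadrant pixels
   zeroed, and resized to 224 × 224 px.
3. **Classification** — each quadrant crop receives one of four labels:
   `homogeneous`, `heterogeneous`, `neoatherosclerosis`, or
   `not_analyzable` (a quadrant containing uncovered struts or a
   side-branch opening). Where tissues mix, the most severe is scored,
   ordered homogeneous < heterogeneous < neoatherosclerosis;
   `not_analyzable` is structural and overrides tissue.
4. **Calibration** — class probabilities pass through test-time
   augmentation, temperature sharpening
   \(q_i = p_i^{1/T} / \sum_j p_j^{1/T}\), and fusion with the two
   angularly adjacent quadrants, so the reported confidence tracks the
   probability of being correct.
5. **Morphometrics** — ray casting from the lumen center measures lumen
   radius and neointimal thickness per angle; aggregates include the
   minimal lumen diameter (MLD) and its frame, uncovered-strut counts and
   stent boundaries.

Everything is exercisable end to end on a built-in synthetic phantom
generator with exact ground truth; no clinical data ship with the package.

## The phantom generator

`phantomSpec()` / `generatePhantomFrame()` draw an annular cross-section:
a circular lumen, a neointima annulus whose thickness and tissue class are
piecewise constant over equal angular sectors (8 by default, two per
quadrant), strut reflectors, and optionally a side-branch opening. The
sector discretization is deliberate: per-pixel mask membership reduces to
a distance/angle test that an independent brute-force oracle can verify
exactly, and mixed-tissue quadrants (for the severity rule) fall out of
sector-level assignment.

Texture models encode the qualitative OCT definitions with minimal
parameters:

* **homogeneous** — mid-bright base with low-variance single-scale
  speckle ("uniform light reflection");
* **heterogeneous** — two-scale speckle under a strongly bimodal patchy
  gain field ("focal variation of the backscattering pattern");
* **neoatherosclerosis** — bright superficial rim with a fixed
  attenuation length of ≈ 3 px, leaving a signal-poor core (the
  lipid/foam-cell appearance). Tissue backscatter is capped below the
  specular strut level: in OCT only metal saturates the detector.

Struts are discs on the vessel wall rendered at near-saturation with a
1-px *blooming ring* outside the true boundary at full strut brightness.
The ring is the package's model of the classic OCT strut artifact, and it
is what keeps the strut class the hardest to segment — reproducing the
clinical difficulty ordering lumen > neointima > strut — without planting
strut-like signal away from real struts. *Covered* struts are embedded
with ≥ 3 px of neointima on the luminal side (so strut + bloom never touch
the lumen); *uncovered* struts protrude 1.2 radii into the lumen with the
annulus zeroed in a narrow angular window above them, matching the
class definition. Shadows attenuate the image radially behind each strut;
the mask is unaffected.

Structural quadrant labels are attributed by angular *pixel extent*: a
strut straddling a quadrant edge makes both quadrants `not_analyzable`
(≥ 2° of visible strut), and a side branch counts only when it opens ≥ 5°
into the quadrant. A center-angle rule would mislabel the neighbour
quadrant whenever a strut sits on the boundary.

`generatePullback()` emulates a pullback at 0.2 mm frame pitch (five
frames per millimetre; every fifth frame carries the 1-mm manual
annotation flag), with struts only inside a configurable stent interval.
Per-frame geometry is randomized; quadrant tissue classes are sampled with
*angular coherence* (a dominant per-frame class followed 65% of the time).
Real neointima is angularly correlated, and the neighbour-fusion
calibration step presupposes that correlation — under independent
per-quadrant sampling, fusion degrades accuracy rather than calibration,
which would misrepresent the method being modelled.

What the phantom does *not* emulate: catheter and guide-wire artifacts,
polar-acquisition geometry (A-line sampling), eccentric/elliptical lumens,
motion between frames, and the full perceptual difficulty of clinical
tissue boundaries. Passing tests on phantoms therefore demonstrate that
the pipeline's machinery is correct and learnable at desk scale, not that
the desk-scale models match clinical-grade networks on patient data.

## Segmentation

The segmentation stage is pluggable behind the `SegModel` handle. The
default desk-scale model is a probability random forest over seven
per-pixel features: raw intensity, Gaussian-smoothed intensity at σ = 2
and 6 px, local standard deviation at the same two scales, fine detail
(|raw − smooth|), and normalized distance from the frame center. Training
samples up to 350 px per class per frame — the stratification that keeps
the tiny strut class from collapsing (the role class weighting plays in a
CNN loss). The forest runs single-threaded with a fixed seed, making
training and inference bit-reproducible.

Postprocessing keeps the largest connected lumen component with holes
filled (struts or neointima inside a filled hole keep their labels),
removes strut components below a minimum area (default 5 px), and leaves
neointima unchanged. It never introduces a foreground label absent from
the raw mask.

With 60 training phantoms (96 px) the held-out Dice ordering is
lumen > neointima > strut, mirroring the difficulty ordering reported for
clinical data: the lumen is a large dark region, neointima a textured
band, struts tiny blooming objects whose true boundary is ambiguous.

## Quadrant classification

Classification is likewise pluggable behind `QuadModel`; the desk-scale
default is a single-hidden-layer softmax network (12 hidden units,
weight decay 5e-4) over 18 engineered features of the 224 × 224 crop. The
features mirror how the tissue classes are defined, anchored at the
lumen: the dark connected component nearest the wedge apex is taken as
lumen (merged with dark components lying hard against it, since a
protruding strut can split it), and a distance map from it yields

* ring means at depths 0–3, 3–6, 6–10, 10–15 px and their slope
  (attenuation — the neoatherosclerosis signature);
* wall-band statistics (mean, SD, 10th/90th percentile, dark and bright
  fractions);
* blockwise patchiness of the wall band (the heterogeneous gain field);
* gradient energy;
* a bright-contact fraction and a per-reflector "wrapped in lumen
  darkness" score (uncovered struts), and an open-boundary fraction
  (side branches);
* the lumen fraction of the wedge.

Features are standardized with training statistics stored in the handle.
Training is seeded and deterministic; validation accuracy and the
confusion matrix are logged.

## Calibration

The inference chain is TTA-average → sharpen → fuse → renormalize.

* **TTA** — horizontal flip and ±10% intensity gain, plus identity.
  Rotations are excluded by design: they would move tissue across the
  fixed 12-o'clock quadrant frame.
* **Sharpening** — `sharpenProbs(p, T)` implements
  \(q_i \propto p_i^{1/T}\); `T = 1` is the identity, the argmax is never
  changed, and `T → 0` approaches one-hot.
* **Fusion** — `fuseNeighbors()` mixes each quadrant with its two angular
  neighbours: \(f_q = w_\text{self} p_q + w_\text{n}(p_{q-1} + p_{q+1})\),
  circularly indexed, renormalized.

Two defaults differ from the obvious first guesses, for measured reasons.
Giving the two neighbours jointly the same weight as the quadrant itself
(w = 0.5/0.25/0.25) lets neighbours outvote the quadrant's own evidence
and costs several points of accuracy; the package default is
(0.8, 0.1, 0.1). And a fixed sharpening temperature below 1 is only
appropriate for an *underconfident* base model — with a shallow,
well-regularized network the raw softmax is already close to calibrated,
and hard sharpening makes reliability worse. The package therefore ships
`fitCalibration()`, which selects `(T, w_self)` jointly on held-out
validation frames by expected calibration error (or NLL), the standard
temperature-scaling practice; `calibrationConfig()` defaults to a neutral
`T = 1`. Validation data only are used for this selection; test frames
are never touched. On phantoms the fitted chain is both slightly more
accurate than raw softmax (fusion exploits the angular coherence of
tissue) and substantially better calibrated, and mixed-texture quadrants
receive visibly lower confidence than pure ones — the behaviour expert
disagreement shows on clinical frames.

## Morphometrics

Rays are cast from the lumen centroid at 1° steps, sampling the nearest
mask label every 0.5 px (no interpolation of categorical labels — a
deliberate determinism choice). Per ray, lumen radius is the distance to
the last lumen pixel (rays whose lumen run reaches the image border, e.g.
a side-branch opening, report missing values), and neointimal thickness is
the contiguous wall run beyond the boundary, counting embedded struts as
wall but scoring pure-strut runs (an uncovered strut against the boundary)
as zero. The per-frame diameter is the minimum over angles of
*opposing-ray sums* — robust to an off-center reference point — and the
MLD frame is the argmin within the stent interval, ties resolved to the
lowest index.

Uncovered struts are connected strut components whose 1-px dilation
touches lumen with at most a configurable neointima run (default 0,
direct contact) between their luminal face and the lumen. Stent
boundaries come from per-frame strut pixel counts, median-filtered with
window 3, thresholded at max(5 px, 10% of the median nonzero count); a
pullback in which no frame passes reports "no stent detected" rather than
raising. All thresholds are arguments with these defaults.

## Evaluation protocols

Dice is 2|A∩B|/(|A|+|B|), with the both-empty case defined as 1 and
flagged — frames with absent neointima are the canonical low-score case,
and a defined value avoids NaN propagation. Macro-F1 averages per-class F1
over classes present in truth or prediction. Fleiss' κ uses the standard
formula with the undefined case (expected agreement 1) returned as a
flagged `NA`. Reliability curves use 10 *equal-count* bins (sizes differ
by ≤ 1, stable sort ties), so the size-weighted mean of bin accuracies
equals overall accuracy by construction. `patientKFold()` assigns whole
patients to folds greedily, largest patient first into the smallest fold,
guaranteeing no patient straddles folds while balancing frame counts.

## Numerical and design choices

* Angles are measured at pixel centers; quadrant intervals are half-open
  `[90(q−1), 90q)`, so boundary pixels resolve deterministically (a pixel
  directly above the center is Q1, directly right is Q2). A pixel exactly
  at the center lands in Q1.
* Argmax ties everywhere resolve to the lowest class index.
* Images resize bilinearly; masks use nearest-neighbour stepping.
* The degenerate no-lumen frame uses the image center, labels all four
  quadrants `not_analyzable` with confidence 0, and is flagged.
* Tissue composition in reports is computed over analyzed
  (non-`not_analyzable`) quadrants within the stent interval, with the
  `not_analyzable` fraction reported separately — the denominators are
  stated because published pullback-level panels often leave them
  implicit.
* I/O: pullbacks are PNG/TIFF frame directories or zip archives, natural-
  sorted; intensities are min-max normalized per pullback. DICOM input is
  out of scope for this implementation. Masks round-trip exactly through
  palette PNGs (0/85/170/255); label tables round-trip through CSV with
  tolerant class-string normalization.

## Problem sizes

The package's own test and acceptance runs use 96-px phantom frames:
segmentation trained on 60 frames and evaluated on 20 held-out frames;
the classifier trained on 600 quadrants (150 frames), calibrated on 60
validation frames, and evaluated on 500 held-out quadrants; morphometrics
checked over 50 random phantoms; and bookkeeping verified on a
1148-frame, 64-px corpus (4592 quadrants). These sizes were chosen as the
smallest at which the phantom tasks have stable learning curves.

## Known limitations

* The desk-scale models are feature-engineered learners, not deep
  networks; they demonstrate the pipeline's correctness on phantoms and
  make no claim about clinical images.
* Layered neointima is not distinguished from heterogeneous (a single
  class covers both), and apposition/malapposition distances are not
  measured.
* Along-pullback fusion (same quadrant, adjacent frames) is not
  implemented; fusion is in-frame only.
* The phantom's circular-lumen geometry flatters centroid-based ray
  casting; strongly eccentric lumens would stress the opposing-ray
  diameter more than these tests do.
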