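---
title: "Cascaded regression trees for cephalometric landmarks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded regression trees for cephalometric landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cephert)
```

## The problem

Orthodontic diagnosis from a lateral cephalogram starts with 26 named
anatomical landmarks — skeletal points such as Sella, Nasion, A point and
Menton, dental points such as the incisor root and crown tips, and the
soft-tissue profile from Glabella to soft-tissue Pogonion. The landmarks
themselves matter less than the angular features derived from them: SNA
and SNB relate maxilla and mandible to the cranial base, ANB = SNA − SNB
summarizes the sagittal discrepancy between the jaws, the incisor
inclinations and mandibular-plane angle describe the dentition, and
G-Sn-Pg′ the soft-tissue convexity. Manual annotation takes an expert
10–15 minutes per film and varies between raters, which motivates
automatic localization.

`cephert` implements the cascaded ensemble-of-regression-trees (ERT)
approach to this problem: a sequence of boosted ensembles of shallow
regression trees, each refining a current estimate of all 26 landmark
positions jointly, using intensity differences between pixel pairs
indexed relative to the current shape estimate. The same family of
models is the standard fast face-alignment method; here the landmarks
are spread across the whole film rather than clustered on facial
features, which the joint 52-dimensional updates handle naturally.

## The model

A fitted model (`ert_train()`, returning an `ert_model`) consists of:

* a **mean shape** — the similarity-normalized average of the training
  shapes (two alternated align/average passes of a generalized
  Procrustes fit), stored with the training frame size;
* **T cascade stages**, each holding a pool of sampled feature points
  (a pixel position expressed as an anchor landmark plus an offset in
  the mean-shape frame) and **K gradient-boosted regression trees**.

Prediction starts from the mean shape scaled into the full image
rectangle — cephalograms are acquired with the skull filling the film,
so no detector box exists or is needed. At each stage, the similarity
transform aligning the mean shape to the current estimate is computed in
closed form; every pool offset is rotated/scaled through it and added to
its anchor's current position; intensities are read with nearest-pixel
lookup (out-of-bounds positions read 0). Each tree descends by comparing
intensity differences of pixel pairs against a threshold and adds its
leaf — a 52-vector of coordinate corrections — scaled by the shrinkage
`nu`.

Training builds `oversampling` (R) examples per image with distinct
initial shapes: the first is the placed mean shape, the rest are
ground-truth shapes of other randomly chosen training images, which
covers the realistic range of initial misalignment. Trees are fitted by
greedy sum-of-squares reduction: each node draws
`candidate_splits_per_node` random (pixel pair, threshold) proposals —
pairs accepted with probability `exp(-d/lambda)` so that splits compare
nearby pixels, thresholds uniform on ±80 intensity units — and keeps the
proposal with the largest reduction in summed squared residuals, the
first drawn winning ties. Leaf values are mean residuals of the examples
reaching the leaf.

**Residuals live in the image frame.** Leaf vectors are pixel
corrections in the training image frame; the similarity alignment is
used only to index features. Because each leaf is the mean of the
residuals it updates, applied with `nu` in (0, 1], the training
sum-of-squares cannot increase at any tree, and since residuals carry
over unchanged between stages, the per-stage mean training error is
monotonically non-increasing across the whole cascade — a property the
test suite asserts for every sweep run. The alternative (normalized-
frame residuals) would generalize better across large scale variation,
which the intended imaging setting does not have; frames of roughly
comparable scale are an assumption of this implementation.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `nu` | shrinkage per tree | 0.2 | interior optimum of the tuning sweep |
| `cascade_depth` (T) | number of stages | 10 | errors plateau near 10 at desk scale |
| `tree_depth` (F) | tree depth, 2^F leaves | 1 | deeper trees overfit before they help |
| `oversampling` (R) | initial shapes per image | 20 | covers initial-misalignment range |
| `trees_per_stage` (K) | boosted trees per stage | 500 | standard capacity for this family |
| `feature_pool_size` | pixel locations per stage | 400 | diminishing returns beyond this |
| `candidate_splits_per_node` | split proposals | 20 | standard practice for the family |
| `feature_locality_lambda` | locality prior scale | 0.1 × image width | favours local contrasts |

Training cost is proportional to the work counters the model records:
T×K trees, n×R examples per stage, 2^F leaves per tree.

## The synthetic generator

No annotated radiograph collection ships with the package, so
`synth_cephalograms()` generates annotation-perfect stand-ins: a fixed
26-point template (constants chosen so all seven angular features are
finite and clinically plausible — ANB ≈ 2°, convexity ≈ 163°), drawn as
smooth splines through anatomically grouped subsets (cranial base,
mandibular border, maxilla, incisor axes, molar cusp marks, soft-tissue
profile, rings at Sella/Porion/Orbitale) over a background intensity
gradient, then Gaussian blur and additive noise.

Each image draws a global similarity placement and a spatially coherent
per-landmark deformation (independent Gaussian offsets smoothed across
the landmark neighbourhood graph with a distance kernel, then rescaled
to the target s.d., so neighbouring landmarks move together as anatomy
does). Defaults: 256 px frame, translation s.d. 15 px per axis, scale
s.d. 5%, rotation s.d. 3°, shape deformation s.d. 3 px, blur 1.2 px,
noise s.d. 8, margin 12 px. The placement numbers encode how much head
framing genuinely varies between acquisitions — around 5–7% of the
frame — which is exactly the variability that makes moderate affine
transforms of training films behave like unseen films. Placements
violating the border margin are redrawn (at most 100 times, then an
error), which truncates the placement distribution slightly at the
frame edges.

What the generator does **not** emulate: radiographic physics (scatter,
beam hardening), overlapping bilateral structures, soft-tissue/bone
texture, rater disagreement, and pathology. Consequently the synthetic
task is easier than real landmarking; results on it demonstrate that
the machinery learns geometry from image evidence, not that a given
pixel accuracy transfers to clinical films. All errors are reported in
pixels; no physical calibration (mm/px) exists for synthetic data.

## Augmentation

All six transforms act jointly on image and annotations. Affine kinds
build a 2×3 matrix about the image centre; the image is warped by
backward mapping with bilinear interpolation and zero fill, while
landmarks go through the matrix exactly, so coordinate mapping carries
no interpolation error (tested against a matrix oracle). Naming fixes
an ambiguity: the *H-shift* moves along the height axis (y), the
*W-shift* along the width axis (x); shear is horizontal (x displaced in
proportion to y) about the centre.

The elastic transform composes a random affine (three control corners
displaced uniformly within ±`alpha_affine`) with a dense displacement
field: per-pixel uniform ±1 noise, Gaussian-smoothed at scale `sigma`,
multiplied by `alpha`. Landmarks are mapped through the forward affine
and then displaced by the field evaluated at their position; the exact
warp inverse is ill-posed, and this approximation's error is of the
order of the field gradient — well under a pixel at the reference
smoothness (sigma 5).

Transformed copies whose landmarks leave the frame are **flagged**,
never clipped: at ±70 px shifts on a 256 px frame content loss is
unavoidable, and the flag lets any consumer decide. The experiment
harnesses keep flagged copies (the coordinates remain exact; off-image
structure simply reads 0), and the novelty tables report flag counts.

## Experiments

* `run_parameter_sweep()` varies one learning parameter at a time
  around a base configuration (matching one-dimensional tuning panels,
  not a factorial design) and records train/test errors plus work
  counters.
* `run_novelty_assessment()` trains once on untransformed images and
  evaluates on transformed copies of both training and test images; the
  elastic condition draws a fresh random realization per image so the
  summary does not hinge on a single affine draw.
* `run_gain_curve()` grows a 50-image base either with unseen originals
  or with randomly transformed copies of the base, over replicate seeds
  (default 3; single runs of the stochastic arms are too noisy to
  compare). "Gain" is the reduction in mean test error relative to the
  baseline model.
* `summarize_directionality()` reports each landmark's circular mean
  error direction and mean resultant length, excluding zero-magnitude
  errors whose direction is undefined.

### Problem sizes and regimes

The packaged analyses run at desk scale: 200 generated images split
150/50, 10 stages, and either 50 trees per stage (accuracy of the
angular features; a 7-second fit) or 500 trees per stage (novelty and
gain experiments). The choice is deliberate: with 50 trees per stage
the model is capacity-limited and its learning curve over training-set
size is flat, so augmentation-gain comparisons are uninformative; at
500 trees per stage the 50-image baseline overfits and both arms of the
gain curve move, which is the regime the gain experiment is about. The
angular-feature accuracy, by contrast, is already comfortable at the
smaller capacity (ANB error s.d. near 1° against a 4° clinical
tolerance), driven by the antagonistic cancellation of SNA and SNB
errors when A- and B-point displacements correlate.

### A note on transform novelty at desk scale

At the 256 px frame, the elastic transform at reference strength is the
most novel condition — its errors exceed every affine condition's, and
its warped films look anatomically implausible — but the separation is
a factor of roughly 1–2, not the order of magnitude one observes on
full-resolution films. The reason is frame-relative magnitude: a fixed
50 px shift is a fifth of a 256 px frame, pushing many landmarks out of
the image entirely, so the shift conditions are themselves drastically
novel; on a film several times larger the same 50 px is well inside the
natural framing variation and the affine conditions stay easy, leaving
the elastic condition alone at the top. The ordering (elastic worst,
rotation/shear next, zoom mildest) is scale-stable and is what the test
suite asserts at the transform level; the ratio itself is resolution-
dependent and should not be quoted without the frame size.

## Numerical choices

* Coordinates are 0-based pixels, origin at the top-left pixel centre,
  x rightward, y downward; all angles are computed in this frame and
  are invariant to it.
* Angles use `atan2(|cross|, dot)`, stable near 0° and 180°; degenerate
  rays (coincident points) raise errors rather than returning 0.
* ANB is reported signed, as SNA − SNB.
* Zero-magnitude landmark errors have undefined direction, reported as
  `NA` and excluded from circular summaries.
* Split thresholds are uniform on ±80 intensity units — wide enough to
  cover contour-versus-background differences after blur, narrow
  enough that most proposals actually split.
* Equal-gain split proposals resolve to the first drawn, making
  training bitwise reproducible; all randomness descends from a single
  integer seed via a fixed derivation, and identical configurations
  reproduce bit-identical datasets, models and predictions.
* Models serialize to versioned JSON at full double precision; readers
  reject unknown versions and truncated files.

## Limitations

* Synthetic films only; see the generator section for what is not
  emulated. Absolute pixel errors do not transfer to clinical films.
* Image-frame residuals assume roughly comparable acquisition scale
  between training and deployment.
* The elastic landmark mapping is a first-order inverse; at extreme
  `alpha/sigma` ratios the approximation degrades.
* Flagged (out-of-frame) landmarks are evaluated like any others;
  errors at such landmarks measure content loss, not model skill.
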