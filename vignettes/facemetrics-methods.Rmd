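---
title: "Automated frontal facial analysis: model, calibration and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated frontal facial analysis: model, calibration and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pre-surgical facial analysis for orthognathic surgery quantifies soft-tissue
proportions — the facial thirds, intercanthal distance, alar base width, lip
lengths, vermilion heights and the interlabial gap — traditionally with a
two-jaw digital caliper on the patient's face. `facemetrics` automates the
frontal part of this analysis from a single photograph: a convolutional
regressor localizes 13 soft-tissue landmarks, a circular fiducial pad of
known 10 mm diameter fixes the millimetre-per-pixel scale, and nine
measurements (M1–M9) are derived as Euclidean distances between landmarks
(or landmark midpoints). A paired-agreement module compares automated
against caliper measurements with per-measurement paired t-tests.

## The landmark model

The regressor follows the "Tweaked" lineage of small landmark CNNs: shared
convolutional stages followed by specialized fully connected heads, one per
landmark. The input is the centred 1024×1024 face crop resized to 40×40 RGB.
Only the stage count (four convolutional layers) and the head structure
(at least two fully connected layers per landmark, emitting an (x, y) pair)
are fixed by the lineage; the remaining hyperparameters are this package's
choices, selected once for CPU-scale training:

* 3×3 kernels with unit zero-padding, channel widths 16, 32, 64, 128;
* tanh activations and 2×2 max-pooling after every stage
  (40 → 20 → 10 → 5 → 2 pixels);
* per-landmark heads 512 → 64 (tanh) → 2 with sigmoid output, so every
  coordinate is normalized to [0, 1] by the crop frame — the loss is
  scale-free mean squared error over the 26 outputs;
* Adam with base learning rate 10⁻³ and default moment parameters, batch
  size fixed at 1 (with this loss normalization larger batches bought
  nothing); the rate decays linearly to 10⁻⁴ over the run — with batch-1
  updates a constant rate leaves the weights diffusing at a noise floor,
  and each run would freeze with its own small systematic landmark
  offsets, visible as seed-dependent measurement biases;
* Glorot-uniform initialization from a private, seeded random stream.

Two epoch presets define the two program versions: version 1 trains 200
epochs, version 2 trains 1000. Training, shuffling and augmentation all
draw from one `std::mt19937` stream, so a run is bit-reproducible from a
single seed on a single thread (BLAS threading is the only external source
of nondeterminism; the package is developed and tested single-threaded).

Augmentation applies, independently at each presentation, exactly one of
two transforms: with probability 0.5 a horizontal inversion — pixels
mirrored, x ← (width − 1) − x for every landmark, and the bilateral index
pairs (4,5), (7,8), (9,10), (11,12) swapped so anatomical left/right labels
remain correct — otherwise a saturation change, scaling HSV saturation by a
factor drawn uniformly from [0.6, 1.4]. The input stays RGB rather than
grayscale precisely because the saturation branch would be a no-op on
grayscale input. The fiducial pad is left in the training images; it is
simply background to the network.

## Scale calibration

The 10 mm silicone pad is detected by intensity thresholding (default:
mean channel ≥ 230 of 255, roughly midway between skin and the white pad
so the anti-aliased edge is cut at its half-intensity contour) inside a
search region defaulting to the upper
third of the frame, connected-component labelling, and a circularity gate
4πA/P² ≥ 0.8. The diameter is the area-equivalent diameter 2√(A/π), which
is robust to anti-aliased edges; the scale is then mm/px = 10/diameter.
Two or more circular candidates of comparable size (second area ≥ 80% of
the largest) raise an ambiguity error rather than guessing. A manifest can
carry a manual mm-per-px override per image for photographs without a
visible pad — the pathway that mirrors measuring the pad by hand in an
image editor.

## The nine measurements

The measurement registry maps each of M1–M9 to two endpoints, each a
landmark index or the midpoint of two indices: M1 (middle third) runs from
the midpoint of the inner eyebrow points — a glabella proxy — to the
subnasale; M2 (lower third) subnasale → menton; M3 inner-eye to inner-eye;
M4 alar tip to alar tip; M5 subnasale → stomion superius; M6 Cupid's-bow
midpoint → stomion superius; M7 stomion inferius → menton; M8 the lower
vermilion height; M9 the interlabial gap. All distances are Euclidean,
matching what a two-jaw caliper measures between two surface points, and
are reported at 0.01 mm (caliper) resolution. The pairing is deliberately
data-driven — a JSON override can substitute alternative endpoint
conventions without touching code — because the endpoint convention is the
one part of the published analysis that is not mechanically fixed by the
landmark schema, and isolating it in one table keeps the assumption
auditable.

## Synthetic faces as study conditions

No public database of consented, marked facial photographs accompanies the
original program, so the package ships a procedural generator that stands
in for it at the same scale: by default 100 subjects per dataset — the
acceptance experiments use 240 (200 train / 40 held out) — emulating
adults with and without dentofacial deformities. Subject anthropometry is
sampled in millimetres around typical adult soft-tissue values (middle
third 62.5 ± 5.0 mm, lower third 67.4 ± 6.2 mm, intercanthal 32.0 ± 2.4 mm,
alar base 33.4 ± 3.5 mm, upper lip 20.6 ± 3.0 mm, upper vermilion
9.3 ± 1.4 mm, lower vermilion 12.0 ± 1.9 mm, interlabial gap 2.2 ± 0.9 mm
truncated at zero so lips may touch), with a configurable deformity
fraction (default 0.25) in which the lower third or lip vermilion is
exaggerated. A per-subject scale is induced by drawing the rendered pad
diameter uniformly from 46–54 px for the 10 mm pad. Faces are schematic:
shaded ellipses for the face outline, brows, eyes, nostrils, lips and chin
crease, each anchored deterministically to its landmarks, plus the uniform
white pad on the forehead and additive Gaussian pixel noise (σ = 4/255).
Bilateral pairs are mirror-symmetric up to a jitter of at most 3 px
(default 1.5). "Conventional" measurements for synthetic subjects are the
noiseless ground truth plus Gaussian caliper noise (σ = 0.3 mm, roughly
the repeatability of a hand-held digital caliper on soft tissue).

What passing on this generator shows — and what it does not: the network
demonstrably learns a consistent appearance-to-landmark mapping end to end
(landmark error on held-out faces well under a tenth of the intercanthal
distance, measurement biases within the tolerances used clinically), and
every non-learning stage is exact. It does not show robustness to real
photographic variation — pose, lighting, occlusion, skin texture — and the
published 20-subject accuracy tables cannot be reproduced without the
private photo database; the package instead reproduces the published
statistical analysis itself from the printed summary statistics.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, origin at the top-left pixel centre, x
  rightward, y downward; annotations are stored at 0.01 px.
* Resampling is bilinear with pixel-centre alignment; landmark coordinates
  rescale by the pure frame ratio (512 in a 1024 frame maps to 20 in a 40
  frame). Crops pad with black and return the applied offset so
  annotations shift losslessly.
* Masks exported from landmark sets carry a sidecar ordering record,
  because a binary mask alone cannot encode landmark identity; recovery
  uses component centroids and is exact to 0.5 px.
* Paired t-tests use the closed form t = d̄/(s_d/√n) with n − 1 degrees of
  freedom, two-sided. A zero-SD series returns p = 1 when the mean
  difference is zero and p = 0 (flagged degenerate) otherwise. Differences
  are oriented reference-minus-automated, the orientation consistent with
  the published tables; no multiple-testing correction is applied, and
  both the 5% and 1% conventions are reported.
* Lips in contact give an interlabial gap of ≈ 0 mm, never negative.

## Problem sizes

The bundled experiments are sized for a desktop CPU: the acceptance
experiment trains version 1 (200 epochs, batch 1) on 200 synthetic faces
and evaluates on 40 held out, about 6–8 minutes of single-core time; the
test suite uses the same conditions once plus much smaller runs (single-
image overfitting, 15-epoch smoke training) for the remaining properties.

## Known limitations

* The generator's schematic appearance is far easier than photographs; the
  reported error rates are a demonstration of the pipeline, not a clinical
  validation.
* Only the frontal at-rest pose is modelled; smile and profile poses, and
  the twelve caliper measurements that need them (incisor and gingival
  exposure, chin–neck line, midline deviations, upper third), are out of
  scope.
* Pad detection assumes one bright circular marker in the search region;
  strongly reflective skin regions could defeat the threshold on real
  photographs, which is why the manual override pathway exists.
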