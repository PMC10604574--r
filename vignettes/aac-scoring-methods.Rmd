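---
title: "Methods: automatic Kauppila scoring of abdominal aortic calcification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic Kauppila scoring of abdominal aortic calcification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacquant)
```

## The measurement problem

Abdominal aortic calcification (AAC) on a lateral lumbar radiograph is
conventionally graded with the Kauppila score: the anterior and posterior
aortic walls adjacent to vertebrae L1–L4 are each scored 0–3 by how much of
the wall's longitudinal extent is calcified (0 none, 1 under one third,
2 from one to two thirds, 3 two thirds or more), for a total of 0–24,
banded as mild (0–4), moderate (5–15) or severe (16–24). Manual scoring is
slow and has known failure modes — for instance a plaque bridging two
vertebral levels may be credited to neither.

`aacquant` implements the automatic chain: given a multi-class mask
(vertebrae, aorta, calcifications — produced by the bundled U-Net or by any
other segmenter), it derives the eight segment scores, the total and the
severity purely geometrically. Because no public radiograph set accompanies
this problem, the package also ships a phantom generator whose ground truth
is known by construction; it is first-class, tested code and the package's
main verification surface.

## Orientation and coordinate conventions

One convention is used everywhere: pixel grids are `[row, col]` matrices
with row 1 at the top; rows increase cranial → caudal (T12 above L5); the
aorta lies anterior to the spine at *smaller* column indices (a left-facing
lateral view). Geometry uses 0-based pixel-center coordinates, and bounding
boxes are half-open.

## The scoring engine

**Vertebral components.** The vertebra class is labelled into 8-connected
components (diagonally touching pixels are one body). If more than six are
present the six largest are kept and the rest dropped with a warning; fewer
than six is an error unless `lenient = TRUE`. The spine axis is the first
principal axis of all vertebra pixels, oriented caudally, and components
are ordered by centroid projection onto it — robust to tilted spines, where
raw row order can fail.

**Level boundaries.** For each adjacent pair the separating line is
perpendicular to the pair's centroid-to-centroid vector, anchored at the
midpoint of the intervertebral gap (midway between the caudal edge of the
upper body and the cranial edge of the lower body, measured along the pair
axis). Anchoring at the gap midpoint rather than at the centroid midpoint
makes the boundary agree with the clinical definition of a level while the
direction still comes from the centroids. Level heights are axial distances
between consecutive boundary anchors.

**Level assignment** counts, for any pixel, how many boundary half-planes
it lies caudal to: 0 means above T12/L1 (unscored), 1–4 are L1–L4, 5 is
below L4/L5 (unscored). Because each pixel is assigned independently, a
plaque bridging a boundary is split by it and contributes to both levels —
deliberately fixing the manual-reading gap noted above.

**Centerline and wall classification.** The aorta (with its embedded
calcification pixels) is treated as one entity; for each axial bin the
centerline is the midpoint of the aorta's perpendicular extent, with axial
gaps filled by linear interpolation. Each 8-connected calcification
component is assigned to the wall on the side of the centerline holding the
majority of its pixels: away from the vertebral column = anterior, toward
it = posterior. An exact 50/50 split goes posterior (a deterministic,
conservative tie rule — posterior calcification is the nearer wall). If a
mask already carries separate anterior/posterior labels,
`trust_wall_labels = TRUE` passes them through.

**Coverage and scores.** Per (level, wall) segment, calcification pixels
project onto the spine axis as pixel-resolution intervals
`[s - 0.5, s + 0.5]`; the merged union length divided by the level height
is the coverage ratio. Using the union, not the sum, means multiple plaques
cannot double-count and the ratio cannot exceed 1 through overlap; ratios
slightly above 1 (plaques overhanging the aorta, rotation quantization) are
clipped with a warning. The ratio-to-score map treats the 1/3 and 2/3
boundaries as closed from below (`[1/3, 2/3) -> 2`, `[2/3, 1] -> 3`): the
strict-inequality wording of the clinical rule leaves the exact boundary
values unassigned, and closed-below bins are deterministic and monotone
while pixel quantization makes exact hits realizable in phantoms. Any
nonzero ratio scores at least 1. A minimum plaque-component size filter
(default 0 px, i.e. exact recovery on clean masks) can be raised for noisy
predicted masks.

## The phantom generator

The phantom emulates exactly the structures the scoring engine consumes: a
vertical column of six separated rectangular vertebral bodies, a
constant-width aortic band strictly anterior to the spine, and 2–3 px thick
calcification strips on the outer (anterior) or inner (posterior) aortic
boundary. Strip thickness is irrelevant to the score, which uses
longitudinal extent only. For a requested coverage fraction `c` the strip
spans `round(c * level_height)` rows, centered within the level and always
inside it; the ground truth is computed from this *realized* coverage, so
whole-pixel rounding can never produce an off-by-one disagreement between
generator and engine. T12 and L5 receive no calcification since the score
is defined for L1–L4 only. Rendering intensities (background 0.1, aorta
0.35, vertebra 0.9, calcification 1.0 before Gaussian noise) are arbitrary
but fixed and configurable; noise is seeded and never touches the mask.

`generate_cohort()` draws per-case coverage so each truth total lands in a
requested severity band: a target total is drawn uniformly within the band,
decomposed into eight per-segment scores, and each score is realized by
sampling an integer pixel extent strictly inside that score's ratio bin —
exact by construction for any level height of at least ~6 px. Band counts
are `floor(n * fraction)` with remainders by largest fractional part; the
80/10/10 split floors the two small sets and gives remainders to training.
The default severity mix (46% mild, 31% moderate, 23% severe) mirrors a
fairly balanced screening population.

What the phantom does *not* emulate: photorealistic radiograph texture,
overlapping bowel gas or contrast material, vertebral fractures or
osteophytes, curved or stenotic aortas, and 3D projection effects. Passing
the phantom suite therefore demonstrates the correctness of the geometry
and scoring logic, not clinical-grade segmentation performance on real
films.

## Preprocessing

The stage-one chain is side crop → isotropic resize with symmetric zero
padding to 517 × 576 → intensity normalization. Two textual ambiguities in
the originating protocol are resolved as explicit design choices, both
config-exposed:

- *Crop/resize order*: sides are cropped **before** resizing (flag
  `crop_after_resize` restores the other order), so the 40%/10% fractions
  refer to the acquired field of view; cropped pixel counts are floored.
- *Normalization*: "zero-mean normalization within 0 to 1" is
  self-contradictory; the implementation centers to zero mean and then
  min-max rescales to `[0, 1]`. The centering changes nothing after min-max
  but mirrors the intended sequence; the operative contract is min 0, max 1.
  Constant images normalize to 0.5 with a warning. The target is read as
  rows = 517, cols = 576.

Augmentation draws uniform scale (0.95–1.05), rotation (±10°) and
translation (≤ 10% of each axis) per call and applies one transform to both
image (bilinear) and mask (nearest-neighbour, so the label set is
preserved). The stage-two crop takes the aorta's bounding box plus a 5 px
margin (clipped at borders), zeroes pixels outside the mask, and returns
the offset needed to map stage-two predictions back.

## The U-Net and its training

The segmentation network is a standard encoder–decoder with skip
connections: double 3×3 convolution + ReLU per scale, 2×2 max-pooling down,
nearest-neighbour upsampling + 3×3 convolution up, 1×1 convolution +
per-pixel softmax head; soft-Dice loss averaged over foreground classes
(`eps = 1e-6`) and Adam. Stage one is a single 3-class model (background /
vertebra / aorta); stage two predicts one generic calcification class by
default, with anterior/posterior assignment left to the geometric engine (a
3-class stage-two variant is supported). It is implemented directly on R
arrays — convolutions as one BLAS matrix product per layer through an
im2col expansion, with hand-written backward passes verified against
numerical differentiation in the test suite. Max-pool gradient ties break
to the first maximum in scan order; inputs not divisible by 16 are padded
internally and the output cropped back, so output shape always equals input
shape.

Two presets exist. `paper` matches the full-resolution protocol: filters
64/128/256/512/1024 down and 512/256/128/64 up, learning rate 1e-4, batch
10, 5 epochs. `tiny` (filters 8–128 on 64 × 64 phantoms) is the default
test and demonstration surface; it uses learning rate 1e-3, chosen because
a small network on small, high-contrast phantoms needs larger steps to move
within a few epochs. Training is fully seeded (shuffling and on-the-fly
augmentation draw from one stream), stops early when the epoch-mean loss
improves by less than 1e-3 for 2 consecutive epochs, and aborts on
non-finite loss. Augmentation is applied on the fly via an
`augment_factor` multiplier rather than materializing augmented files.

The learning check used by the package trains the tiny preset for 5 epochs
on 20 phantom cases (batch 10) and evaluates vertebra Dice on 10 held-out
phantoms; it runs in well under a minute on one CPU and reaches a held-out
vertebra DSC around 0.65 — a sanity bound on the training loop, not a
performance claim.

## Metrics

Dice (`2|A∩B|/(|A|+|B|)`) and volume similarity (`1 − ||A|−|B||/(|A|+|B|)`)
use the convention that two empty masks agree perfectly (value 1, with a
warning) — this matters for per-case calcification metrics when no AAC
exists. The Hausdorff distance is the exact symmetric max-min between
boundary pixel sets (pixels with a 4-neighbour outside the mask), scaled by
pixel spacing into mm; a percentile variant is available but the default is
the exact maximum. Kendall's W uses mid-ranks and the standard tie
correction (`W = 12S / (m²(n³−n) − mΣT)`), returning `NA` with a warning in
the degenerate all-tied case; ordinal AAC scores tie heavily, so the
correction is not optional. Adjusted R² uses one predictor (a simple
regression of one total on the other). Bland–Altman reports the mean
difference, `±1.96 sd` limits of agreement with the sample standard
deviation, and a normal-approximation 95% CI of the bias.

## File formats

Radiographs are read from PNG, TIFF or NIfTI (written as 16-bit TIFF, 8-bit
PNG or float NIfTI) with pixel spacing from a JSON sidecar or the NIfTI
header, defaulting to 0.14 mm — a typical detector pitch for these films.
A sidecar `photometric: "MONOCHROME1"` entry flips intensities at read so
higher always means denser. Masks round-trip losslessly through 8-bit PNG
or NIfTI with the label map in the sidecar. Score tables are plain CSV
(`case_id, L1_ant..L4_post, total, severity`); pipeline configuration is
YAML merged over package defaults, and every pipeline result carries a hash
of its configuration for provenance.

## Problem sizes and determinism

The verification suite uses deliberately desk-scale problems: exact
truth recovery over 200 randomized phantom geometries (full-size,
~300 × 180 px), brute-force coverage cross-checks on 100 phantoms capped at
100 × 100 px, rotation equivariance at ±6–10°, and the 20-case tiny-preset
training run described above. Everything stochastic — phantom noise,
cohort sampling, augmentation, weight initialization, shuffling — flows
from explicit integer seeds, and identical seeds give bit-identical results
on CPU.

## Known limitations

- Wall classification is per connected component; a single plaque wrapping
  around the centerline (anterior and posterior simultaneously) is
  assigned wholly to its majority side.
- Scores are invariant under rigid transforms only up to pixel
  quantization: a coverage ratio within about one pixel of the 1/3 or 2/3
  threshold can change score under rotation.
- The 24-point Kauppila variant (L1–L4, two walls) is the only scoring
  system implemented; density-weighted variants are out of scope.
- DICOM files are not parsed directly; export to PNG/TIFF with a spacing
  sidecar (or NIfTI) first.
- The phantom's realism limits are listed above; segmentation performance
  on clinical radiographs must be established on clinical data.
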