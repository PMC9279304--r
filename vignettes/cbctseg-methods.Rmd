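---
title: "Coarse-to-fine CBCT segmentation and airway morphometry: methods"
author: "cbctseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine CBCT segmentation and airway morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cone-beam CT (CBCT) of the craniomaxillofacial region is routinely used to
assess the pharyngeal airway — its volume (cc), per-slice cross-sectional
area (mm²), and the narrowest point (mm) — quantities that matter in
obstructive sleep apnea work-ups and orthodontic planning. Manual
segmentation of the airway and surrounding anatomy is slow and
operator-dependent. `cbctseg` implements a fully automatic pipeline:
a two-stage (coarse-to-fine) 3D U-Net semantic segmentation of the head
volume into six classes (background, upper skull, mandible, maxillary teeth,
mandibular teeth, airway), the airway morphometry computed from the
resulting masks, and the inter-method reliability statistics (two-way
mixed-model ICC, Mann–Whitney U, Kruskal–Wallis H) used to compare
measurement methods.

# The cascade

**Preprocessing.** Intensities are clipped to a fixed window
$[-1000, 2000]$ (CBCT units are HU-like but uncalibrated) and min–max
normalized to $[0, 1]$. Volumes are resampled to each stage's voxel spacing
by trilinear interpolation, sampling at output voxel centres with edge
clamping; the output grid is `ceiling(shape * spacing / target)` so the
physical extent is always covered.

**Coarse stage.** The whole volume, resampled to 1.0 mm isotropic (2.0 mm in
the desk-scale configuration), passes through a 3D U-Net in a single forward
pass. Its training targets are *soft*: the ground-truth label map is one-hot
encoded to C channels and each channel is trilinearly downsampled to the
coarse grid, giving a per-voxel class distribution. Because trilinear
interpolation is linear and its weights sum to one, the channels still sum
to one at every coarse voxel — an invariant the tests assert to `1e-5`.

**Coarse hints without leakage.** The fine stage receives the coarse
probabilities as extra input channels ("hints"). If the coarse model that
produces a training subject's hint had seen that subject, the fine model
would learn to trust unrealistically good hints. Hints for training subjects
are therefore produced by 3-fold cross-validation — the hint for subject $s$
comes from the fold model whose training set excludes $s$ — while dev/test
and new subjects get hints from the coarse model trained on all training
data (which never saw them). `generate_hints()` re-audits this invariant at
run time and aborts on any violation.

**Fine stage.** At 0.25 mm (1.0 mm desk-scale), training samples random
cubic patches (144³ full-scale, 32³ desk-scale): each epoch draws
`samples_per_volume` patches per volume through a bounded queue
(capacity 180 full-scale) that shuffles emission order. The fine model input
is the intensity channel concatenated with the C hint channels, so
`in_channels = C + 1`, versus 1 for the coarse stage. Targets are hard
labels obtained by nearest-neighbour resampling of the ground truth.

**Architecture.** Both stages use the same 3D U-Net: per level two
3×3×3 convolutions, each followed by instance normalization and ReLU; 2×
max-pooling between encoder levels; nearest-neighbour upsampling plus skip
concatenation in the decoder; a 1×1×1 output convolution to C score maps.
Channel widths double per level from `base_channels`. The full-scale
default is base 32 / depth 4; desk-scale tests use base 8 / depth 3.
Normalization and activation choices are visible in `model_config()`.
Convolutions are implemented as im2col plus BLAS GEMM in C++; all backward
passes are hand-derived and verified against central finite differences in
the test suite (relative error ~1e-10).

**Loss.** The sum of cross-entropy and a soft multiclass Jaccard surrogate:
for class $c$, with predicted probabilities $p$ (softmax) and target
distribution $g$,
$$J_c = \frac{\sum_v p_{vc} g_{vc} + \varepsilon}
             {\sum_v p_{vc} + \sum_v g_{vc} - \sum_v p_{vc} g_{vc} + \varepsilon},
\qquad
L = -\frac1V \sum_v \sum_c g_{vc} \log p_{vc} + \Big(1 - \frac1C \sum_c J_c\Big),$$
with $\varepsilon = 10^{-6}$ and the Jaccard average taken over all classes
including background — the standard soft-IoU surrogate, which counteracts
the extreme class imbalance (teeth are a few hundred voxels in a ~260k-voxel
head). Hard labels are treated as one-hot distributions, so both stages
share one formula; the coarse stage's cross-entropy consumes the soft-target
distributions directly ($-\sum_c g_c \log p_c$).

**Optimization.** Adam (β = 0.9/0.999) with batch size 1 — one whole volume
per step at the coarse stage, one patch per step at the fine stage — under a
one-cycle schedule: linear warmup from `min_lr = 1e-6` to `max_lr = 1e-3`
over the first 5% of steps, then cosine annealing back to `min_lr` at the
last step. The curve between the named endpoints is our choice; the schedule
is tested at its endpoints and for unimodality. Full-scale epochs are 100
(coarse) and 40 (fine); the checkpoint with the lowest recorded dev loss is
kept.

**Augmentation.** Random blur, noise, rotations, scaling, crops, elastic
deformation and anisotropic resampling; the fine stage omits elastic
deformation and anisotropy (they are expensive on large patches). Geometric
transforms are applied identically to image (trilinear) and labels (nearest;
soft targets trilinear + renormalization). All magnitudes live in
`augment_params()`.

**Inference.** The coarse stage runs on the whole (padded) volume; its
softmax probabilities are trilinearly upsampled to the fine grid, clipped
and renormalized, and concatenated with the fine-resampled intensity. The
fine stage runs on overlapping tiles with a minimum overlap of 16 voxels
(stride = patch − 16, the last tile shifted inward to end at the boundary —
coverage of every voxel is asserted by brute force over random shapes).
Tile probabilities (not logits — probabilities keep the per-voxel simplex
closed under averaging) are blended with a separable Hann window floored at
1% of its peak, so patch centres dominate and borders, where patch-based
predictions are least reliable, are down-weighted. Argmax ties break toward
the lowest class index.

# Morphometry

The pharyngeal airway is the airway-class voxel set restricted to an axial
slab `airway_bounds(superior_z, inferior_z)` and reduced to its largest
26-connected component. The bounds are explicit z-levels in mm: on patient
scans the slab is anatomically defined by landmark planes whose automatic
detection is out of scope here, and on predicted masks the bounds also
remove the frayed ends of the segmented air column, which otherwise
dominate the minimum-area search.

* volume (cc) = voxel count × voxel volume / 1000;
* cross-sectional area (mm²) per axial slice = in-plane voxel count × sy·sx
  (so area summed over slices × slice thickness equals the voxel volume
  exactly — asserted in the tests);
* the narrow slice is the slice of minimal nonzero area; the scalar
  "narrowest point" (mm) is the anteroposterior (y) extent of that slice's
  largest 8-connected in-plane component. Clinical tools do not document
  their linear definition; the `measure = "min_extent"` option takes the
  smaller of the two in-plane extents instead.

`export_stl()` writes the 0.5-level isosurface of the binary mask as the
exact voxel-boundary (cuberille) triangulation: every face between an
inside and an outside voxel becomes two consistently oriented triangles.
The mesh is closed by construction, its area equals the voxel surface area
exactly, and its signed volume equals the voxel volume exactly — properties
the tests exploit (cube area 600 mm², sphere mesh volume = voxel volume).
A smoothed marching-cubes surface was deliberately not used: for
morphometry audits an exactly volume-preserving surface is worth more than
a visually smoother one.

# Agreement statistics

`measurement_table()` holds an n-subjects × k-methods matrix of one metric.

* **ICC.** `icc_two_way_mixed()` defaults to ICC(3,1): single-rater
  consistency from the two-way mixed-effects ANOVA,
  $(MS_S - MS_E) / (MS_S + (k-1) MS_E)$. "Two-way mixed model" admits
  several forms; ICC(3,1) is the standard single-measurement consistency
  reading, and ICC(3,k) and ICC(2,1) are available as options and recorded
  in the report. Reliability classes use the conventional thresholds:
  `> 0.90` excellent, `> 0.75` good.
* **Mann–Whitney U** is reported in the min-U convention with midranks.
  The two-sided p-value is exact (full enumeration over group assignments,
  valid under ties) when both groups have ≤ 8 observations, otherwise the
  normal approximation with tie-corrected variance and *no* continuity
  correction — chosen so that for two groups the Kruskal–Wallis
  $H = z^2$ identity holds to 1e-6, which the tests assert. Note the test
  is unpaired; applying it to paired designs (same subjects measured by two
  methods) is conservative about the pairing structure but matches common
  practice in this literature.
* **Kruskal–Wallis H** from midranks with tie correction, referred to
  χ²(g−1).
* `compare_methods()` assembles per-method summaries, pairwise MWU +
  ICC, KW for ≥ 3 methods, and significance flags at α = 0.05.

# The head phantom

`generate_head_phantom()` builds the synthetic study population: a
soft-tissue ellipsoidal head (~40 intensity units), an upper-skull shell and
an anterior mandible arc of bone (~1200), two tooth arcs (~1800), and a
curved vertical airway tube (air, −1000) whose radius tapers smoothly from
`r_end` at both ends to `r_waist` at a configurable waist, plus Gaussian
noise (sd 30). Exterior air is also −1000 — deliberately, because that makes
the airway *not* separable by intensity alone: the network must use spatial
context to distinguish interior from exterior air, which is the core
difficulty of the real task. Labels are painted from the same geometry as
the intensities, so ground truth is exact. Per-subject seeds jitter head
shape, tube curvature and placement, but never the configured radii, so the
waist area π·r_waist² is an analytic target. An optional "epiglottis-like"
soft-tissue flap protrudes into the lumen below the waist and reduces the
measured minimum CSA — a geometric regression test for a known confounder of
automatic airway measurement.

Defaults: 64³ voxels at 1 mm, r_end = 7 mm, r_waist = 4 mm. The waist radius
was chosen from a digitization-error analysis: at 1 mm voxels the voxelized
disc area of a 4 mm circle deviates from π r² by at most ~8.5% over all
sub-voxel centre offsets, keeping ground-truth morphometry within a 10%
band of the analytic value for every seed; at 3 mm the worst case exceeds
13%. The waist's Gaussian axial profile (sd = 12% of tube length) makes the
area gradient near the waist larger than digitization noise, so the narrow
slice localizes to within ~2 slices.

What the phantom does *not* emulate: beam hardening, scatter, motion
artifacts, anatomical variability of real skulls, and soft-palate/epiglottis
anatomy beyond the single flap. Passing the end-to-end test therefore shows
the pipeline's machinery (targets, hints, patch training, tiled fusion,
morphometry) is correct and trainable — not that the shipped defaults reach
clinical accuracy on patient CBCTs.

# Desk-scale study conditions

The end-to-end test and `scripts/acceptance.R` train the full cascade at a
reduced scale chosen once: 12 phantom subjects (90/5/5 split → 10/1/1),
stages at 2.0 / 1.0 mm, U-Net base 8 / depth 3, 32³ patches with overlap 16,
15 coarse + 10 fine epochs, 8 patches per volume per epoch (queue 80), no
augmentation (the phantom population is already randomized; augmentation
correctness is unit-tested separately). Evaluation on the held-out subject
reports the airway Dice and the waist morphometry inside bounds of
waist ± 12 mm. All randomness flows from explicit seeds; two runs with the
same seed produce bit-identical logs.

# Numerical choices and edge cases

* Resampling out-of-range samples clamp to the edge; constant volumes
  resample exactly; label maps always use nearest-neighbour.
* Volumes smaller than the network's divisibility requirement (2^(depth−1))
  or the patch size are padded on the high side with 0 (= air after
  normalization) and background probability 1; predictions are cropped back.
* Soft probabilities are clipped to [0,1] and renormalized after every
  interpolation to absorb float drift (linearity preserves the simplex in
  exact arithmetic).
* Degenerate statistics: zero total variance is an error for ICC; identical
  groups give H = 0, p = 1; empty masks are errors for area/narrowest and
  0 cc for volume.
* The DICOM reader supports explicit-VR little-endian uncompressed 16-bit
  series — the subset needed to ingest CBCT exports — and derives slice
  spacing from slice positions, rejecting inconsistent spacing beyond 0.1%.

# Known limitations

* Landmark-based airway bounds (palatal plane, C2) are not detected
  automatically; bounds are explicit z-levels supplied by the user.
* The narrowest-point linear measure is a convention (AP extent at the
  minimal-area slice); clinical software may define it differently.
* Full-scale training (100/40 epochs at 1.0/0.25 mm) is supported by the
  same code paths but is a multi-hour CPU job; the shipped tests exercise
  the desk scale only.
* No mixed precision, no GPU, no multi-device training; single-threaded
  BLAS is assumed.
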