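---
title: "Three-stage subject-level stroke classification for non-contrast head CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage subject-level stroke classification for non-contrast head CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chronic (non-acute) cerebral infarcts hypoattenuate on non-contrast head
CT: dead tissue drops below roughly 32 HU while normal parenchyma sits
near 30--40 HU.  The diagnostic question addressed here is *subject-level*:
given a whole CT volume, how likely is it that the scan contains an
infarct?  The difficulty is that other structures — most prominently the
CSF-filled ventricles — are also hypodense, so a naive intensity rule
produces abundant false positives, and whole-volume end-to-end classifiers
need far more training data than a typical single-centre archive provides.

`nctstroke` implements a three-stage pipeline that successively shrinks
the voxel set under consideration and turns a segmentation problem into a
classification score a clinician can audit:

1. **Cranial cavity segmentation.** An encoder-decoder network (2D
   slice-wise or fully 3D) segments the skull-enclosed space, removing
   bone, scalp and the patient table.  Because the 3D variant runs on a
   heavily downsampled grid, its upsampled border is blurred; a
   *boundary-refinement* step keeps voxels within a band around the border
   only if their HU value is below 50 HU (infarcts stay safely below this
   bound), while deep-interior voxels are kept unconditionally.
2. **Region proposals.** A slice-wise encoder-decoder trained with a Dice
   loss on lesion-bearing slices marks candidate infarct voxels with
   deliberately high sensitivity.  Connected components smaller than
   0.2 cm^3 are removed.
3. **Border-patch classification.** Each surviving component is scored by
   a dual-pathway, densely connected 3D network applied to 70 random
   positions on the component's border, each seen at two scales
   (3x32x32 voxels, and 3x64x64 downsampled to 3x32x32).  The lesion
   score is the mean of its 70 patch probabilities (bag-of-local-features)
   and the subject score is the maximum over lesions; a subject with no
   surviving proposals scores exactly 0.

Stage 3's negative training class is *mined* from stage 2's false
positives on healthy volumes (hard-negative mining), and the minority
class is oversampled with replacement to exact parity.

# Model and loss details

* Segmenters: three resolution levels (two 2x2 poolings), skip
  connections, ReLU activations, sigmoid single-channel output.  2D
  variants use 5x5 kernels, the 3D variant 3x3x3.  Stage 1 trains with
  unweighted binary cross-entropy; stage 2 with the smoothed Dice loss
  `1 - (2*sum(S*y) + eps) / (sum(S^2 + y^2) + eps)`, `eps = 1e-6`,
  computed per batch sample and averaged, so small and large lesions are
  penalised alike.  The smoothing constant makes the empty-empty case well
  defined.
* Patch classifier: per pathway a 3x3x3 stem convolution, then dense
  blocks (each layer concatenates all previous outputs in its block and
  adds `growth` channels) alternating with transition blocks (1x1x1
  compression convolution + 1x2x2 max-pooling; an extra 1x2x2 pooling
  follows the stem).  Global average pooling, pathway concatenation,
  dropout 0.2, a fully connected layer, and a 2-unit softmax with
  categorical cross-entropy.  Batch normalisation uses momentum 0.99 and
  epsilon 1e-3.
* Training: Adam; glorot-uniform weights, zero biases.  Reference
  learning rates and epochs are carried as config defaults (1e-4/30 for
  2D cavity, 1e-4/320 for 3D cavity, 1e-4/30 for proposals, 1e-5/5 for
  patches).  Weights are checkpointed at the best validation loss
  (segmenters) or validation accuracy (patch classifier).
* All networks are executed by a compact CPU convolution engine inside
  the package (im2col convolutions with hand-written backward passes,
  verified against finite differences in the test suite).

# Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| HU window | 0--80 HU | stroke window; values clipped then divided by 80 |
| `band_px` | 11 px (desk preset: 3) | boundary-refinement band half-width |
| `hu_max` | 50 HU | strict upper bound for in-band voxels |
| `min_cm3` | 0.2 cm^3 | strict lower bound on proposal components |
| `n_per_lesion` | 70 | border positions scored per lesion at inference |
| threshold | 0.3 | subject-score operating point for confusion matrices |
| bootstrap | 1000 reps of 100 | AUC confidence interval |

The 11-pixel band is defined at the native in-plane resolution of
clinical scans (roughly 0.45 mm pixels, i.e. a ~5 mm band).  The desk
phantoms use 2 mm pixels, so the desk preset scales the band to 3 px to
keep the same physical width; the geometric rule itself is unchanged and
is tested at several band widths.

# The synthetic phantom cohort

Real head CT cannot ship with the package, so every stage is exercised on
a parametric phantom designed to reproduce exactly the features each
stage keys on:

* a bright ellipsoid skull shell (700 HU) with slice-varying radii around
  a soft-tissue cavity (parenchyma 35 +/- 5 HU);
* paired near-midline ventricles (8 HU) scaled by an age factor
  (`0.75 + 0.005 * age`) — the hypodense confounder that makes stage 3
  non-trivial;
* hypodense ellipsoidal lesions at 22 HU mean (below the 32 HU infarct
  profile bound; the true intensity distribution of infarcts is not
  prescribed anywhere, so this is a free parameter chosen mid-range),
  radius 8--16 mm, placed fully inside the cavity and off the
  ventricles;
* a patient-table slab (300 HU) outside the head;
* additive Gaussian HU noise followed by a per-scanner Gaussian
  reconstruction kernel (profile A: sigma 0.6 px, sd 5 HU; profile B:
  sigma 1.4 px, sd 7 HU), emulating scanner texture differences for the
  dataset-bias analysis;
* optional in-plane head rotation for the midline-alignment tests.

The default grid is 24x96x96 voxels at 5x2x2 mm — the dominant clinical
slice thickness is 5 mm, and the in-plane resolution is reduced so a
whole cohort trains on one CPU.  Ages are drawn uniformly from 40--90
years and scanners uniformly from the two profiles.  One integer seed
fully determines a cohort.

**What passing tests do and do not show.**  The phantoms are stylized:
lesions are homogeneous ellipsoids, the skull has no base/sinus
structure, there is no beam hardening, no hemorrhage, and intensity
contrasts are cleaner than in real scans.  A high synthetic AUC
demonstrates that the pipeline mechanics (masking, proposal, mining,
aggregation, evaluation) are implemented correctly and can be trained end
to end — not that the method reaches any particular performance on
clinical data.

# Numerical and design choices

* **Midline alignment** (no method is prescribed): grid search over
  [-30, 30] degrees at 0.5 degree steps, maximising the Dice overlap of
  the cavity mask with its left-right mirror; ties break toward the
  smaller absolute angle.  The objective is evaluated on up to 8 central
  slices (the head is z-coherent); the winning rotation is applied once
  to the full volume, bilinear for intensities and nearest-neighbour for
  masks.  Mask-based symmetry was chosen over intensity correlation
  because it is robust to lesion asymmetry and needs no extra model.
* **Boundary refinement band** extends to *both* sides of the border:
  upsampling blur spills both ways, so in-band voxels on either side are
  re-decided by the HU rule.
* **Connectivity** is 26-neighbour in 3D everywhere, so lesions touching
  diagonally across slices count once.
* **Border definition**: lesion voxels with non-zero per-slice Sobel
  magnitude of the binary mask.  This keeps the border inside the lesion,
  so patch centres sit on lesion tissue; for a filled rectangle it equals
  the in-plane adjacency boundary (asserted in tests).
* **70 border positions** are drawn without replacement when the border
  has at least 70 points and with replacement otherwise, so the patch
  count per lesion is always exactly 70.
* **Oversampling** replicates minority-class patches with replacement to
  exact parity, seeded.
* **Bootstrap CI**: resamples of size 100 drawn with replacement;
  nearest-rank 2.5/97.5 percentiles of the 1000 sorted AUCs; single-class
  resamples are redrawn (cap 1000).  AUC itself is the rank statistic
  (ties count one half), checked against a brute-force pairwise oracle
  and against pROC.
* **Stratified test sets** select `min(n_stroke, n_healthy)` subjects of
  each class per stratum (scanner model or age decade), without
  replacement; strata missing a class contribute nothing.
* **Default experiment**: cropping around the cavity ON, pixel-wise
  cavity masking OFF (the reference configuration that performed best);
  both are flags in `pipeline_config()`.
* **Determinism**: a single global seed is fanned out into named
  per-stage sub-seeds (splits, initialisation, shuffling, augmentation,
  sampling, bootstrap).  Repeated single-threaded runs are bit-identical.

# Desk-scale problem sizes

The test suite and `scripts/acceptance.R` train everything from scratch
on one CPU.  The sizes used are the package's chosen study conditions:
100 phantoms (50% stroke; split 50 train / 10 val / 40 test); 3D cavity
input 12x32x32 with filters (4, 8, 16) and 6 epochs at lr 3e-3; proposal
input 64x64 with filters (6, 12, 24) and 6 epochs at lr 3e-3; patch
classifier with stem 4, two dense blocks of two layers (growth 4),
5 epochs at lr 1e-3 on 12 training positions per lesion (inference always
scores 70).  Augmentation is off in the desk presets — phantom cohorts
already vary in geometry, age and scanner texture.  The end-to-end
property required of this configuration is held-out subject-level
AUC >= 0.90 and lesion-level proposal sensitivity >= 0.80, with the full
pipeline at least as good as its any-proposal ablation.

# Known limitations

* The engine is CPU-bound and meant for desk-scale models; reference-scale
  settings (e.g. 512x512 2D cavity input, 320 epochs) are expressible but
  slow.
* DICOM reading is a minimal geometry/intensity reader behind an optional
  dependency; NIfTI is the first-class interchange format.
* The deposited-datapoint recomputation (`deposited_datapoint_stats()`)
  requires the per-subject score file of the original clinical study,
  which is not redistributable with the package; the corresponding
  acceptance check reports failure until that CSV is supplied.
* Phantom realism limits, as discussed above.
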