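---
title: "Automated MTV delineation and classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated MTV delineation and classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metabolic tumor volume (MTV) and total tumor burden (TTB, the union of the
primary tumor and all lymph-node metastases) are prognostic of overall
survival in head-and-neck cancer, but delineating and classifying every
FDG-avid lesion by hand is slow and observer-dependent. Threshold-based
semi-automatic tools work at high lesion-to-background contrast and degrade
exactly where the clinical interest is greatest — lymph-node metastases with
SUV around 3–4, indistinguishable by intensity from physiological uptake in
tonsils, salivary glands, brown fat, or vocal cords. `mtvseg` implements a
fully automated alternative: a residual 3D U-Net with a self-attention
bottleneck that consumes paired PET/CT volumes and emits a 3-class voxel map
(background / primary tumor / LN metastasis), together with the complete
evaluation and survival-analysis machinery needed to judge such a tool.

## Preprocessing

All analysis happens on a common 2.5 mm isotropic grid. Scalar volumes are
resampled trilinearly, label maps by nearest neighbour (preserving label
integrality — the paper-silent interpolation orders are the field's
standard). Volumes are centrally cropped in the transaxial plane to
128 × 128 voxels (32 × 32 cm); smaller inputs are padded symmetrically.
The axial crop that restricts attention to the head-and-neck region is
exposed as an explicit slice range rather than inferred anatomically: an
anatomical detector is a research problem of its own, and phantoms simply
use their full extent. CT is clipped to the soft-tissue window
[−150, 150] HU; both modalities are then min–max normalized **per volume**
to [0, 1]. This makes network inputs contrast-relative: the model sees
relative uptake, never absolute SUV, which aids generalization across
scanners but means a lesion-free volume will have its background noise
stretched over the full range. Targets are one-hot encoded over the three
classes; should primary and LN delineations ever overlap on input, class 1
wins, keeping targets deterministic.

Training samples are 128 × 128 × 32 patches (configurable) slid along the
axial axis with at least 75% overlap — stride
`floor(depth × (1 − overlap))`, i.e. 8 slices at the defaults — with the
final patch aligned flush with the last slice so every slice is covered.
Flush alignment was chosen over zero-padding to avoid border artifacts in
the deepest slices. The dense overlap doubles as an implicit shift
augmentation; no other augmentation is applied.

## Network

The segmentation model is a residual 3D U-Net whose bottleneck is wrapped in
one multi-head self-attention (MHSA) block:

* **Encoder** — one residual block per level (two 3 × 3 × 3 convolutions with
  instance normalization and leaky-ReLU, plus an identity shortcut that is a
  1 × 1 × 1 projection when channel counts change), with strided-convolution
  downsampling. Channel width doubles per level from `base_channels`.
* **Bottleneck** — the `patch / 2^(levels−1)` grid is flattened into tokens;
  a pre-norm MHSA block with a learned positional embedding and residual
  connection mixes information globally. Global context is what lets a local
  texture decide between "primary tumor" and "LN metastasis", which are
  positional as much as textural categories.
* **Decoder** — nearest-neighbour upsampling, concatenation with the skip
  connection, one residual block per level; a final 1 × 1 × 1 convolution and
  voxel-wise softmax produce the class probabilities.

Block composition, normalization type, activation and downsampling are
standard choices; every capacity knob (levels, base channels, heads, patch
shape) is a `network_config()` field, so the desk-scale model used in the
tests (levels = 3, base = 4, 64 × 64 × 16 patches, ~49k parameters) and a
full-scale model differ only in configuration. All forward and backward
passes are implemented in the package itself (the convolution inner loop as
compiled im2col + GEMM), and the hand-written gradients are verified against
finite differences in the test suite at 1e−3 relative tolerance.

## Loss and monitoring metric

Training minimizes Dice + cross-entropy:

* the CE term is the mean voxel-wise negative log-likelihood;
* the Dice term is `1 − mean_c D_c` over the two foreground classes, with
  `D_c = (2 Σ p t + ε) / (Σ p + Σ t + ε)` and ε = 1 in numerator and
  denominator. Background is excluded (lesions are sparse; including
  background would drown the signal) and ε keeps lesion-free patches finite
  and gently penalizes false positives on them.

Validation is monitored with the **soft DSC**,
`2 Σ p t / (Σ p + Σ t + ε)` averaged over foreground classes. Here ε
appears only in the denominator, so a class absent from both maps scores 0
rather than 1 — the metric rewards actual overlap, not absence. It equals
the hard DSC up to the ε term when predictions are binary. Validation soft
DSC is computed per patch and averaged; a per-reconstructed-volume variant
would be costlier and, being a monotone proxy at fixed patching, would
select essentially the same checkpoints.

## Training procedure

Patients are shuffled once and partitioned into 5 equal folds at patient
level (all patches of a patient stay together — leakage control must happen
at the patient, not the patch, level). Each fold trains on 64% of patients,
validates on 16%, tests on 20%. Optimization is Adadelta at canonical
hyperparameters (ρ = 0.9, ε = 1e−6, lr = 1) with gradient accumulation to
the requested batch size, for up to 200 epochs, stopping early when the
validation soft DSC has not strictly improved for `patience = 30` epochs
(ties do not reset the counter; `patience = 0` stops at the first
non-improving epoch). The returned checkpoint is the argmax of validation
soft DSC over epochs. With fixed seeds and single-threaded BLAS, runs are
reproducible.

## Inference

Per-patch probability maps are fused into a volume with Gaussian weights
whose per-axis FWHM equals the patch side length
(σ_d = L_d / (2√(2 ln 2))): predictions are most reliable at the patch
centre, and the weight falls to half at the patch face. The fused value is
the quotient `Σ w_i p_i / Σ w_i`, which makes per-patch weight normalization
irrelevant, preserves the probability simplex, and is exactly the input
wherever a single patch contributes. For model ensembles the fused per-model
maps are averaged voxel-wise before class assignment. Voxels take the argmax
class, with exact ties resolved toward background — the conservative choice
for a diagnostic tool. Finally, connected components (26-connectivity by
default, 6 available) with volume strictly below 0.1 ml are relabeled to
background, mirroring the analysis rule applied to manual and automatic
delineations alike; at 2.5 mm spacing this is the boundary between 6 voxels
(0.094 ml, removed) and 7 voxels (0.109 ml, kept). Predictions stay on the
2.5 mm analysis grid; an inverse resample to the native grid is available
but is not part of any metric.

## Evaluation conventions

* **Cohort vs individual DSC** — the cohort DSC pools intersection and mask
  sizes over all patients before taking the ratio; individual DSCs are
  per-patient. A patient with empty reference *and* empty prediction for a
  target has undefined DSC and is excluded from summaries (rather than
  scored 1), which is also why failures are counted as "non-empty reference
  with DSC = 0". The "50% CI" is the central interquartile interval
  [25th, 75th percentile] of individual DSCs.
* **Voxel classification** — restricted to voxels delineated as lesion by
  both reference and prediction; `TPR_PT = T_PT/(T_PT + F_LN)`,
  `TPR_LN = T_LN/(T_LN + F_PT)`, `ACC = (T_PT + T_LN)/total`.
* **Structure-wise analysis** — lesions are connected components; a
  reference lesion covered **≥ 50%** by the prediction counts as detected,
  a predicted structure covered **> 50%** by the reference as a true
  positive. The asymmetric boundary is kept exactly as the analysis defines
  it. For the combined target the masks are classless (a primary predicted
  as LN still covers the union lesion); both per-class and union matching
  are computed since published combined rows can be read either way.
* **TTB agreement** — after rejecting the `⌈n/100⌉` pairs with the largest
  absolute difference (the top 1%, guarding the fit against gross failures),
  automated TTB is regressed on manual TTB by OLS, reporting R², the
  coefficients, the mean absolute difference, and a 95% prediction band.

## Survival analysis

Patients are split at the median reference TTB (strictly greater = high
risk; boundary ties go low); the same numeric cutoff can be reused on other
cohorts. The univariate Cox proportional-hazards model for the binary group
covariate is implemented directly — Newton–Raphson on the partial
likelihood to |Δβ| < 1e−8 with Breslow tie handling by default and Efron
available — so that its correctness is testable against a one-dimensional
grid-search oracle and against the `survival` package as an independent
cross-check (never as the implementation). If the likelihood is monotone
(complete separation), iteration stops where the score numerically
vanishes. Kaplan–Meier curves use the product-limit estimator per group.
The concordance helper reports the percentage of patients whose high/low
assignment differs between manual- and CNN-derived TTB; any outcome-based
"truth" labelling is an explicit argument, since such a criterion is a
modelling choice, not a property of the data.

## The phantom generator

Synthetic cohorts make every stage testable without clinical data. Each
patient gets one primary tumor (upper-central zone) and 0–4 LN metastases
(lateral/caudal zones), with ellipsoid volumes drawn from log-normal
distributions calibrated so mean/median volumes match the clinical regime
(primary 13.21/8.16 ml, LN 5.45/2.74 ml; a log-normal is fixed by a
mean/median pair). Peak SUVs are uniform over a configurable range
(defaults within the clinical 3–22 span) over a background of 1.5. Lesion
uptake follows a generalized-Gaussian radial profile scaled so that uptake
crosses half of peak-above-background exactly on the ellipsoid surface —
the ground-truth label is that half-maximum isocontour, mirroring the
adaptive-threshold philosophy of the reference delineations without
re-implementing them. Optional necrotic cores suppress central uptake and
are excluded from the label, as a reader delineating metabolically active
volume would do. Every default cohort carries 1–3 physiological confounder
hot spots (labeled background) so specificity is genuinely exercised, and
placements that would overlap lesions of different classes are rejected
(ambiguous truth is an error, not a warning). CT volumes are structural
props: air, a soft-tissue body, a bone column, slightly elevated density in
lesions.

What the phantoms do **not** emulate: PET reconstruction physics (no point
spread, attenuation, or correlated noise texture), anatomical realism, and
reader variability. A green test suite on phantoms therefore demonstrates
that the machinery — preprocessing, optimization, fusion, metrics — is
correct and that the model class can learn the task, not that clinical
performance is reproduced.

## Scaled-down experiments and numerical choices

The self-contained experiments in the test suite and the acceptance script
use 64 × 64 × 16-voxel phantoms (one patch each), a 25-patient cohort split
16/4/5 into train/validation/held-out, a tiny network (levels = 3,
base_channels = 4, 8 heads), 15 epochs with batch size 1, and a
high-contrast lesion regime (peak SUV 10–22, PET noise SD 0.05). These
sizes were chosen once as the smallest configuration on which the full
pipeline trains to a clearly non-trivial result on a single CPU: held-out
union cohort DSC around 0.85–0.9 and every primary detected, versus 0.87 at
clinical scale in the motivating study. Batch size 16 and 200-epoch
training remain the defaults of `train_fold()`.

Other numerics worth knowing:

* internal feature maps are dense double-precision matrices; convolutions
  run as compiled im2col + BLAS GEMM;
* softmax and attention use max-shift stabilization; probabilities are
  clamped at 1e−12 inside the CE logarithm;
* constant volumes min–max normalize to all-zeros rather than dividing by
  zero;
* argmax ties (exactly equal probabilities) go to the lower class index;
* `fuse_patches` refuses volumes with uncovered voxels, and
  `generate_phantom` refuses cross-class lesion overlap.

## Known limitations

* Training at the published scale (698 patients, 9535 patches of
  128 × 128 × 32) is far beyond a single-CPU R process; the package keeps
  the architecture and procedure faithful and the scale configurable.
* The axial head-and-neck crop is a manual parameter.
* PET/CT pairs must be co-registered; no registration is attempted.
* No DICOM input and no SUV computation from raw activity: NIfTI in, NIfTI
  out.
* Hausdorff or surface distances and per-site stratified reporting are out
  of scope.
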