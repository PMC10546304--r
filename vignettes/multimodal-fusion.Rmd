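---
title: "Multi-modality MRI fusion for pancreatic cyst classification: models and methods"
author: "cystfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modality MRI fusion for pancreatic cyst classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serous cystic neoplasms (SCN) of the pancreas are almost always benign;
mucinous cystic neoplasms (MCN) carry a substantial malignant-transformation
risk. The two are frequently confused on imaging, yet the management
decision (surveillance versus resection) hinges on telling them apart. A
routine abdominal MR examination produces several co-registered volumes per
patient — here seven: the T1-weighted contrast phases `T1pre`, `T1a1`,
`T1a2`, `T1v1`, `T1v2`, `T1post` (pre-contrast through delayed) and a
T2-weighted series. The diagnostic signal is spread across them: cyst fluid
is bright on T2 and dark on T1; walls, mural nodules and septations enhance
progressively after gadolinium, most strongly on the delayed phase, and
more strongly in MCN than SCN.

`cystfuse` implements a slice-based deep-network pipeline over these seven
modalities: per-modality convolutional feature extraction, a fusion block,
a two-layer fully-connected classifier, per-modality auxiliary outputs,
and slice-to-patient aggregation, evaluated under stratified patient-level
cross-validation. Because clinical cohorts of this kind are private, the
package ships a seven-modality lesion phantom generator with analytic
ground truth so that every stage is exercised end to end on synthetic data.

## The fusion model

Each modality's 80×80 slice passes through its own convolutional backbone
producing a feature vector $f_m \in \mathbb{R}^D$, $m = 1,\dots,7$. Four
feature-level fusion blocks are provided:

* **SUM**: $\sum_m f_m$ (length $D$),
* **MAX**: elementwise maximum (length $D$),
* **CAT**: concatenation in canonical modality order (length $7D$),
* **DIS** (disentanglement): each $f_m$ is split into an *appearance* part
  $a_m = f_m[1..L_a]$, modality-specific, and a *content* part
  $c_m = f_m[L_a+1..D]$, shared. The fused feature is
  $(a_1 \,\|\, \cdots \,\|\, a_7 \,\|\, \sum_m c_m)$, length
  $7L_a + (D - L_a)$. At $L_a = 0$ DIS is exactly SUM; at $L_a = D$ it is
  exactly CAT — both identities are asserted bit-exactly in the tests.

Image-level (early) fusion, **IMG-F**, is also available: the seven slices
are stacked into a 7-channel image consumed by a single backbone whose
first convolution takes 7 input channels (randomly initialized — 3-channel
pre-trained kernels do not transfer). IMG-F has no per-modality secondary
outputs.

The classifier is two affine layers with a ReLU between and a two-way
softmax; the (SCN, MCN) probabilities sum to one. Secondary heads of the
same architecture (independent weights by default; a shared-weights option
exists) sit behind each modality's feature and serve two purposes:
auxiliary supervision during training and single-modality evaluation.

## Training losses

The total loss is

$$L = \mathrm{CE}(p_{\text{main}}, y) +
\lambda_{\text{aux}} \sum_{m=1}^{7} \mathrm{CE}(p_m, y) +
\lambda_{\text{con}} L_c + \lambda_{\text{app}} L_{\text{app}},$$

with two-class cross-entropy clamped at $10^{-12}$ so it is finite for
degenerate probabilities. The disentanglement constraints are not fixed by
any published formula, so the package defines them (both pluggable):

* **content consistency** — the normalized variance around the
  across-modality mean,
  $L_c = \frac{1}{7(D-L_a)} \sum_m \lVert c_m - \bar c\rVert^2$, zero iff
  all content vectors agree, quadratically homogeneous;
* **appearance separation** — the mean squared pairwise cosine
  $L_{\text{app}} = \binom{7}{2}^{-1} \sum_{m<n} \cos^2(a_m, a_n)$,
  bounded in $[0,1]$, minimized by pairwise-orthogonal appearance vectors,
  with the convention $\cos = 0$ for zero vectors.

Both were chosen for boundedness and closed-form testability; their
gradients (and the full network's) are hand-derived and verified against
central finite differences in the test suite. Default weights are
$(\lambda_{\text{aux}}, \lambda_{\text{con}}, \lambda_{\text{app}}) =
(1.0, 0.1, 0.1)$; the optimizer is Adam at learning rate $10^{-3}$
(config-exposed). Training is fully deterministic given the model and
shuffle seeds. Content fusion uses SUM rather than the mean; a mean
variant is available via `contentMean = TRUE`.

Two backbones are provided. The default `tiny` backbone (two 3×3 conv
blocks with 4×4 max-pooling, global average pooling to a configurable $D$)
operates directly on the 80×80 slice and is what all desk-scale
experiments use. An `alexnet-conv` topology (five conv blocks, slice
resized to 224 and replicated to three channels, GAP to $D=256$) mirrors
the standard truncated-AlexNet feature extractor; loading pre-trained
weights is possible through the weights slot but is never required by any
test, and no pre-training is performed here.

## Preprocessing

The slice-preparation chain is: trilinear resampling to 1 mm isotropic
spacing (output dimension `roundHalfUp(dims * spacing)`; half always
rounds away from zero so grid sizes do not depend on parity), per-modality
intensity windowing onto $[-1, 1]$ via
$v' = 2\,(\mathrm{clip}(v, lo, hi) - lo)/(hi - lo) - 1$, an 80-voxel
lesion-centered crop over the half-open range $[c-40, c+40)$ per axis
padded with $-1$ (the post-normalization minimum, indistinguishable from
dark background), and extraction of $k$ consecutive axial slices centered
on the crop middle, paired across the seven modalities at identical
positions.

Two windowing policies exist. The default is a robust per-volume
percentile window (0.5th/99.5th of nonzero voxels), which adapts to
arbitrary intensity scales. When the raw scale is known — as for the
phantoms — fixed per-modality windows should be passed instead, because
percentile windows deliberately discard the global intensity scale and
with it any class signal carried by absolute enhancement levels. The
planted-signal experiment below does exactly that.

The number of slices per patient is a free parameter (`kSlices`, odd). A
clinical cohort of 69 patients yielding on the order of 1835 slice groups
corresponds to roughly 27 slices per patient, which is the package
default; the desk-scale experiments use 3 to keep runtimes short. Training
augmentation applies one geometric transform per pack — horizontal or
vertical flip, or rotation within ±15° — identically to all seven slices
(preserving their pairing), plus an independent per-modality intensity
jitter (scale 1±0.05, shift ±0.05, re-clipped); each training pack yields
one original plus `nAug` augmented copies (default 3 in `augmentPacks`,
disabled by default in `runExperiment`).

## The phantom generator

`generatePhantom()` builds one lesion geometry per patient from analytic
primitives — unions and differences of ellipsoids (cysts), thin shells
(walls), planes (septations) and small spheres (nodules) — so every
compartment's voxel set is known exactly and stored in the returned truth
object. Class morphology follows the radiological picture:

* **SCN**: a cluster of 2–6 small cysts (semi-axes 4–9 mm) with 1-voxel
  walls and a lobulated union contour; a central scar sphere is present
  with probability 0.30;
* **MCN**: one dominant cyst (semi-axes 12–18 mm) with a thick
  (2–4 voxel), azimuthally uneven wall, 1–3 mural nodules and 1–2
  septations.

Appearance is modality-specific: fluid is 60 (raw units) on the T1 phases
and 300 on T2; wall/nodule/septum intensity is a base level plus an
additive enhancement that ramps linearly over the six contrast phases,
with a steeper ramp for MCN (defaults 40 vs 100 raw units at the delayed
phase; T2 receives no contrast effect). The background is a constant
tissue level plus one smooth low-order bias field per patient (shared
across the seven modalities, like a session-level inhomogeneity) and
Gaussian noise (SD 5). Per-patient voxel spacings are drawn uniformly from
the clinical acquisition ranges (T1 in-plane 0.78–1.04 mm, axial
2.50–2.59 mm; T2 in-plane 0.625–0.88 mm, axial 4.80–8.40 mm), so isotropic
resampling is genuinely exercised. An optional rigid integer translation
per modality (`misalignmentSd`, default off) models imperfect
co-registration; it is the mechanism by which early fusion's sensitivity
to misalignment can be studied.

Two deliberate idealizations matter for interpreting test results. First,
the lesion geometry is rasterized once on the shared voxel grid and reused
by all seven modalities, so the lesion-support mask is identical across
modalities by construction; since T2 carries a much larger nominal axial
spacing, its lesion becomes stretched in z after 1 mm resampling — the
voxel-level pairing invariant was preferred over physical consistency
here. Second, there is no anatomy, no MR physics (no k-space, TE/TR, or
partial-volume modeling) and no class overlap in morphology parameters.
Passing tests therefore demonstrate that the pipeline recovers planted,
well-separated signal; they say nothing about performance on real
patients.

For planted-signal studies the generator can be told to draw both classes
from the same (solitary-cyst) geometry distribution
(`classGeometry = FALSE`), leaving the per-class enhancement vectors as
the only class difference — this is how the acceptance experiment plants
discriminative signal exclusively in the T1post channel.

## Patient-level aggregation and evaluation

A trained model emits per-slice MCN probabilities. Three result-level
fusions are implemented: per-slice majority voting over the seven
secondary outputs ("Average Result"; each modality votes MCN iff
$p_{\text{MCN}} \ge 0.5$, seven voters cannot tie), per-patient majority
voting over slices (vote ties fall back to the mean probability, and a
mean of exactly 0.5 predicts MCN — the clinically conservative choice),
and an RBF-kernel SVM over a 9-dimensional summary of each patient's slice
scores (mean, sd, min, max, median, quartiles, fraction above 0.5,
log(1+n)). The SVM input representation is this package's design — no
published construction exists — with C = 1 and the standard
`gamma = 1/d`-style default; standardization parameters are learned from
training-fold patients only. One practical caveat found during
development: for patients far outside the training score distribution the
RBF decision surface decays to its intercept, so the aggregator is only
as trustworthy as the coverage of its training folds.

Evaluation treats MCN as the positive class: sensitivity is the accuracy
on MCN, specificity the accuracy on SCN. The ROC is a full threshold
sweep whose trapezoid area equals the pairwise Mann–Whitney statistic with
ties counting half; the suite asserts agreement to $10^{-12}$ against a
brute-force pairwise oracle. Cross-validation is stratified at the patient
level: patients are shuffled within class and distributed so per-fold
class counts deviate from proportionality by at most one, surplus going to
the currently smallest folds (a 33 SCN / 36 MCN cohort at $k=4$ always
yields fold sizes 18/17/17/17 with SCN 9/8/8/8 and MCN 9/9/9/9). Metrics
undefined in a fold (an empty class) are reported as missing and excluded
from the mean with a warning, never zero-filled. Reports print both the
standard deviation and the min–max fold range, so either dispersion
convention is recoverable. Cohort "Table 1"-style summaries use Welch's
t-test (age), chi-square with continuity correction (sex) and
Mann–Whitney (size) as flagged package defaults.

## Problem sizes and numerical choices

The desk-scale study conditions used by the acceptance checks are: 40
phantom patients (20/20) with shared geometry and T1post-only enhancement
signal, fixed raw-scale windows, 3 slices per patient, the tiny backbone
with $D=16$, $L_a=4$, 2 folds, 8 epochs of Adam at $10^{-3}$, batch size
8, SVM patient aggregation, three independent seeds. Under these
conditions the T1post secondary output attains the top single-modality
AUC and DIS-fusion patient-level AUC keeps within 0.05 of the best single
modality in at least two of three seeds, and every epoch-end training
loss trace is non-increasing. The scar-frequency check generates 1000
independently seeded SCN phantoms. These sizes are the package's chosen
defaults for a reproducible desk-scale demonstration; scaling any of them
up only costs time.

Other numerical conventions: probabilities at exactly the 0.5 threshold
predict MCN everywhere; resampled dimensions round half away from zero;
max-pooling and MAX-fusion gradients follow the first maximum on ties;
all randomness flows from explicit integer seeds (per-patient and
per-fold seeds are derived deterministically from the master seed), and
repeated runs with identical configuration reproduce every CSV
byte-for-byte.

## Known limitations

The phantoms are geometric idealizations (see above); windows, slice
counts and constraint-loss forms are package choices where no published
values exist; the AlexNet-style backbone is provided untrained; DWI and
the IPMN/SPN cyst subtypes are out of scope; and the radiomics baseline
and human-reader comparisons that contextualize clinical performance are
not part of this package.
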