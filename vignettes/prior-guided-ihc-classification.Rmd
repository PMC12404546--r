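---
title: "Stain-deconvolution priors for IHC patch classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-deconvolution priors for IHC patch classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcprior)
```

## The problem

Semi-quantitative grading of DAB immunohistochemistry asks two questions of
every tissue patch: *how intensely* is the marker stained, and *how much* of
the patch is positive. Pathologists score intensity 0–3 and positive
proportion 0–4 and grade the sum. A plain CNN classifier sees only RGB
pixels and must rediscover this structure from scratch; `ihcprior`
instead injects it as a *prior*: a physically-derived map of where and how
strongly DAB is deposited, computed by colour deconvolution, feeds a second
network branch, while a feature-importance attention module steers the image
branch toward stained regions.

## Optical density and colour deconvolution

Brightfield transmission follows the Lambert–Beer law, so the optical
density $OD_c = -\log_{10}(I_c / I_{0,c})$ in each channel $c \in \{R,G,B\}$
is linear in stain amount. Each dye has a characteristic OD vector measured
from singly-stained slides; stacking the vectors of hematoxylin, eosin and
DAB as rows gives the stain matrix $M$, row-normalized to $\hat{M}$ so unit
concentration means unit OD along the stain direction. With per-pixel column
OD vector $y$ and concentrations $C$, mixing is $y = \hat{M}^\top C$ and
unmixing is $C = D\,y$ with $D = (\hat{M}^\top)^{-1}$.

Numerical conventions fixed here:

* **Incident intensity** $I_0 = 255$ per channel (8-bit white). The
  transform clamps transmitted intensity at 1 grey level, bounding OD by
  $\log_{10} 255 \approx 2.41$ instead of diverging at black pixels.
* **Convention check**: the classical published $\hat{M}$ and $D$ for
  H/E/DAB are built in (`stain_matrix_hed_normalized()`,
  `deconvolution_matrix_hed()`). Inverting the published $\hat{M}$
  reproduces the published $D$ entrywise only to ±0.02, because the printed
  matrices are rounded to two decimals while their source measurements were
  not; the package's tests assert exactly that tolerance and the exact
  inverse property ($D \hat{M}^\top = I$ to 1e-6) on matrices it normalizes
  itself.
* **Two-stain completion**: H-DAB protocols give two stain vectors; the
  third "residual" direction is the unit cross product of the two normalized
  vectors — exactly orthogonal to both, so residual signal never leaks into
  the H or DAB estimates. Its components may be negative; it is a direction,
  not a dye. (Clamping it nonnegative, as is sometimes done for display,
  would not change the H/DAB concentrations but would break orthogonality,
  so it is not done here.)
* **Unmixing noise**: negative concentrations are preserved in the
  `concentration_map` (they are information about model mismatch) and
  clipped to zero only when the DAB channel is normalized into the
  **anomaly map** `clip(c_DAB, 0, saturation_od) / saturation_od`. The
  saturation OD defaults to 1.0, a typical strong-DAB optical density;
  values above it are treated as fully saturated positivity.

## The synthetic patch model

Everything downstream is trained and validated on patches from a
Lambert–Beer forward simulator (`render_patch()`), so the whole pipeline is
testable with no external data. A scene is: $n$ nuclei (disks, radius 5–9 px,
hematoxylin OD 0.4–0.9 each, overlapping by maximum) plus DAB-positive
structures — disks (r 6–12 px) or ribbon random walks — added until a target
area fraction is covered, each carrying a constant DAB OD. Concentrations are
mixed through the *unit-norm* H-DAB stain vectors (the same geometry the
deconvolution inverts, which is what makes exact concentration recovery a
meaningful round-trip contract), converted to transmitted light, optionally
jittered and noised, and quantized to 8 bits.

Controlled realism, and its limits:

* `stain_jitter_sd` (default 0.02 OD) perturbs the raw stain vectors per
  patch before renormalization, emulating staining variability; `noise_sd`
  (default 2 grey levels) adds sensor noise. Under these defaults the mean
  absolute concentration-recovery error stays below 0.05.
* The generator does **not** emulate nuclear texture, chromatin, stromal
  eosin background, focus blur or compression artifacts. Passing the
  desk-scale experiment therefore shows the architecture and training loop
  work and that the prior carries usable signal — it does not certify
  performance on real slides.
* The quantization-free path (`quantize = FALSE`) exists only for the
  algebraic recovery check (max error ≤ 1e-3); 8-bit quantization alone
  contributes ~0.01 OD error at dark pixels, so the exact contract is stated
  on continuous intensities.

**Scoring.** The paper-standard scheme — intensity 0–3 plus proportion 0–4,
sum graded into negative / weak / positive / strong — needs concrete cut
points, which practice leaves to the pathologist. Defaults (all
configurable): intensity lower edges (0, 0.15, 0.4, 0.8) OD; proportion
lower edges (0, 0.01, 0.1, 0.33, 0.66); totals 0, 1–3, 4–5, 6–7 map to the
four classes. Per-class scene ranges sit inside their bins with margin for
the generator's bounded upward area overshoot, so every generated label is
consistent with its recomputed score — a tested invariant. The default
imbalance profile (`default_imbalance_counts()`) mirrors a realistic 4:1
negative-dominated collection; splits are stratified 7:3 with the floor on
the training side (2,437 → 1,705/732).

**Augmentation** is label-preserving by construction: quarter-turn
rotations, crop-and-resize (scale ≥ 0.85), and per-channel gain jitter
bounded at ±5% — a gain of 1.05 shifts OD by $\log_{10} 1.05 \approx 0.021$,
under half the narrowest intensity-bin gap, so a mid-bin patch cannot change
class.

## Perception attention

The image branch's backbone produces a $16 \times 16 \times c$ feature grid
for a $256^2$ patch. The attention module:

1. downsamples the ITU-R 601 grayscale of the input to the feature grid by
   area averaging (block means; anti-aliased by construction),
2. min–max normalizes each feature channel to $[0,1]$ per image (a constant
   channel maps to zeros — the degenerate case must be defined because
   ReLU-dead channels do occur),
3. gates each normalized channel by the grayscale image into a mask stack,
4. scores the stack with the **feature weighting block** (FWB): two 3×3
   convolutions (c→16→16) with ReLU, global average pooling, a linear
   layer to $c$ raw scores, and a sigmoid mapping each importance score
   into $(0,1)$ — importance weights are nonnegative by construction, so
   the CAM can only highlight (never invert) the activity of important
   channels and its orientation toward stained regions is not left to the
   sign symmetry of a free linear output,
5. combines scores with the *raw* feature channels into a class activation
   map $CAM = \mathrm{ReLU}(\sum_c S_c F_c)$, and
6. re-weights the features as $(1 + CAM) \otimes F$, so a zero CAM is
   exactly the identity.

The FWB is trained jointly with the classification loss (no separate
objective). During backpropagation the min–max statistics of step 2 are
treated as constants (a straight-through choice); every other path —
through the $(1+CAM)$ product, the CAM's weighted sum, and the FWB itself —
is exact, verified against finite differences. The CAM doubles as the
visual explanation: `write_cam_png()` exports it bilinearly upsampled and
scaled by its per-image maximum.

## The two-branch classifier

The prior branch runs an independent backbone (1-channel stem) over the
anomaly map. Both branches are globally average-pooled to $c$-vectors,
concatenated, LayerNorm-ed over the concatenated $2c$ axis (the
normalization axis is not dictated by the architecture sketch; normalizing
the full fused vector is the common reading), and mapped by a single linear
layer to class logits. The classifier weights start at zero, so an untrained
model emits uniform class probabilities (cross-entropy exactly $\ln K$)
and training curves begin from a well-defined baseline; hidden linear
layers use the standard uniform $\pm 1/\sqrt{d}$ initialization and
convolutions use He initialization. Cross-entropy loss; SGD with momentum 0.9; weight
decay 1e-4; the learning rate drops 10× entering 50% and 75% of the epochs.

Two backbones satisfy the 16×16 contract:

* `resnet18` — the 18-layer reference residual network, with its last stage
  at stride 1 so a $256^2$ input ends at 16×16 instead of 8×8 (parameter
  count unaffected). Convolutions followed by batch norm are bias-free, as
  in the reference accounting: 11,177,538 parameters (11.18M) with a 2-class
  linear head; the dual-ResNet18 two-branch model with a 1-channel prior
  stem is 22,350,850 (22.35M).
* `small_cnn` — four conv+ReLU stages (5×5 stride-4 stem, then 3×3 at
  strides 2, 2, 1; channels 8/16/32/64, $c = 64$). This is the desk-scale
  default: the synthetic task's signal (DAB intensity and area) is
  low-frequency, so an aggressive stem loses little while training in
  minutes on one CPU core. Widths and stem were fixed from that compute
  argument before any accuracy was measured.

The engine behind both (single-precision gather-based im2col convolutions in
compiled code, batch/layer norm, max pooling, SGD with momentum) lives in
the package; every layer's backward pass is validated by finite-difference
tests.

## The desk-scale experiment

`run_experiment()` is the package's own analogue of an ablation table: per
seed it generates a fresh 400-patch training and 160-patch validation set
(100/40 per class), trains the prior-guided model and a same-budget
no-prior, no-attention baseline on the identical split (30 epochs, lr 1e-3,
batch 32 — the `"desk"` preset; the `"reference"` preset keeps the
full-scale 300-epoch / lr 1e-5 recipe), and reports per-class and macro
precision/recall/F1 with mean ± sd over seeds. The acceptance test asserts,
over seeds 1–3: prior macro-F1 ≥ baseline in at least 2 of 3 seeds, both
means above 0.80, and — as a localization check — that the trained model's
CAM averages higher inside the generator's true DAB mask than outside on at
least 90% of strong-positive validation patches. Model selection is by best
validation macro-F1 (the recipe leaves selection unstated; macro-F1 is the
headline metric, so it is the natural criterion). Macro averages exclude
zero-support classes with a warning; weighted averages are reported
alongside.

Problem sizes throughout (400/160 patches, 30 epochs, 3 seeds, 128-pixel
patches in the generator-only property tests) are the package's desk-scale
study conditions: large enough that both models clear 0.80 macro-F1 and the
prior's contribution is visible, small enough to run on a single CPU core.

## Known limitations

* The synthetic classes are separable by two sufficient statistics (DAB
  intensity and area); the margin between the prior-guided model and the
  baseline is accordingly small. On real slides, where colour variability
  and confounding structure are worse, the paper-scale gap cannot be
  inferred from these tests.
* Stain vectors are fixed published constants; per-slide stain estimation
  (Macenko-style) is out of scope by design.
* The straight-through treatment of min–max statistics makes the attention
  gradient a subgradient approximation; training is stable in practice, but
  the loss is not exactly differentiated through the normalization.
* Training the `resnet18` configuration end-to-end is supported by the same
  engine but is not exercised at scale here; it exists as the
  reference-faithful architecture for parameter accounting, shape contracts
  and inference.
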