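# ihcprior

Stain-deconvolution priors and attention for classifying DAB
immunohistochemistry (IHC) patches — with a Lambert–Beer patch simulator so
the whole method trains, evaluates and verifies itself without any external
dataset.

## Who this is for

Computational-pathology researchers and method developers who want (a) a
clean, tested R implementation of Ruifrok-style colour deconvolution for
DAB quantification, (b) a reference implementation of a prior-guided
two-branch CNN classifier with feature-importance attention, and (c) a
controlled synthetic testbed for both.

## The model

Brightfield staining obeys the Lambert–Beer law: optical density
`OD_c = -log10(I_c / I_0)` is linear in stain concentration. Stacking the
unit-norm OD vectors of the stains as rows of `M̂`, a pixel's OD column
vector `y` mixes as `y = M̂ᵀ C`, and colour deconvolution recovers the
per-stain concentrations as `C = D y` with `D = (M̂ᵀ)⁻¹`. The DAB channel of
`C`, clipped and rescaled, is the single-channel **colour anomaly map** — a
physical image of "where and how strongly the marker stained".

The classifier feeds two branches into one head:

* **image branch** — a CNN backbone (16×16×c feature grid for 256² input)
  whose features are re-weighted by `(1 + CAM)`, where
  `CAM = ReLU(Σ_c S_c F_c)` and the per-channel importance scores `S` come
  from a small feature-weighting block applied to grayscale-gated,
  per-channel-normalized feature masks;
* **prior branch** — an independent backbone over the anomaly map.

Both are global-average-pooled, concatenated, LayerNorm-ed and linearly
mapped to class logits; training is SGD with momentum under cross-entropy.
Patches are graded on the standard semi-quantitative scale (intensity 0–3 +
proportion 0–4 → negative / weak / positive / strong).

## Worked example

```r
library(ihcprior)

# Colour deconvolution: invert the published normalized H/E/DAB OD matrix
deconvolution_matrix(stain_matrix_hed_normalized())
#> <deconvolution_matrix> C = D y, rows:
#>                   R       G       B
#> hematoxylin  1.8780 -0.0659 -0.6019
#> eosin       -1.0077  1.1347 -0.4804
#> dab         -0.5561 -0.1355  1.5736
```

The diagonal (1.88, 1.13, 1.57) matches the classical published
deconvolution matrix to the ±0.02 that its two-decimal rounding permits.

```r
# Render a synthetic patch: 20% DAB coverage at OD 0.9, realistic noise
spec <- scene_spec(dab_area_fraction = 0.2, dab_mean_od = 0.9,
                   stain_jitter_sd = 0.02, noise_sd = 2, seed = 7)
rec <- render_patch(spec)
rec$label
#> [1] "positive"        # intensity 3 + proportion 2 = total 5

# Extract its anomaly map and quantify positivity
am <- anomaly_map_from_image(rec$image)
mean(am$map > 0.1)
#> [1] 0.2              # recovered positive-area fraction

# Parameter accounting and split arithmetic
count_parameters(backbone("resnet18"), head = 2)$millions
#> [1] 11.18
s <- split_dataset(sprintf("p%d", 1:2437), rep("negative", 2437), seed = 1)
c(length(s$train), length(s$val))
#> [1] 1705  732
```

Training and the prior-vs-baseline comparison (about 6 minutes per seed on
one CPU core):

```r
res <- run_experiment(seeds = 1L)   # 400 train / 160 val patches, 30 epochs
res$aggregate
#>      model macro_precision_mean macro_recall_mean macro_f1_mean macro_f1_sd
#> 1    prior            0.9630326           0.96250     0.9624765          NA
#> 2 baseline            0.9574167           0.95625     0.9561884          NA
```

The macro-F1 difference (`res$delta_macro_f1`) is the package's desk-scale
measure of what the colour-deconvolution prior contributes over an
identically-budgeted plain CNN. A command-line front end with verbs
`synth-generate`, `patchify`, `split`, `train`, `eval`, `cam-export` and
`run-experiment` is installed at `inst/scripts/ihcprior-cli.R`.

## Vignette

`vignettes/prior-guided-ihc-classification.Rmd` documents the model and its
assumptions: the deconvolution conventions, the simulator and what it does
and does not emulate, the attention module's degenerate cases and gradient
treatment, the scoring bins, and the desk-scale study conditions.
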