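---
title: "Models and methods: SPEM enhancement, edRVFL classification, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spemRVFL)
```

## Scope

spemRVFL implements a desk-scale pipeline for staged ischemic-stroke
classification on 8-bit brain CT renderings: a composite image-enhancement
model with quantitative quality metrics, an ensemble deep random vector
functional link (edRVFL) classifier trained entirely in closed form,
Dice-scored box-guided segmentation evaluation, and a synthetic phantom
generator that makes every stage testable without clinical data. This
vignette explains the models, the tunable parameters, and the design
decisions taken where the methods admit more than one reasonable reading.

## The enhancement model

`spem_enhance()` composes four classical operators, in order:

1. **Morphological erosion** — a sliding-window minimum over a
   $(2r+1)\times(2r+1)$ square element ($r = 1$ by default), with edge
   replication. It suppresses small bright noise before equalization.
2. **CLAHE** — contrast-limited adaptive histogram equalization on an
   $8\times8$ tile grid with 256 bins. Each tile's histogram is clipped at
   `clip_limit` times the uniform bin height (default 4, the operating
   point used throughout), the excess is redistributed uniformly in a
   single pass, and per-pixel mappings are bilinearly interpolated between
   the four neighbouring tile mappings. A tile with a single intensity
   gets an identity mapping, so constant images pass through unchanged.
3. **LoG edge boosting** — Gaussian smoothing at `log_sigma` (1.5 px)
   followed by the 5-point discrete Laplacian; the signed response is added
   back with weight `edge_weight` (0.3) and the result clipped to
   $[0, 255]$. The method descriptions this model follows leave the fusion
   of the edge map unstated; additive re-injection with a configurable
   weight is the simplest fusion that preserves the input range and
   degrades to the identity at weight 0.
4. **Unsharp masking** —
   $\mathrm{clip}(x + a\,(x - G_\sigma x))$ with $\sigma = 2$ px and gain
   $a = 1$.

All arithmetic is double precision on the 8-bit scale; quantization
(round half away from zero, clip) happens only when an image is written.

Quality is scored by three metrics. The effective measure of enhancement
partitions the image into $K_1 \times K_2$ blocks (the last block in each
dimension absorbs remainder pixels) and averages the per-block log
contrast ratio

$$\mathrm{EME} = \frac{1}{K_1 K_2} \sum_{k,l}
  20 \log_{10}\frac{I^{\max}_{k,l} + \varepsilon}{I^{\min}_{k,l} + \varepsilon},$$

with $\varepsilon = 1$ by default: blocks containing zeros would otherwise
make the ratio undefined, and a positive offset keeps the score finite and
monotone in contrast. The base-10 (decibel) convention is used, which is
the standard form for this metric. MSE is the plain mean squared pixel
difference, and $\mathrm{PSNR} = 10\log_{10}(255^2/\mathrm{MSE})$, with
identical images reported as `Inf`.

## The classifier

`edrvfl()` fits the ensemble deep RVFL: a stack of `n_layers` hidden
layers whose weights are drawn once from $U[-1,1]$ and never trained, with
*direct links* — the standardized input concatenated into every layer's
design matrix — and one closed-form ridge output head per layer:

$$H_1 = \phi(XW_1 + b_1), \qquad
  H_l = \phi([H_{l-1}\,|\,X]\,W_l + b_l), \qquad
  D_l = [H_l \,|\, X \,|\, 1],$$

$$W^{(l)}_{\mathrm{out}} = (D_l^\top D_l + \lambda I)^{-1} D_l^\top Y,$$

where $Y$ is the one-hot label matrix and $\phi$ is tanh by default. The
published account of the architecture prints the activation twice in its
defining equation; a single application is used here, matching the RVFL
literature the architecture builds on, and the activation is configurable
(`tanh`, `relu`, `sigmoid`). The output bias is absorbed as a constant-1
design column, so one symmetric positive-definite solve per layer fits the
whole head; with at most a few hundred design columns there is no need for
an iterative solver.

Defaults follow the reported operating point: 10 enhancement nodes per
layer ("per layer" being our reading of a count the source leaves
ambiguous; it is configurable), 10 layers, and regularization parameter
$C = 100$. Whether $C$ multiplies the penalty or its inverse is also left
open by the source; the default convention is $\lambda = 1/C$ (large $C$ =
weak ridge), dominant in the RVFL literature, with `direct_lambda`
exposed as the alternative. Features are standardized to zero mean and
unit training-split variance — random $U[-1,1]$ weights need bounded
inputs for tanh to stay informative. Prediction averages the per-layer
score matrices (`mean_score`) or takes per-layer argmax vote shares
(`majority_vote`); ties break toward the earliest class in the model's
class order, deterministically. A `bagging_fraction` below 1 fits each
layer's head on its own seeded row subsample, realizing the reading in
which ensemble members see different data segments; the default of 1 keeps
the closed-form fit permutation invariant.

## Features

The clinical-scale pipeline this package mirrors extracts CNN embeddings
(DenseNet121) before classification. Shipping or training such a network
is out of scope; instead the classifier consumes either of two
`feature_extractor`s: `block_stat_extractor()` — per-block mean and
population standard deviation on an $8\times8$ grid plus a 16-bin global
normalized histogram (144 dimensions, deterministic, training-free) — or
`embedding_file_extractor()`, an adapter for externally computed
fixed-length embeddings keyed by sample id, which keeps the original
architecture reachable without bundling weights.

## Segmentation evaluation

`dsc()` is the Dice similarity coefficient $2|A\cap B|/(|A|+|B|)$. Two
empty masks score 1 by default — agreement on the absence of a lesion is
correct absence — with 0 available for strict benchmarking.
`otsu_box_segment()` is the classical reference segmenter standing in for
a promptable foundation model: Otsu's threshold computed from intensities
inside the prompt box only (so skull intensities cannot skew it), the
hypodense side kept (the ischemic appearance), and the largest 4-connected
component retained. `evaluate_segmentation()` scores any segmenter against
ground-truth masks, optionally pairing raw with SPEM-enhanced inputs.

## The phantom generator

`generate_phantom()` draws a brain-CT-like slice: an elliptical skull ring
(intensity 230), parenchyma at 100 with Gaussian noise of SD 8, a dark
ventricle pair (40), and — for stroke stages — a hypodense elliptical
lesion whose additive contrast and boundary blur encode stage
conspicuity: hyper-acute $(-6, \sigma=4)$, acute $(-15, 3)$, sub-acute
$(-25, 2)$, chronic $(-40, 1)$. Lesion semi-axes are drawn from 8–15% of
the image side. The ground-truth mask is the half-peak contour of the
pre-noise lesion field, so truth does not depend on the noise draw; the
bounding box is the mask's tight bound. Lesions are parenchymal: a
placement overlapping the ventricles is resampled at the same radius, and
the radius only shrinks when a lesion cannot geometrically fit inside the
brain (ten attempts, then an error). The default 128-pixel side keeps
test suites fast; 640 mirrors full-size inputs.

What the phantoms emulate is the *relative* difficulty structure of the
staging problem — faint blurred early lesions, well-demarcated chronic
ones — not CT physics: there is no Hounsfield calibration, no beam
hardening, no anatomy beyond one ventricle pair, and the noise is white
Gaussian whereas real reconstruction noise is spatially correlated.
Passing tests on phantoms therefore validate the pipeline's mechanics and
its qualitative orderings, not clinical performance.

## Protocol choices

- **Cross-validation first.** The source protocol reports both a fixed
  70/20/10 split and 25-fold cross-validation; the harness makes CV the
  primary protocol (`cv_folds = 25` by default; tests and the acceptance
  script use 5 folds at their small sample sizes). The positive class of
  each binary task is the stroke stage, so recall reads as stroke
  sensitivity.
- **Augmentation.** `augment()` quadruples a training set (original,
  horizontal flip, a rotation drawn from $[-15^\circ, +15^\circ]$ with
  reflective padding, and an 85–100% area random crop resampled back).
  Enhancement runs after augmentation. The harness defaults to
  `augment_data = FALSE`: at phantom scale augmentation quadruples runtime
  for a modest accuracy change, and every augmented variant travels with
  its source image into the same CV fold to prevent leakage.
- **Reports.** `run_experiment()` writes per-fold and mean metric rows to
  `metrics.csv` and wall-clock times to a separate `timings.csv`; keeping
  time out of the metrics file makes the scientific report bit-reproducible
  under a fixed seed while still reporting cost informationally.
- **Degenerate ratios.** Precision/recall with empty denominators are
  reported as 0 with a `degenerate` flag rather than as errors, so a bad
  fold cannot abort a run. AUC uses the midrank Mann–Whitney form and is
  therefore invariant under monotone score transforms.

## Known limitations, and one negative result

The enhancement benefit reported on clinical data does not reproduce on
these phantoms: with the default block-statistic features, mean
normal-vs-hyper-acute accuracy with full SPEM enhancement falls slightly
below the raw-image baseline (the acceptance script computes both
numbers). The mechanism is visible in stage ablations: erosion alone and
CLAHE alone each help, but the LoG and unsharp stages, applied after
CLAHE has stretched the local intensity scale, amplify the stretched
white noise faster than the faint, heavily blurred hyper-acute signal.
On phantoms whose dynamic range is already full and whose noise is white,
contrast enhancement has little headroom to add information — unlike
window-rendered clinical JPEGs. We keep the composite's published
defaults rather than disabling the sharpening stages, and report the
direction as measured.

Other limitations: the classifier's capacity at 10 nodes per layer is
modest, and near $p \approx n$ the weak default ridge ($\lambda = 0.01$)
is sensitive to sample size; the Otsu reference segmenter assumes a
bimodal in-box histogram and degrades gracefully (empty mask, warning)
when the box is degenerate; JPEG inputs are accepted but all writes are
PNG, since lossy recompression would break metric reproducibility.
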