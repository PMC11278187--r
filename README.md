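# spemRVFL

Staged ischemic-stroke analysis for 8-bit brain CT renderings, at desk
scale. Ischemic lesions appear on CT as *hypodense* (darker) parenchyma
whose conspicuity grows with stage — hyper-acute changes are faint and
blurry, chronic infarcts deep and well demarcated — which makes the early
stages both the clinically urgent ones and the hardest to classify. The
package implements the full analysis loop for this problem so that every
stage is testable without clinical data:

- **SPEM enhancement** (`spem_enhance()`): morphological erosion → CLAHE
  (clip limit 4, 8×8 tiles) → Laplacian-of-Gaussian edge boosting →
  unsharp masking, with the EME, MSE and PSNR quality metrics:

  EME = (1/K₁K₂) Σ 20·log₁₀((Iᵐᵃˣ+ε)/(Iᵐⁱⁿ+ε)),  PSNR = 10·log₁₀(255²/MSE).

- **edRVFL classification** (`edrvfl()`): an ensemble deep random vector
  functional link network — stacked hidden layers with frozen U[−1,1]
  weights, direct input links at every depth, and one closed-form ridge
  head per layer, W = (DᵀD + λI)⁻¹DᵀY, aggregated by mean score. No
  iterative training; fits are deterministic given a seed. Defaults: 10
  enhancement nodes, 10 layers, C = 100 (λ = 1/C), tanh.
- **Box-guided segmentation scoring** (`dsc()`, `otsu_box_segment()`,
  `evaluate_segmentation()`): Dice overlap DSC = 2|A∩B|/(|A|+|B|) against
  ground-truth masks, with a classical in-box Otsu reference segmenter
  standing in for promptable foundation models.
- **Synthetic phantoms** (`generate_phantom()`, `generate_dataset()`):
  seeded brain-CT-like slices — skull ring, noisy parenchyma, ventricles,
  and stage-dependent hypodense lesions with masks and boxes — emitting
  exactly the PNG + CSV-manifest formats the rest of the package consumes.
- **Experiment harness** (`run_experiment()`): binary normal-vs-stage
  tasks, stratified k-fold cross-validation, optional 4× augmentation and
  raw-vs-enhanced paired comparisons, reporting accuracy, precision,
  recall, F1 and rank-sum AUC.

## Worked example

```r
library(spemRVFL)

dir <- file.path(tempdir(), "demo")
man <- generate_dataset(20, phantom_config(), seed = 1, out_dir = dir)
res <- run_experiment(man, "chronic", cv_folds = 5, seed = 1,
                      out_dir = file.path(dir, "report"))
subset(res$metrics, is.na(fold))
#>                   task fold accuracy precision recall        f1  auc
#>  normal_vs_chronic_raw   NA      0.9         1    0.8 0.8761905 0.95
```

Twenty phantoms per stage is a deliberately tiny run; the mean row says
the chronic-vs-normal task is solved at 90% accuracy with perfect
precision (every "chronic" call was a chronic phantom) and recall 0.8
(one in five chronic lesions missed at this sample size). Enhancement and
segmentation of a single phantom:

```r
ph  <- generate_phantom("chronic", seed = 3)
enh <- spem_enhance(ph$image)
enh$report
#> $eme_before 13.5   $eme_after 34.1   $mse 2667   $psnr 13.9
dsc(otsu_box_segment(ph$image, ph$box), ph$mask)
#> [1] 0.959
```

EME rises from 13.5 to 34.1 dB — the enhanced slice has far more local
contrast — while the PSNR of 13.9 dB against the input quantifies how far
the enhancement moved the image. The Otsu reference segmenter, prompted
with the ground-truth box, recovers the chronic lesion at Dice 0.96.

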