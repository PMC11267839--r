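# sproutscan

Image-based, non-destructive monitoring of seed germination. Germination
tests traditionally require manual counting of sprouted seeds, which is slow,
subjective and error-prone. `sproutscan` implements the computational stack
for an automated alternative: seeds germinating in a multi-cell culture dish
are photographed every 15 minutes for 48 hours, a lightweight two-class
object detector ("sprout" / "not sprout") counts germinated seeds in every
frame, and the counts are turned into the standard seed-vitality indices over
a salinity-by-nanoparticle treatment design (NaCl 0–120 mmol/L crossed with
ZnO nanoparticles 0–800 mg/L).

The package provides, as testable R components:

* **Architecture blocks and variant assembly** — a declarative layer
  description (`layer_spec`) plus a numeric forward engine for the six-step
  ablation ladder of a lightweight anchor-free detector: the YOLOv8n baseline
  and its successive substitutions (PP-LCNet depthwise-separable backbone,
  CCFM cross-scale fusion neck, re-parameterized OREPA fusion blocks,
  FocalModulation in place of SPPF, and the LADH asymmetric dual head).
* **Complexity accounting** — exact parameter counts
  (`Params = C_in/g · K² · C_out` per convolution, plus bias and batch-norm
  affine terms) and FLOP accounting
  (`FLOPs = 2·H·W·(C_in K²/g + [bias])·C_out`, one multiply–accumulate = 2
  FLOPs), reported at table precision (millions to 2 decimals, GFLOPs to 1
  decimal), plus half-precision checkpoint serialization.
* **Online re-parameterization (OREPA)** — multi-branch affine blocks
  (3×3, 1×1, 1×1→3×3, average-pool prior, per-branch channel scaling) with an
  exact squeeze into a single 3×3 convolution + bias.
* **Post-processing** — box decoding for the distributional regression head,
  IoU, hard NMS, and Gaussian soft-NMS (`exp(−IoU²/σ)` decay, σ = 0.5,
  pruning threshold 0.01).
* **Detection metrics** — greedy one-to-one matching, precision, recall,
  all-point-interpolated average precision and mAP50.
* **Dataset construction** — PASCAL VOC XML reading/writing (LabelImg
  dialect), the 12-hour temporal filter, dish-stratified train/test/val
  splitting (whole dishes per split, or a 6:2:2 ratio mode) and the
  six-method photometric augmentation policy (Add, Multiply, GaussianBlur,
  CoarsePepper, GammaContrast, GaussianNoise).
* **Germination vitality** — germination rate `N_t/N × 100%`, germination
  energy (fraction germinated by the 32 h cutoff) and germination index
  `Σ G_t/D_t`, with replicate aggregation over the 5 × 5 treatment grid.
* **Synthetic data** — a deterministic generator of dish-cell image
  sequences (seeds as dark ellipses growing white radicles on filter-paper
  texture) with per-seed germination schedules following a log-normal ×
  hormesis dose–response family, plus VOC ground truth, so every component
  is testable without any external imagery.

## Worked example

Assemble the final lightweight variant and measure its complexity:

```r
library(sproutscan)
v <- assemble_variant("YOLOv8-R")
complexity_report(v, 640, precision = "fp16")
#> complexity report (input 640x640, fp16)
#>   params : 849,968  (0.85 M)
#>   flops  : 2,999,176,864  (3.0 G)
#>   weights: 1.6 MB (fp16)
```

0.85 M parameters and 3.0 GFLOPs are the deployed budget of the final
variant — about 3.5× smaller and 2.7× cheaper than the 3.01 M / 8.1 G
baseline (`assemble_variant("YOLOv8n")`), which is what makes it suitable
for embedded deployment next to the incubator.

Run the end-to-end pipeline on a synthetic run (here with ground-truth boxes
fed back as an oracle detector, which must score perfectly and recover the
generator's schedule exactly):

```r
cfg <- scene_config(cells = 3, seeds_per_cell = 6, image_size = 192,
                    interval_h = 2, seed = 7)
rep <- run_pipeline(cfg, treatment = "BT2", oracle = TRUE)
rep$evaluation
#> detection evaluation (IoU 0.5)
#>   AP[sprout] = 1.0000  (n_gt = 136)
#>   AP[not_sprout] = 1.0000  (n_gt = 296)
#>   mAP50 = 1.0000
#>   P = 1.0000, R = 1.0000 at confidence 1.000
rep$vitality$summary
#>   treatment final_rate energy    index
#> 1       BT2   83.33333  61.11  0.52504
```

`BT2` is 400 mg/L ZnO under 60 mmol/L NaCl: of the 18 synthetic seeds, 83%
have germinated by 48 h, 61% within the first 32 h (the germination energy),
and the germination index weights the early germinations more heavily.

Soft-NMS keeps, rather than deletes, overlapping boxes — a fully overlapping
box decays from 0.8 to `0.8·e^(−1/0.5·1²)` ≈ 0.108 and survives the 0.01
pruning threshold:

```r
d <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                c("sprout", "sprout"), c(0.9, 0.8))
soft_nms(d, sigma = 0.5, score_threshold = 0.01)
#>   x1 y1 x2 y2  label confidence
#> 1  0  0 10 10 sprout  0.9000000
#> 2  0  0 10 10 sprout  0.1082682
```

A thin command-line wrapper over these functions is installed at
`inst/cli/sproutscan.R` with subcommands `generate`, `build-dataset`,
`complexity`, `train`, `detect`, `evaluate`, `analyze` and `pipeline`.

## Scope

The detector variants here are assembled and verified against their
published complexity budgets and exercised with smoke-scale CPU training on
synthetic imagery. Reproducing published *accuracy* figures of a trained
detector would require the original (unpublished) dish imagery and GPU-scale
training, which is outside this package's scope; the synthetic-data
pipeline reproduces the computation, not those values. See the methods
vignette (`vignettes/sproutscan-methods.Rmd`) for the model description,
calibration choices and limitations.
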