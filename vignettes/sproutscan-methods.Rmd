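---
title: "Models and methods behind sproutscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sproutscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutscan)
```

## The problem

A germination test asks how many seeds of a batch germinate, how fast, and
how uniformly. Done by eye this is slow and subjective; done by camera it
becomes an object-detection problem: a 16-cell culture dish is photographed
cell by cell every 15 minutes for 48 hours, each seed in each frame is
classified as *sprout* (a white radicle has broken through the coat) or
*not sprout*, and the per-frame counts are converted into vitality indices.
The scientific use case here is a dose–response experiment: salt stress
(NaCl at 0/30/60/90/120 mmol/L) crossed with zinc-oxide nanoparticle
treatment (ZnO NPs at 0/200/400/600/800 mg/L), 25 treatments, each in 4
cells with 3 repetitions.

`sproutscan` implements that stack in four layers: a family of lightweight
detector architectures with exact complexity accounting, detection
post-processing and evaluation, dataset construction, and the vitality
analysis — plus a synthetic-data generator that stands in for the imaging
hardware so every layer is testable end to end.

## The detector ladder

The detector family is an ablation ladder of six variants. The baseline is
YOLOv8n (depth multiple 0.33, width multiple 0.25, two classes): a CSP-style
backbone of `C2f` blocks with SPPF pooling, a PAN neck, and a decoupled
anchor-free head whose box branch predicts, for each of the four box sides,
a categorical distribution over 16 distance bins (the expectation of which,
times the scale stride, is the decoded distance). Each subsequent variant
substitutes one component, cumulatively:

1. **P-** — the backbone becomes PP-LCNet: a stride-2 stem followed by
   stages of `DepthSepConv` blocks (depthwise 3×3/5×5 + BN + h-swish, then
   pointwise 1×1 + BN + h-swish, no skip connection), squeeze-and-excitation
   (ratio 4, ReLU/hard-sigmoid gates) in the late stage. The neck's two
   downsampling convolutions also become DepthSepConv blocks, which by
   itself removes 0.16 M parameters and 0.2 GFLOPs.
2. **PC-** — the neck becomes CCFM: 1×1 laterals projecting the three taps
   to one uniform width, a top-down path (nearest-neighbour upsample +
   fusion) and a bottom-up path (stride-2 DepthSepConv + fusion).
3. **PCO-** — the neck's C2f fusion blocks are replaced by OREPA-style
   re-parameterized convolutions, counted in deployed (squeezed) form.
4. **PCOF-** — SPPF is replaced by FocalModulation: a query projection, a
   stack of depthwise convolutions of growing kernel (3/5/7) forming
   hierarchical context plus a global-average level, gates that aggregate
   the levels into a modulator, and an output projection of
   query × modulator. The block preserves shape and channels, so it is a
   drop-in SPPF replacement.
5. **YOLOv8-R** — the head becomes LADH: per scale, a shallow
   classification branch (one depthwise 3×3 stage) and a deeper regression
   branch (two depthwise stages), built from depthwise convolutions with
   1×1 projections, with per-scale hidden widths (the "asymmetric
   compression"); the 16-bin distributional box encoding is retained.

Every variant exposes detection maps at strides 8/16/32 (80², 40², 20² for a
640² input) with `num_classes + 4·16` channels per location.

### Complexity accounting

Parameters are exact weight enumeration: a convolution holds
`(C_in/groups)·K²·C_out` kernel weights, `C_out` bias terms when a bias
exists, and `2·C_out` batch-norm affine terms; running statistics are not
parameters; a composite is the sum over its children; a squeezed OREPA block
counts as one 3×3 convolution + bias (deployment is what a complexity table
describes). The test suite checks that this declarative count equals the
enumerated weight count of the instantiated model, exactly, for all six
variants.

The headline FLOP figure counts one multiply–accumulate as 2 FLOPs over
convolution/linear layers — `2·H·W·(C_in K²/g + [bias])·C_out` per layer —
and excludes elementwise work (BN, activations, pooling, upsampling), which
is tallied in a separate column of the per-layer table. This matches how
deployed-detector budgets are conventionally printed (BN is folded away at
deployment); counting elementwise ops would shift the baseline by roughly
+0.2 G and no published budget table would be reproducible under that
convention. Weight size assumes 2 bytes per value (half precision); the
checkpoint writer serializes kernels, biases, batch-norm parameters and
running statistics with small per-tensor headers, which is why a 0.85 M
model yields a ≈1.65 MB file rather than exactly 1.70 MB.

### Calibration of the internal schedule

The printed complexity ladder (3.01/1.69/0.75/0.94/0.93/0.85 M parameters;
8.1/5.0/3.6/3.2/3.2/3.0 GFLOPs) pins down each variant's budget but not its
full internal channel schedule. The baseline needs no calibration: the
public YOLOv8n definition at two classes reproduces 3.01 M / 8.1 G as is
(we validated the constructor against the public 80-class reference count,
3,157,200, before switching to two classes). For the lightweight variants
the budgets are the binding constraint and the internal schedule is
calibrated to them once, then frozen in `variant_config()`:

* PP-LCNet width multiplier 0.25 (taps at 32/64/128 channels), with extra
  stride-1 repeats per stage of (3, 1, 4, 1) and SE only in the stride-32
  extras — backbone budget of P-.
* CCFM uniform width 48; C2f fusion hidden widths (42, 36, 42, 12) with
  (1, 2, 3, 1) bottlenecks per site — PC-.
* OREPA fusion chains per site: 96→4→48, 96→48, 96→16→48 and 96→272→48
  (heavier at the coarse scale, lighter at the fine scales, which is what
  simultaneously raises parameters and lowers FLOPs relative to C2f
  fusion, as the ladder requires) — PCO-.
* FocalModulation inner width 54 — PCOF-.
* LADH classification width 64 and per-scale regression widths
  (268, 192, 212) — YOLOv8-R.

Odd-looking widths are the price of hitting printed two-decimal budgets
exactly; they are configuration, not magic numbers in code.

### OREPA squeezing

Every OREPA branch is affine: 3×3 conv, 1×1 conv (embedded at the 3×3
centre), 1×1→3×3 (merged by kernel composition
`W[u,v,i,o] = Σ_m W₁[i,m]·W₃[u,v,m,o]`), and an average-pool prior (1×1
projection composed with the fixed uniform 1/9 kernel), each followed by
batch norm and a per-branch channel scaling. Batch norm folds as
`w·γ/σ, b = β − μγ/σ` and requires frozen statistics — squeezing an
unfrozen block is refused. One subtlety: in the average-pool branch the
batch norm sits *after* the pool (implemented as a per-channel affine). If
it sat before the pool, its bias would be attenuated at zero-padded borders
and no single convolution could reproduce the block; placed after, the
squeeze is exact everywhere, and the test suite demands agreement within
1e-5 maximum absolute difference over 100 random inputs per block
configuration (observed: ~1e-14).

## Post-processing and evaluation

Decoding applies a sigmoid to class logits, takes the softmax expectation of
each 16-bin side distribution times the stride, and anchors the box at the
cell centre. Soft-NMS then decays, per class, every box overlapping the
current maximum by `exp(−IoU²/σ)` with σ = 0.5 and prunes below 0.01 —
sprout and not-sprout boxes never suppress each other since they are
mutually exclusive states of distinct objects. As σ→0 this reduces to hard
suppression, which the tests check against a hard-NMS oracle. The default
pre-NMS confidence threshold is 0.25; the 0.01 threshold applies to
post-decay pruning. Soft-NMS is also used at evaluation time by default,
exposed as a flag.

Evaluation uses greedy confidence-ordered one-to-one matching at IoU ≥ 0.5
(highest-IoU unmatched ground truth of the same class; ties broken by
ground-truth index, so evaluation is deterministic), and AP is the area
under the monotone precision envelope over all points — the modern
convention, not 11-point interpolation. Published tables print a single
P/R pair without stating an operating threshold; we report P/R at the
confidence maximising F1 and record that confidence. With zero detections
precision is reported as 1 (no false positives were made); with zero ground
truth recall is 1.

## Dataset construction

VOC XML uses the LabelImg dialect: 1-based inclusive corners on disk,
converted to 0-based half-open in memory (width = x2 − x1). Unknown labels
are rejected by name. The first 12 hours of frames are dropped (germination
is not yet visible, 768 of 3072 frames under the default design). The
augmentation policy draws one of six photometric methods per original image
under a fixed seed — parameter ranges: Add ±25 intensity, Multiply
×[0.8, 1.2], GaussianBlur σ∈[0.5, 1.5], CoarsePepper 2% at 3% patch size,
GammaContrast γ∈[0.7, 1.5], GaussianNoise σ = 10/255, conventional mild
settings — one augmented copy per original, because only a doubling
(2304→4608) is consistent with the design's printed totals. Photometric
transforms leave box geometry untouched by construction.

Splitting offers two modes because the two published descriptions are
arithmetically different partitions: assigning whole dishes 1–12/13–14/15–16
gives 75/12.5/12.5% of images, whereas the printed per-split image counts
(2764/922/922 of 4608) are 6:2:2. `dish_stratified_split()` implements both
— dish mode (default; no dish ever appears in two splits) and a ratio mode
that systematically samples along (dish, time) order to hit 6:2:2 counts
while keeping class mixtures similar. Neither is asserted to be the one the
original analysts ran.

## Vitality indices

With `N` seeds per cell and `N_t` the cumulative count germinated by
culture time `t`:

* germination rate `= N_t/N × 100%`;
* germination energy (potential) `= N_32/N × 100%`, the fraction
  germinated by the 32 h cutoff, taken at the last observation at or before
  32 h. The cutoff is fixed at 32 h (the phrase "before the peak of
  germination" admits a peak-relative reading; the fixed cutoff is the
  reproducible one and is exposed as a parameter);
* germination index `= Σ_t G_t/D_t`, with `G_t` the count newly germinated
  in the interval ending at `D_t`. `D_t` is measured in hours since sowing
  at 0.25 h resolution — the printed indices of the original study cannot
  disambiguate hours from days without the raw counts, so the finer unit is
  used and documented. The index strictly rewards earlier germination:
  shifting any germination event earlier never decreases it (a property the
  tests enforce on enumerated schedules).

Detector counts bridge to these indices via `counts_from_detections()`:
`N` = all boxes, germinated = sprout boxes, with a running maximum over
time because detection counts can dip transiently; zero-box frames are
flagged and excluded. Replicates aggregate in 3.75 h windows (15 capture
intervals) as mean ± sd of the rate, with per-treatment energy and index
means over replicates; unequal replicate totals trigger a weighted pooled
rate.

## The synthetic generator

The generator emulates the collection system: per run, 16 cells × 192
timepoints (one frame per cell every 0.25 h for 48 h → 3072 frames), 20
seeds per cell placed with a minimum centre separation and fully inside the
frame. Frames are 640² by default; seeds render as dark ellipses on a
low-amplitude filter-paper texture, and a germinated seed grows a bright
curved radicle whose bounding box joins the seed's. The per-seed label
flips from not-sprout to sprout exactly once.

Germination schedules follow the simplest family that can express the
study's qualitative findings — log-normal times with a hormesis (biphasic)
dose modulation:

* germination probability `plogis(logit(0.975) − 4.28·s·(1 − π))`, where
  `s = NaCl/120` and `π(zno) = 0.5·(z/400)·exp(1 − z/400)` is the
  stress-relief factor (maximal 0.5 at 400 mg/L). The baseline 0.975 makes
  an unstressed cell of 120 seeds germinate ~97.5% by 48 h; the slope 4.28
  brings full salt stress without ZnO down to ~35%, matching the order of
  magnitude of strong-salt inhibition;
* log-median time `log 20 h + 0.5·s − 0.3·π + 0.3·(z/800)²` with log-sd
  0.25: salt delays germination, moderate ZnO accelerates it, high ZnO
  delays it again. The speed optimum lands at 200 mg/L without salt —
  consistent with the index peaking at the low dose in unstressed
  cultivation — while the germinated-fraction optimum is at 400 mg/L.

These defaults were chosen once, from the study's qualitative conclusions
(monotone NaCl inhibition; promotion at low ZnO dose, inhibition at high
dose), and are not fitted to any printed percentage. Consequently the
pipeline reproduces the *computation* and the qualitative dose–response
shapes, not the study's numeric percentages — those depend on the original
seeds and imagery. The generator also does not attempt photorealism
(no specular water film, no seed-coat texture, no radicle
curvature/length phenotypes) and renders single cells, not whole dishes; a
detector trained on it says nothing about real-dish accuracy. What passing
tests *do* establish: the geometry/label contract of the ground truth, the
exact identity between generator schedules and the vitality pipeline when
detections are perfect, and the determinism of the whole path under a seed.

## Smoke training

Full detector training is a GPU-scale task out of scope on a desk CPU.
The smoke harness freezes the randomly initialised backbone and neck as a
feature extractor and fits only the final 1×1 output projections of the
classification and box-distribution branches — binary cross-entropy on the
per-cell class raster plus cross-entropy of the binned box distances at
positive cells. That objective is convex in the fitted weights, so the loss
decreases monotonically for a modest step size, which is exactly what the
harness asserts; features are computed once and cached, so epochs are cheap.
The default smoke problem is 50 frames at 160² for 5 epochs — large enough
that the target rasteriser, the branch plumbing and the gradient math are
all exercised, small enough to run in about a minute. The full-scale recipe
(100 epochs, batch 16, 640², Adam, lr 1e-4, weight decay 1e-4, momentum
0.937, 8 workers) is recorded in `run_config()` and any smoke-scale
override is logged.

## Numerical choices and degenerate inputs

* OREPA squeeze tolerance 1e-5 max-abs (observed ~1e-14 in double
  precision); squeezing refuses unfrozen batch-norm statistics.
* Weight initialisation is He-normal by fan-in; batch norm initialises to
  identity except in re-parameterization tests, where non-trivial frozen
  statistics are drawn deliberately.
* Degenerate boxes (area ≤ 0) are errors, not silently dropped; empty
  detection sets flow through NMS and evaluation as empty, not as errors.
* `N = 0` seeds, non-increasing timestamps, or a germination event at
  `D_t = 0` are errors in the vitality layer; transient count dips are
  monotonised by running maximum.
* A single-dish split warns and assigns everything to training; re-splitting
  an already-split manifest drops the stale assignment first.
* Checkpoint half-precision round-trips to ~1e-3 relative accuracy, which
  is ample for deployment-size accounting (the fp16 file is the quantity
  of interest, not bit-exact weights).

## Known limitations

* The internal schedules of the five lightweight variants are calibrated to
  the published budgets, not copied from a released implementation; other
  schedules could meet the same budgets. The budgets, shapes and component
  semantics are the tested contract.
* The forward engine is single-image, CPU, double precision — built for
  correctness and testability, not throughput.
* Smoke training fits only the output projections; it validates plumbing
  and learnability of the target encoding, never accuracy claims.
* The synthetic dose–response family is a stand-in with documented, fixed
  parameters; it is not a calibrated biological model of radish
  germination.
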