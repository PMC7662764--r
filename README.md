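# stgcn — spatial-temporal graph convolutional networks for tennis stroke recognition

`stgcn` classifies short tennis motion sequences — **forehand**, **backhand**
and **no-shot** (running between strokes) — from optical motion-capture
recordings of a player and their racket. It is aimed at movement-analysis and
sports-biomechanics work where stroke labels must be derived automatically
from marker trajectories, and at methodological work on whether *fuzzifying*
the network input improves skeleton-based action recognition.

The package implements the full pipeline in R:

* **Skeleton I/O** — a C3D reader/writer (plain-text CSV fallback), reduction
  of the 39-marker Plug-in-Gait body set + 7 racket markers to a canonical
  19-node human+racket skeleton, plane projection, phase assembly and
  per-sample normalization.
* **Graph machinery** — the skeleton graph G = (V, E) with symmetric
  degree-normalized adjacency and the graph-convolution primitive

  f_out = Λ^(−1/2) (A + I) Λ^(−1/2) f_in W,   Λᵢᵢ = Σⱼ (Aᵢⱼ + Iᵢⱼ),

  equivalent to a weighted sum over each joint's distance-≤1 neighbor set.
* **Fuzzification** — trapezoidal low/mid/high membership functions per
  coordinate channel, fitted as a partition of unity at training-split
  quantiles, expanding C = 2 coordinate channels to C = 6 memberships.
* **Classifier** — a 3-layer ST-GCN (32/64/64 feature maps; spatial graph
  conv → temporal conv → BatchNorm → ReLU), global average pooling over
  joints and time, a 1×1 convolution, fusion with an "active features"
  vector (per-joint speed/acceleration plus lower/upper posture-triangle
  lengths and angles), and a 3-way softmax head, trained by SGD with
  momentum and early stopping. Backpropagation is implemented in the
  package (BLAS matrix products plus two small compiled kernels).
* **Synthetic benchmark** — a kinematic generator emulating the study
  design: 1080 samples (348/354/378 per class), each assembled from three
  randomly combined within-class phase instances, with calibrated Gaussian
  noise and sparse marker artifacts.
* **Experiment protocol** — stratified train-fraction sweeps (10–65%,
  3 replicates) with paired raw-vs-fuzzy arms sharing splits and seeds.

## Worked example

Generate the default benchmark dataset, fit the fuzzy-input variant on a
50% stratified split, and evaluate on the held-out half (about a minute on
one CPU):

```r
library(stgcn)

ds  <- generate_dataset(generator_config(seed = 7))
ds
#> Motion dataset: 1080 samples of (C=2, V=19, T=14)
#>
#> forehand backhand  no_shot
#>      348      354      378

sp  <- stratified_split(ds$y, fraction = 0.5, seed = 1)
fit <- stgcn(ds[sp$train], fuzzy = TRUE, seed = 1)
evaluate(fit, ds[sp$test])
#> Overall accuracy: 92.2%
#> Per-class true-positive rates:
#> forehand backhand  no_shot
#>    0.937    0.915    0.915
#> Confusion matrix (rows = truth):
#>           predicted
#> truth      forehand backhand no_shot
#>   forehand      163        4       7
#>   backhand        0      162      15
#>   no_shot         0       16     173
```

The printed accuracy is the trace of the confusion matrix over the test-set
size; the per-class rates are its diagonal over the row sums. Setting
`fuzzy = FALSE` fits the raw-coordinate variant of the same architecture —
on this calibrated benchmark it scores several points lower, because sparse
marker artifacts pass unchecked into raw coordinates but saturate the
bounded membership channels. `run_sweep()` runs the full paired protocol
and `compare_variants()` tabulates the per-fraction fuzzy−raw differences.

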