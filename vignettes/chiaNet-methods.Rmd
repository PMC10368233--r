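---
title: "Predicting ChIA-PET interactions from Hi-C and ChIP-seq: models and methods"
author: "chiaNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ChIA-PET interactions from Hi-C and ChIP-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiaNet)
```

## The problem

ChIA-PET assays capture genome-wide chromatin contacts mediated by one
specific protein (CTCF, RNAPII, RAD21, ...), but the assay is expensive and
has been run in few cell types. Hi-C contact maps and 1D ChIP-seq binding
tracks are far more widely available. chiaNet treats the recovery of
protein-mediated interactions as a dense binary classification over the
pixels of a binned contact map: given the KR-normalized Hi-C matrix of a
chromosome and the binned ChIP-seq coverage of the mediating protein,
predict for every pixel (bin~i~, bin~j~) the probability that a ChIA-PET
interaction joins the two bins.

Ground truth for training comes from published ChIA-PET interactions: pixel
(i, j) is positive when bin i's interval overlaps one anchor and bin j's the
other anchor of any interaction (strict interval intersection; anchors are
usually shorter than one 10-kb bin, so most interactions light a single
pixel and its transpose).

## Data preparation

All coordinates are 0-based half-open bp in the file formats (BED-family
conventions) and 1-based bin indices inside R. Bin b covers
[(b-1)·r, b·r) at resolution r.

* **Hi-C**: read from Juicer-dump style triplet text (`bp1 bp2 value`) or a
  dense whitespace matrix, mirrored into a dense symmetric matrix. KR
  balancing itself is upstream; its NaN gaps are zeroed and bins whose whole
  row is zero are flagged *unmappable* and excluded from evaluation, so the
  huge all-zero stretches of centromeres cannot inflate the negative pool.
* **ChIP-seq**: a bedGraph binned by coverage-weighted mean, uncovered bases
  counting as zero, i.e. `sum(value x overlap) / r` per bin.
* **Normalization**: Hi-C counts are compressed with log2(x + 1) and
  min-max rescaled to [0, 1] per chromosome; ChIP-seq is min-max rescaled
  per chromosome. Both are then z-scored with a *frozen* reference mean/SD
  pooled over all training-chromosome window samples (`fitReferenceStats`),
  so validation, test chromosomes and other datasets are normalized
  identically to the data the network saw during training.
* **Windows**: samples are W x W tiles slid along the matrix diagonal with
  step s (defaults W = 250, s = 50 at 10 kb; W = 500, s = 100 at 5 kb). A
  final clipped origin n - W + 1 is appended so chromosome tails are always
  covered; chromosomes shorter than W yield one zero-padded tile. The 1D
  ChIP-seq window is broadcast into two 2D channels (chip[i] row-wise and
  chip[j] column-wise — always transposes of each other), concatenated with
  the Hi-C tile into a 3 x W x W tensor. Ablation configurations use only
  the Hi-C channel (C = 1) or only the two ChIP channels (C = 2).

## The network

A dilated residual convolutional network maps the C x W x W input to a
W x W logit map:

1. 1x1 convolution lifting C channels to a hidden width H (default 128),
   batch norm, ReLU;
2. B residual blocks (default 40), each with two dilated 3x3 convolutions
   (conv -> BN -> ReLU -> conv -> BN, added to the block input, ReLU);
3. 1x1 convolution down to one channel followed by batch norm; the logistic
   of the result is the per-pixel interaction probability.

Padding is always dilation·(k-1)/2, so every layer preserves the spatial
dimensions and the model applies to any W. Dilations are assigned
cyclically from the configurable cycle (default 1, 2, 4, 8, 16) across the
2B dilated convolutions, so the two convolutions of a block always differ
and the receptive field spans multiple scales, exceeding the 2-Mb
evaluation band. The exact per-block schedule of the original design is not
recoverable from its description, which is why the cycle is a config option
(`modelConfig(dilationCycle = ...)`) rather than a constant.

The engine is self-contained: forward pass, backpropagation, batch norm and
Adam are implemented in the package, with the convolution and batch-norm
kernels in C++ (im2col + GEMM via RcppArmadillo). Gradients are verified
against central finite differences in the test suite.

## Training protocol

Blind testing is leave-one-chromosome-out: the test chromosome contributes
no sample to training or validation; validation tiles come from the largest
remaining chromosome and all others form the training set (for human data,
testing chr1 means validating on chr2 and training on chr3..chrX). Every
pixel of every training tile — positive or negative — enters the loss; the
loss is positive-weighted binary cross entropy on logits in numerically
stable form (positive weight default 1, grid values 1/3/6/9/12).

Optimization is Adam with weight decay 1e-4, initial learning rate 1e-3
and batch size 16 by default, with the learning rate multiplied by 0.1
whenever the validation loss has not improved for 10 epochs. The returned
checkpoint is the epoch with the lowest validation loss. Two choices are
ours where the protocol is silent: training stops after `maxEpochs` or
after three plateau reductions with no later improvement; and the output
batch-norm bias is initialized at the empirical prior log-odds of a
positive pixel, so optimization starts at the base-rate predictor instead
of spending its first few hundred steps drifting the output bias across the
extreme class imbalance. Batch-norm running statistics adopt the first
batch's statistics outright before the usual exponential update, so early
validation losses are meaningful.

## Inference

A chromosome is tiled exactly as in training; each tile's probabilities are
accumulated per pixel, divided by the number of covering tiles, and the
matrix is symmetrized by averaging with its transpose. Probabilities, not
logits, are what get averaged — the merged scores are then directly
interpretable and rankable. For
the default geometries every pixel of the evaluation band is covered by at
least one tile (checked exhaustively in the tests for all n from 250 to
1000). Ranking is by descending probability with deterministic (i, j)
tie-breaks.

Shuffle controls quantify input attribution: `shuffleChIPseq` permutes the
1D binned vector before broadcasting; `shuffleHiC` permutes the strict
upper triangle of the normalized matrix and mirrors it, preserving symmetry
and the marginal value distribution while destroying spatial structure.
Keeping the diagonal fixed and mirroring is our choice — the input then
remains a valid symmetric contact map.

## Evaluation

Interactions live between 20 kb and 2 Mb, so only band pixels at distances
2..floor(2 Mb / r) bins (2-200 at 10 kb, 2-400 at 5 kb) are evaluated, in
the upper triangle only, excluding unmappable bins. Because negatives
outnumber positives by hundreds-fold, metrics are reported on negative sets
of controlled size — k·P sampled negatives for k in {1, 5, 20, 100}
(re-drawn 10 times, metrics averaged) plus the complete negative pool:

* **AP** — non-interpolated area under the step precision-recall curve
  (mean precision at each positive's rank);
* **ROC-AUC** — Mann-Whitney form from average ranks, ties counting 1/2,
  identical to the exhaustive all-pairs count;
* **top-N accuracy** — percent of true positives among the N top-ranked
  band pixels, N defaulting to P (then it equals recall at rank P).

Both AP and AUC are verified against brute-force oracles (explicit
rank-walking; all-pairs comparison) to 1e-12 in the tests. AP falls as
negatives are added while AUC is invariant in expectation — the expected
qualitative signature of any sound implementation, and a property test
here.

The model-free reference is the ChIP-seq inner product: score(i, j) =
sum over offsets a in [-5, 5] of chip[i+a]·chip[j+a], windows clipped to
common valid offsets at chromosome ends (the clipping rule is ours). It
captures "two peaks facing each other" and nothing about 3D contact
geometry.

## The synthetic generator

`simulateTrio` emulates the statistical setting of the real data with the
minimal generative model that couples all three data types:

* Hi-C counts are Poisson with mean
  `A·(1 + d)^(-alpha) x tadBoost^[same TAD] x loopEnrichment^[planted loop pixel]` —
  a distance-decay power law (default A = 120, alpha = 1, the range
  reported for mammalian contact maps), TAD blocks (mean size 80 bins,
  boost 1.6), and multiplicative enrichment (default 4) at planted loop
  pixels.
* ChIP-seq is exponential background (mean 1) plus peaks (amplitude ~8) at
  every loop-anchor bin *and* at decoy bins that carry no loop, plus
  Gaussian jitter; the decoys guarantee that ChIP-seq alone cannot classify
  perfectly, which is what makes the channel-ablation ordering
  (both >= Hi-C-only >= ChIP-only) a meaningful check rather than a
  tautology.
* ChIA-PET interactions are exactly the planted loop pixels' bin intervals,
  so the label matrix reconstructed through the BEDPE round trip equals the
  planted truth bitwise.

The desk-scale study conditions are three chromosomes of 480/520/560 bins
with 60 loops and 60 decoys each at distances 5-45 bins, window 64, step
16, band 2-48 bins, and a small network (H = 16, B = 4) trained with batch
size 4 and initial learning rate 0.01 for at most 60 epochs — batch size
and rate taken from the small end of the hyperparameter grid because the
corpus is ~50x smaller than a real genome, giving a comparable number of
optimizer steps per epoch budget. These conditions are what the acceptance
script and the end-to-end tests run.

What the generator does *not* emulate: KR balancing biases and their NaN
structure beyond whole-bin gaps, copy-number and mappability artifacts,
anchor-length variation below bin size (anchors are bin-aligned by
default), distance-dependent loop strength, and the correlated noise of
real sequencing. Passing the synthetic recovery tests therefore shows the
pipeline is implemented coherently end to end — not that the small model
would reach the same headline numbers on real GM12878 data, which requires
GPU-scale training of the full 128 x 40 network.

## Numerical choices and degenerate inputs

* Min-max of a constant matrix or track returns all zeros; the reference SD
  is floored at 1e-8 with a warning.
* Score ties anywhere (ranking, AP, AUC, top-N) break by ascending (i, j)
  or original position, making every reported number deterministic.
* Triplet duplicates overwrite with a warning; negative counts are rejected
  row-wise; bins beyond the grid are an error naming the offending row.
* Chromosomes shorter than the band minimum produce an empty prediction
  with a warning rather than an error, so genome-wide loops don't crash on
  chrM-sized scaffolds.
* Pixels in tiles beyond a short chromosome's end (zero padding) contribute
  neither to training loss tiles nor to merged predictions.

## Limitations

The full-scale configuration (H = 128, B = 40, W = 250) is expressible and
correct but not practical to train in this CPU-only implementation; the
package targets method development, protocol validation and desk-scale
experiments. Loop-cluster merging, inter-chromosomal contacts, and
significance tests beyond the reported metrics are out of scope.
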