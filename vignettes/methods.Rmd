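---
title: "From clinical records to images: methods behind tab2img"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical records to images: methods behind tab2img}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tab2img)
```

## The problem

Convolutional networks exploit spatial correlation between neighbouring
pixels, which a 1-D clinical record — a vector $x \in \mathbb{R}^d$ of
unitless measurements with a binary diagnosis — does not have.  tab2img
makes tabular records eligible for convolution by rendering each record
as a small 2-D image in which nearby pixels *are* correlated by
construction, then trains a compact CNN on the rendered images.  The
motivating application is breast-cancer diagnosis from cytology and
biopsy measurements (the two classic Wisconsin tables, with 9 and 30
features respectively), but nothing in the package is specific to that
domain beyond the malignant-negative label convention.

## The three encoders

All encoders require the record to be min-max normalized to $[0,1]$
per feature over the observed data (`minmax_normalize()`; constant
columns map to 0 so uninformative fields render as empty bars).

**Equidistant bar graph.**  Feature $k$ becomes a vertical bar of width
$\psi$ pixels; bars are separated and flanked by gaps of $\gamma$
pixels, so the image width is

$$W = \psi d + \gamma(d+1),$$

and the height is set equal to $W$ to make the image square.  Bar $k$
is drawn bottom-up with $\mathrm{round}(x_k W)$ foreground pixels at
intensity 1 on a 0 background.  With the defaults $\psi = 1$,
$\gamma = 2$ the side is $3d + 2 \approx 3d$.  The `px1`/`px2`/`px4`
variants set $\psi$ to 1, 2 or 4 with $\gamma$ fixed at 2.  Two
conventions here are genuinely open — nothing pins down the rasterizer:
we draw bottom-up and round the bar height with R's `round()`
(round-half-to-even at exact ties); flooring or anti-aliased rendering
would be equally defensible and differ by at most one pixel row.

**Normalized distance matrix.**  Pixel $(i,j)$ is the Euclidean
distance between the two scalar features, $|x_i - x_j|$.  The matrix is
divided by its own maximum so intensities span $[0,1]$; a constant
record yields an all-zero image rather than an error.  Per-image (not
dataset-wide) normalization keeps every image's full dynamic range, at
the cost of making absolute intensities incomparable across records —
the network only ever sees one image at a time, so contrast matters
more than comparability.  The native $d \times d$ image is upscaled by
integer pixel replication (default 3, giving $3d \times 3d$); replication
rather than interpolation keeps the image an exact function of the
record.

**Combined (3-channel).**  A colour image of size $3d \times 3d \times 3$:
channel 1 the distance matrix upscaled 3×, channel 2 the bar graph,
channel 3 a row-wise copy of the record ($x_{ij} = x_i$, replicated over
three pixel rows per feature).  The bar graph's native width $3d+2$
does not match $3d$; we centre-crop one pixel from each border (for
other $\psi$ the graph is nearest-neighbour resampled).  The crop loses
only gap columns on the left/right and at most the top pixel row of a
saturated bar.  Channel order follows the listing order above.

## Ordering the fields

Bar-graph and combined images change with the order of the fields, and
placing related fields adjacently gives the convolution kernels local
structure to work with.  Relatedness is measured by covariance: from
the sample covariance of the (normalized) features, each row of the
$d \times d$ matrix is converted to ranks — the partner with the largest
covariance *magnitude* gets rank 1, ties break to the lower column
index.  Magnitude is used because a strong negative covariance is just
as much relatedness as a positive one.  A field ordering is scored by
the sum of symmetrized ranks $\tfrac12(r_{ij} + r_{ji})$ over
consecutive pairs — an open path, since a row of bars has two ends and
no wrap-around — and reversing an ordering never changes its cost.
The rank matrix is row-wise asymmetric, so some symmetrization is
needed to make the path objective well defined; averaging the two
directed ranks is the least-committal choice.

Minimizing this cost is a travelling-salesman-path problem.  Two
solvers are provided:

* `brute_force_order()` — exact, for $d \le 10$: lexicographic
  depth-first enumeration with branch-and-bound pruning, halving the
  work via reversal symmetry.  The first strict improvement is kept, so
  ties resolve to the lexicographically smallest optimum.
* `ga_order()` — a permutation-encoded genetic algorithm for any $d$:
  tournament selection (size 3), order crossover (rate 0.9),
  per-position swap mutation (rate 0.1), elitism of one, five random
  immigrants per generation, and a 2-swap hill-climb polish of each
  generation's best individual, run for 100 generations over a
  population of 100 that always contains the identity ordering (so the
  returned cost is never worse than not reordering at all).

The GA's population size, immigrant injection and elite polish were
chosen by benchmarking against the exhaustive solver on batches of 100
random rank instances ($3 \le d \le 8$) across several independent seed
sets: a plain small-population GA (population and generations of 50,
whole-offspring mutation) stalled on local optima in up to ~18% of
instances, while the configuration above recovers the exact optimum in
96–99% of instances in every batch while remaining fast at $d \approx 30$.
On well-structured problems the best cost typically stops improving
within the first ten generations.

## The network and training protocol

`build_architecture()` constructs a VGG-style network with exactly four
convolutional blocks.  Block $L$ ($L = 1..4$) holds a $3 \times 3$
same-padding convolution with

$$f_L = \left\lfloor 0.5 \cdot L \cdot \lfloor \sqrt{P} \rfloor \right\rfloor$$

filters ($P$ = spatial pixel count of the input; for square images
$\lfloor\sqrt P\rfloor$ is the side length), a ReLU, and a
$2 \times 2$ max pool of stride 2 (odd trailing rows/columns dropped).
The head flattens the last block into one hidden dense layer (width 64,
our choice — the convolutional trunk is the specified part) and a
2-way softmax.  Inputs must be at least $16 \times 16$ so that four
pools remain feasible; smaller encodings should be upscaled.

Training (`train_cnn()`) is plain SGD with classical momentum 0.88, L2
penalty $9.4 \times 10^{-7}$, mini-batches of 8 sampled uniformly, and a
constant learning rate of 0.02 (these rates were originally found by a
log-scale search; an optional exponential decay is available but off by
default).  The iteration budget is 1000 update steps, counted as
mini-batch updates rather than epochs; every 50 steps the
full-training-set cross-entropy is evaluated and training stops early
once it falls below $10^{-3}$ — on separable data this typically
triggers within a few hundred steps and changes nothing but run time.
Weights use He initialization; the whole run is a deterministic
function of the seed.  The engine itself is written in base R: the
convolutions are lowered to matrix multiplications via im2col with
memoised gather indices, so BLAS does the arithmetic, and the backward
pass was verified against central finite differences.

`run_experiment()` implements the evaluation protocol: per attempt the
dataset is re-split — 80% training / 20% test, then 20% of training
held out for validation, stratified, using floor arithmetic for the
partition sizes (at $N = 569$: test 113, validation 91, training 365) —
the records are encoded, a fresh network is trained, and validation and
test accuracies are recorded.  Attempt $a$ uses seed $\texttt{seed}+a$.
Best and mean accuracies over attempts are reported, mirroring the
best/average presentation of repeated-attempt studies; re-splitting
per attempt is the more conservative reading of "attempt" (the
alternative — re-initializing weights on a fixed split — measures only
optimizer noise).  Normalization statistics default to the full dataset
before splitting, matching the wrangle-then-split protocol; `tabcnn()`
and `minmax_normalize(stats_from =)` support train-only statistics for
leakage-free deployment.

## Evaluation

Malignant is the negative class (0), benign the positive (1), so the
true-negative cell counts correctly identified malignant records.  From
the confusion matrix: sensitivity $tp/(tp+fn)$, specificity
$tn/(tn+fp)$, precision $tp/(tp+fp)$, F1 their harmonic mean, accuracy
$(tp+tn)/N$.  A zero denominator raises an explicit error rather than
silently scoring 0.  Rounding to two decimals happens only at
presentation; all internal comparisons are on exact count ratios.

## The synthetic generator

`simulate_tabular()` draws features class-conditionally from
multivariate normal distributions with unit variances and
block-diagonal correlation; informative features (the first
`ceiling(informative_fraction * d)`) have class means at
$\pm\,\mathrm{separation}/2$.  A Gaussian model is appropriate because
the target tables are continuous/ordinal measurements and min-max
normalization is applied before encoding anyway; the correlation blocks
give the ordering optimizer a known ground truth to recover.  Defaults
(half the features informative, no correlation, balanced classes, no
missing cells) describe a moderately informative clinical table; tests
and the acceptance script state their own settings explicitly.

At separation 3 with 5 informative features the Mahalanobis distance
between classes is $3\sqrt5 \approx 6.7$, putting the Bayes error below
$10^{-3}$ — a pipeline that works must score near 100%.  At separation
0 the labels are independent of the features, so any test accuracy
outside the binomial band around the majority rate indicates leakage.

What the generator does **not** emulate: the integer quantization,
skewed marginals and feature-scale heterogeneity of real cytology
measurements, missingness that is informative rather than uniform, and
inter-patient correlation.  Passing on synthetic data therefore
demonstrates the machinery (encoding, optimization, training,
bookkeeping) under known ground truth, not clinical performance; the
loaders accept the real UCI files for that purpose.

## Degenerate inputs and numerical choices

* Constant feature columns normalize to 0 and rank last under the
  covariance tie rule; constant records give all-zero distance images.
* Missing cells must be resolved before normalization; `drop_rows` is
  the default policy in `tabcnn()` (consistent with the evaluation
  partition sizes observed on the classic 699-row table), `impute_mean`
  the alternative; imputing an entirely missing feature is an error.
* Image files are 8-bit quantized PNGs; the in-memory contract stays
  real-valued in $[0,1]$.
* Problem sizes in the test-suite and acceptance script — $n = 400$,
  $d = 10$, 5 attempts for recovery; 100 rank instances at $d \le 8$
  for the ordering oracle — were chosen as the smallest sizes at which
  the respective claims are statistically meaningful.

## Limitations

* The engine is CPU-scale by design: images of side $\lesssim 100$ and
  a few thousand records train in minutes; it is not a general deep
  learning framework (no GPU, no alternative optimizers or
  architectures).
* Bar shapes, colours and arrangements beyond the equidistant design,
  and distance matrices augmented with neighbourhood statistics, are
  out of scope.
* ROC/AUC and calibration are not computed; the evaluation surface is
  the confusion matrix and its derived diagnostics.
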