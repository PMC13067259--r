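---
title: "Texture-based image classification with annealed feature weights and a simulated quantum-classical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based image classification with annealed feature weights and a simulated quantum-classical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantex)
```

## Overview

`quantex` classifies grayscale images by their second-order texture
statistics. The pipeline has four stages:

1. **Preprocessing** — mean imputation of missing pixels, Gaussian
   smoothing, min-max intensity normalization, and uniform gray-level
   quantization to `L` levels.
2. **Texture description** — gray-level co-occurrence matrices (GLCMs)
   over a grid of pixel-pair distances and angles, summarized by six
   Haralick features each: contrast, energy, correlation, homogeneity,
   entropy, and dissimilarity.
3. **Feature weighting (FSSA)** — a simulated-annealing search over a
   continuous weight in $[0,1]$ per feature, maximizing
   $a\cdot\text{accuracy} - b\cdot\text{redundancy}$. Features are
   re-weighted, never eliminated.
4. **Classification** — a hybrid quantum-classical model simulated
   exactly on a state vector: one amplitude-encoded input qubit per
   selected feature, a Hadamard-initialized hidden register, a
   controlled-rotation entangling layer, exact Z-expectation readout, and
   a classical tanh/sigmoid head trained against binary cross-entropy by
   simulated annealing, one one-vs-rest head per class.

A synthetic generator supplies class-labelled textured images and
planted-signal feature tables, so the whole pipeline is testable without
external data.

## Preprocessing

Images are numeric matrices of 8-bit intensities with `NA` marking
missing pixels. Missingness never arises from PNG input; it exists so the
imputation stage is exercised (synthetic injection) and so the pipeline
tolerates partially corrupt sources. Mean imputation replaces each `NA`
with the mean of the observed pixels and is idempotent.

Smoothing is a separable Gaussian convolution with kernel truncated at
$3\sigma$ and renormalized to unit sum, with **reflective** boundary
handling. This combination preserves constant images exactly and
conserves total pixel mass, both of which are asserted in the tests.
Default `smooth_sigma = 1` pixel — enough to suppress pixel noise without
erasing the short-range structure the $d = 1$ co-occurrences measure.

Min-max normalization maps every image to $[0,1]$; a constant image maps
to zeros by convention so the operation is total. Quantization bins
$[0,1]$ uniformly into `L` integer levels $0..L-1$. The composition
`quantize(normalize_intensity(.))` is invariant under affine intensity
rescaling, which makes the texture features robust to global gain and
offset changes.

The default gray-level count is $L = 32$. A $256\times256$ co-occurrence
matrix cannot be populated meaningfully by small images or windows; 32
levels is the usual compromise between intensity resolution and matrix
occupancy. Motion correction and slice-timing compensation exist as named
identity hooks: they mark where registration-grade preprocessing would
sit in a full MRI chain, which is outside this package's scope.

## GLCMs and Haralick features

For an offset given by distance $d$ and angle
$\theta \in \{0, \pi/4, \pi/2, 3\pi/4\}$ (image convention: $\theta = 0$
points along rows to the right, $\pi/2$ points up), the GLCM entry
$P(i,j)$ is the probability that gray levels $i$ and $j$ co-occur at that
offset. By default matrices are **symmetric** (each pair counted in both
directions) and normalized to sum one. The features are the standard
forms:

$$\text{contrast} = \sum_{i,j}(i-j)^2 P(i,j), \quad
  \text{energy} = \sum_{i,j}P(i,j)^2, \quad
  \text{dissimilarity} = \sum_{i,j}|i-j|\,P(i,j),$$

$$\text{homogeneity} = \sum_{i,j}\frac{P(i,j)}{1+|i-j|}, \quad
  \text{correlation} = \frac{\sum_{i,j} ij\,P(i,j)-\mu_x\mu_y}{\sigma_x\sigma_y}, \quad
  \text{entropy} = -\sum_{i,j}P(i,j)\log_2(P(i,j)+\varepsilon).$$

Numerical conventions: correlation returns 0 when a marginal is
degenerate ($\sigma_x\sigma_y < 10^{-12}$); entropy uses
$\varepsilon = 10^{-12}$ so empty cells contribute nothing, and carries
the minus sign so that randomness increases entropy.

The default grid is distances $\{1,3,5,7\}$ times four angles times six
features — a 96-long vector per image, concatenated rather than averaged
across offsets, so the downstream weighting stage can decide which
offsets matter. A 9×9 sliding-window mode (averaging per-window feature
values) is available but opt-in; whole-image GLCMs are the default
because they are two orders of magnitude cheaper and equally
discriminative on globally textured images.

## The annealing engine

One Metropolis engine serves both the feature-weight search and
classifier training, under a minimization convention (maximizers negate
their objective). A proposal with energy change $\Delta E \le 0$ is always
accepted (ties included — this aids plateau exploration); otherwise it is
accepted with probability $e^{-\Delta E/T}$. The temperature follows
geometric cooling $T_{t+1} = \gamma T_t$ with defaults $T_0 = 1$,
$\gamma = 0.95$, 500 iterations, stopping early if $T$ falls below
`T_min` ($10^{-6}$). A rejected proposal leaves the chain in place; the
best solution ever accepted is returned, so the best-energy trace is
monotone. Runs are bit-reproducible under a fixed seed.

## FSSA

Weights start uniform on $[0,1]^n$ and are perturbed by i.i.d. Gaussian
noise ($\sigma = 0.05$) on **every** coordinate, clipped back to
$[0,1]$. Clipping puts positive probability on the exact boundary values,
which is how a feature can be silenced completely. The objective is
$a \cdot \text{accuracy} - b \cdot \text{redundancy}$ with defaults
$a = 1$, $b = 0.5$:

* **accuracy** is, by default, a nearest-class-centroid classifier on a
  seeded stratified 75/25 split of the training data. Putting a full
  network training inside every annealing step would multiply the cost by
  the iteration count; the centroid classifier responds to the same
  geometry (distances in weighted feature space) at negligible cost. The
  evaluator is pluggable (`accuracy_fn` in `fssa_config()`), so the full
  classifier can be substituted where fidelity matters more than time.
* **redundancy** is the mean absolute Pearson correlation over all
  unordered feature pairs of the weighted matrix. Absolute values are
  used because sign cancellation would let strongly anti-correlated pairs
  evade the penalty. Correlation is scale-invariant, so this term responds
  to the weights only through exact zeros — another reason the clipped
  perturbation matters.

We kept the all-coordinate perturbation after explicitly comparing it
with single-coordinate proposals, which move each weight only
$\sim\!500/n$ times per run and recover planted structure less often.

A known limitation, visible in the package's own planted-signal check:
when the classes are separable enough that the internal validation
accuracy saturates, the objective loses its ability to distinguish
informative from noise features (zeroing noise columns no longer changes
accuracy, while the redundancy term mildly prefers zeroing the mutually
correlated informative columns). Under the default study conditions the
recovery rate is roughly 0.7–0.8 per seed rather than near-certain. The
acceptance script reports the measured rate; nothing in the package
asserts a higher one.

## The classifier

With $N$ input and $M$ hidden qubits (register msb-first, inputs first),
a scaled feature $x \in [0,1]$ is encoded as
$\sqrt{x}\,|0\rangle + \sqrt{1-x}\,|1\rangle$ and the sample is the
tensor product of its feature qubits. The hidden register starts in the
uniform superposition. The trainable quantum part is an entangling layer
of controlled rotations: for each input qubit $i$ and hidden qubit $j$, a
controlled-$R_y(W_{ji})$ with control on $|1\rangle$ of qubit $i$,
applied in fixed $(i, j)$ ascending order. A linear map
$|h_j\rangle = \sum_i W_{ji}|x_i\rangle$ is not unitary, so the
controlled-rotation layer is the smallest faithful realization of a
parameterized input-to-hidden transition that preserves the $W_{ji}$
indexing and creates genuine entanglement.

Readout is exact: each hidden qubit's Z-expectation
$a_j = P(0) - P(1)$ is computed from the amplitudes (no shot noise), then
$\hat y = \operatorname{sigmoid}\!\big(\sum_j V_j \tanh a_j\big)$. The
hyperbolic tangent respects the $[-1,1]$ range of an expectation; the
sigmoid produces the probability that binary cross-entropy requires. The
output register contributes no gates — the readout is classical — but the
architecture records `K` output qubits for bookkeeping. With $W = 0$ the
hidden register never sees the inputs and $\hat y = 0.5$ for any sample;
with $V = 0$, likewise. Both degeneracies are asserted in tests, as is
agreement with an independent dense-matrix gate oracle for all register
sizes up to four qubits.

Everything is simulated on a dense state vector, capped at
$N + M \le 14$ qubits. The batch forward pass holds all samples'
amplitudes as a matrix and applies each gate once to the whole batch,
which is what makes annealed training (one full-data loss per iteration)
cheap.

Training flattens $(W, V)$, initializes uniformly in $[-0.1, 0.1]$ (small
angles keep the entangling layer near identity, so training starts from
an unbiased $\hat y \approx 0.5$), and anneals with Gaussian proposals of
$\sigma = 0.1$ radians under the same default schedule. An optional
finite-difference gradient mode (central differences, step $10^{-4}$,
learning rate 0.01, 200 epochs, batch 32) honors the classical
hyperparameter set; `mode = "sa+gd"` chains them. Multiclass problems use
one-vs-rest heads sharing the architecture, trained independently with
derived per-head seeds; prediction is the argmax of the head
probabilities with ties to the lowest class index. Binary cross-entropy
uses the natural logarithm and clips predictions to
$[10^{-12}, 1-10^{-12}]$.

When more features exist than input qubits, the $N$ features with the
largest FSSA weights are encoded — the weights are the pipeline's own
relevance measure. Selected features are min-max scaled to $[0,1]$ on the
training fold; validation samples are clipped into the training range.

## Evaluation

Confusion matrices are true-by-predicted count matrices. For multiclass
reports, `accuracy` is the overall fraction correct (so chance on
balanced four-class data is 0.25), while precision, sensitivity and
specificity are macro-averaged one-vs-rest values with any $0/0$ mapped
to 0; per-class values are also returned. Cross-validation is stratified
by default, and FSSA is refit inside each training fold — the held-out
fold influences neither the weights nor the scaling, which closes the
leakage channel a single pre-CV weighting would open. The
`compare_fssa` switch evaluates the identical folds with and without the
weighting stage.

## Synthetic data

The image generator emulates the *shape* of a four-class, balanced,
128×128 8-bit grayscale dataset, not its anatomy: each class is a
Gaussian random field — white noise smoothed at a class-specific
correlation length, standardized, scaled by a class amplitude, shifted to
mid-gray and clipped. Default smoothness $(0.5, 1, 2, 4)$ pixels
(strictly increasing, so short-range GLCM contrast is strictly ordered
across classes by construction) and amplitudes $(1.0, 0.9, 0.8, 0.7)$.
These defaults give separation that is comfortably detectable but not
trivial at $L = 32$. An elliptical zero-background mask and `NA`
injection are optional; images are written as PNG because lossy
compression would perturb the deterministic GLCM tests.

What passing tests on this generator do **not** show: robustness to
anatomical variability, intensity bias fields, acquisition noise
statistics, or class differences that are morphological rather than
textural. The generator plants exactly the kind of signal the method
measures; real-data performance claims are outside what this package can
support.

The planted feature table draws `k_informative` columns with
class-dependent means separated by `effect` within-class standard
deviations (means proportional to the class index) plus pure-noise
columns, shuffles the column order, and records the ground-truth mask in
an attribute.

## Problem sizes and reproducibility

The shipped study conditions are 100 images per class (400 total) at
128×128, a 96-feature Haralick grid, FSSA and training budgets of 500
annealing iterations, and 5-fold stratified cross-validation; the
acceptance script additionally runs ten 400-sample planted tables. One
global seed fans out to per-stage seeds through a fixed stage-name hash,
and a complete `run_all()` is byte-reproducible: identical feature CSVs
and model JSONs across executions with the same seed.

## Known limitations

* The entangling layer is one controlled-rotation sweep; deeper circuits,
  shot noise, decoherence and hardware backends are out of scope.
* The FSSA objective loses identifiability when its internal accuracy
  estimate saturates (see above).
* Only 2D single-channel images are supported; no 3D volumes, NIfTI,
  registration or skull stripping.
* `read_image()` reads PNG; other formats should be converted upstream.
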