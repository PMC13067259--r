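# quantex

Texture-based classification of grayscale images with simulated-annealing
feature weighting and a simulated hybrid quantum-classical classifier.

`quantex` is aimed at researchers studying texture-driven image
classification — the setting where disease stages (e.g. dementia severity
on axial brain MRI) express themselves as changes in second-order
intensity statistics rather than shape. The package implements the whole
chain as reusable, seeded, testable R functions, with a synthetic
generator standing in for clinical data.

## The method

**Texture features.** For each offset (distance $d$, angle $\theta$), the
gray-level co-occurrence matrix (GLCM) $P(i,j)$ holds the probability that
quantized intensities $i, j$ co-occur at that offset. Six Haralick
descriptors summarize each matrix:

- contrast $\sum (i-j)^2 P(i,j)$, dissimilarity $\sum |i-j| P(i,j)$
- energy $\sum P(i,j)^2$, homogeneity $\sum P(i,j)/(1+|i-j|)$
- correlation $(\sum ij\,P(i,j) - \mu_x\mu_y)/(\sigma_x\sigma_y)$
- entropy $-\sum P(i,j)\log_2(P(i,j)+\varepsilon)$

The default grid (distances 1, 3, 5, 7 × four angles) yields 96 features
per image.

**FSSA (feature-specific simulated annealing).** Each feature gets a
continuous weight $w \in [0,1]$; a Metropolis chain with geometric cooling
($T_0 = 1$, $\gamma = 0.95$, 500 iterations) maximizes
$a\cdot\mathrm{accuracy}(F_w) - b\cdot\mathrm{redundancy}(F_w)$, where
accuracy is a fast nearest-centroid hold-out estimate (pluggable) and
redundancy the mean absolute pairwise feature correlation. Features are
re-weighted, never discarded.

**Classifier.** The top-$N$ weighted features are amplitude-encoded, one
qubit each ($\sqrt{x}|0\rangle + \sqrt{1-x}|1\rangle$); a
Hadamard-initialized hidden register is entangled with the inputs by
controlled-$R_y(W_{ji})$ rotations; exact Z-expectations $a_j$ are read
out and combined classically,
$\hat y = \mathrm{sigmoid}(\sum_j V_j \tanh a_j)$. Heads are trained
one-vs-rest against binary cross-entropy by the same annealing engine
(gradient mode also available). Everything runs on an exact state-vector
simulation — no quantum hardware, no sampling noise.

**Evaluation.** Stratified k-fold cross-validation with the weighting and
training refit inside each training fold, confusion matrices, and
accuracy / macro precision / sensitivity / specificity, including a
with/without-FSSA comparison on identical folds.

## Worked example

Four synthetic texture classes (Gaussian random fields of increasing
smoothness), 25 images per class at 64×64, a reduced feature grid, and
5-fold cross-validation:

```r
library(quantex)

cfg <- pipeline_config(
  seed     = 11L,
  simulate = synthetic_config(n_per_class = 25L, size = 64L),
  texture  = texture_config(distances = c(1L, 3L), levels = 32L),
  arch     = qdnn_architecture(4L, 2L),
  k        = 5L)

ds       <- generate_dataset(cfg$simulate)
features <- run_extract(ds$manifest, cfg, images = ds$images)
dim(features$values)
#> [1] 100  48

round(features$values[1:3, 1:4], 3)
#>      d1_a0_contrast d1_a0_energy d1_a0_correlation d1_a0_homogeneity
#> [1,]          8.582        0.006             0.811             0.416
#> [2,]          5.967        0.006             0.890             0.448
#> [3,]          2.749        0.010             0.954             0.561

res <- run_evaluate(features, cfg, compare_fssa = TRUE)
unlist(res$with_fssa$mean)
#>    accuracy   precision sensitivity specificity
#>       0.950       0.958       0.950       0.983
res$with_fssa$confusion
#>     predicted
#> true  0  1  2  3
#>    0 24  1  0  0
#>    1  1 24  0  0
#>    2  0  0 25  0
#>    3  1  0  2 22
```

Rougher textures have higher short-range contrast (row 1 vs row 3 above),
which is the signal the classifier learns. Mean cross-validated accuracy
is 0.95 against a 0.25 chance level; the pooled confusion matrix shows
the residual confusions sit between the most similar (adjacent-smoothness)
classes. On this easy fixture the unweighted pipeline reaches 0.98 —
FSSA's value shows on feature sets with genuinely redundant or noisy
columns, and its planted-signal behaviour is quantified by the
acceptance script below.

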