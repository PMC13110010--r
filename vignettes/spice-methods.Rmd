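---
title: "Identifying cell-cell-communication-affected genes by model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cell-cell-communication-affected genes by model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spice)
```

## The problem and the approach

Imaging-based spatial transcriptomics (MERFISH, Xenium and kin) measures
gene expression per cell *and* keeps each cell's position in the tissue.
That makes a question answerable that bulk and dissociated single-cell
assays cannot touch: does the expression of a gene in a cell depend on what
its *neighbors* are doing — i.e., is the gene under the influence of
cell-cell communication (CCC)?

`spice` answers it by model selection on predictive performance. For each
response gene we fit two predictors of its per-cell expression from ligand
and receptor expression:

* a **spatially ignorant** model, which sees only the target cell's own
  predictors (neighborhood radius $r = 0$), and
* a **spatially informed** model, which additionally sees the predictors of
  every cell within $r$ micrometres (graph radius $r > 0$).

Both are evaluated on held-out tissue. Writing $\hat\sigma^2_{r,g}$ for the
test mean squared error of the radius-$r$ model on gene $g$, the per-gene
evidence for spatial regulation is the loss reduction

$$\mathrm{LR}(g, r) = 100 \cdot
  \frac{\hat\sigma^2_{0,g} - \hat\sigma^2_{r,g}}{\hat\sigma^2_{0,g}}.$$

Because the exact conditional expectation minimizes MSE, a substantially
positive loss reduction means a spatially ignorant conditional model is
inadequate for that gene. The validity of this comparison hinges on the
spatially informed model being flexible enough: if it summarizes the
neighborhood with a fixed statistic (say, the mean expression of neighbors),
a failure to improve may reflect the summary, not the biology. The package
therefore uses a graph convolutional network that learns its own
neighborhood aggregation, and ships the fixed-summary regressors (ridge,
lasso, elastic net, gradient boosting on mean-aggregated features) as the
comparison class.

## The model

Cells are nodes of a per-tissue graph; a pair of directed edges connects
every two cells strictly closer than $r$ µm. Each edge carries a polar
descriptor $e_{ij} = (\lVert x_j - x_i \rVert,\;
\operatorname{atan2}(y_j - y_i, x_j - x_i))$ — or distance, azimuth and
inclination in 3D. The convolution operator is a Gaussian-mixture kernel
(the MoNet family): kernel $k$ owns a linear map $\Theta_k$, a center
$\mu_k$ and a diagonal covariance $\Sigma_k$ on edge-descriptor space, and a
node aggregates

$$x_i' = \frac{1}{|N(i)|} \sum_{j \in N(i)} \frac{1}{K} \sum_{k=1}^K
  w_k(e_{ij})\, \Theta_k x_j, \qquad
  w_k(e) = \exp\!\left(-\tfrac12 (e - \mu_k)^\top \Sigma_k^{-1}
  (e - \mu_k)\right).$$

Three hidden blocks of the form
$H^{(\ell+1)} = \mathrm{ReLU}\!\left(\mathrm{GMMConv}(H^{(\ell)}) +
H^{(\ell)} W^{(\ell)}\right)$ are followed by a plain dense output layer
onto the response genes; all genes are predicted jointly under one MSE
loss. Ligand/receptor inputs are `log1p`-transformed; responses stay on
their raw scale. Training uses Adam at learning rate $10^{-3}$, one
gradient step per training graph, early stopping after 10 epochs without
validation improvement, $K = 10$ kernels per layer. Forward and backward
passes are implemented directly on (sparse) matrices, so the package has no
deep-learning runtime dependency and is bit-reproducible given a seed.

### Conventions and numerical choices

* **Empty neighborhoods.** $1/|N(i)|$ is undefined for an isolated cell;
  the convolution then returns the zero vector. A useful consequence: the
  $r = 0$ network is *exactly* the per-cell dense network, so the spatially
  ignorant baseline is the same architecture minus the graph — the model
  families are nested by construction.
* **Strict threshold.** An edge requires $0 < d(i,j) < r$; ties at exactly
  $r$ are excluded, and $r = 0$ yields an edgeless graph.
* **Angles.** The two-argument arctangent is used, so angles live in
  $(-\pi, \pi]$ and resolve the full quadrant; a principal-branch
  $\arctan(\Delta y / \Delta x)$ would fold opposite directions together.
  The Gaussian kernels do not wrap angles periodically; kernels near
  $\pm\pi$ can in principle split a direction across two kernels, which the
  mixture compensates for in practice.
* **Covariances.** $\Sigma_k$ is parameterized as diagonal learnable
  log-variances — positive-definite by construction.
* **Initialization.** Distances are kept in raw µm, so kernel
  initialization must carry the scale: centers spread the distance
  component uniformly over $[0, r]$ and angles over $(-\pi, \pi]$;
  log-variances start at $\log((r/2)^2)$ for distance and $\log(\pi^2)$ for
  angles, so initial kernels cover the whole attainable descriptor range.
  (Unit variances would leave almost every edge at weight
  $\approx e^{-d^2/2}$ — numerically zero beyond a few µm — and gradients
  dead.) Dense weights and $\Theta_k$ use fan-in-scaled uniform draws.
* **Output bias warm start.** The final dense bias starts at the per-gene
  training-mean response (`init_output_bias = "target_mean"`). With a fixed
  learning rate of $10^{-3}$ and graph-level steps, starting at zero would
  spend on the order of a thousand updates just reaching the response mean;
  the warm start is the usual intercept initialization for regression
  networks and changes nothing about the model class.
* **Hidden width.** Not dictated by the architecture; the constructor
  default is 256, and the benchmark studies in this package use 64 (stated
  below with the study sizes).
* **Biases.** Dense layers carry biases; the convolution does not. No
  self-loops are added — the residual dense term carries self-information.

## Splitting: why it is not random over cells

Cells within one tissue are dependent, so random cell-level splits leak.
Two modes are provided:

* `split_by_group()` holds out whole animals/donors (the natural protocol
  when many tissues are available) — no group contributes cells to two
  partitions.
* `spatial_partition()` handles the single-tissue case: the tissue is tiled
  along its longest axis into equal-count tiles and a strip of width
  `buffer` is dropped at each internal boundary, so retained cells in
  different tiles are farther than `buffer` apart and no graph with
  $r \le$ `buffer` ever connects two partitions. The tiling-with-buffer
  construction is this package's design; it guarantees the disconnectedness
  property by geometry and is verified by brute force in the tests. Tiles
  are then interleaved across train/validation/test deterministically.

The same split is reused for every radius in `radius_sweep()`, so
per-radius MSEs are paired comparisons, and per-radius seeds are derived
deterministically from one master seed.

## Inference: the paired cluster bootstrap

A loss reduction is a point estimate; `paired_error_test()` attaches
uncertainty. For gene $g$ let $d_c = \mathrm{err}_{r_0}(c) -
\mathrm{err}_{r}(c)$ be the per-cell squared-error difference on the test
set. We test the one-sided null $E[d_c] \le 0$ (the informed model is no
better) by resampling *clusters* — slices, or animals when available — with
replacement, respecting within-tissue dependence. The p-value is the
add-one-corrected fraction of bootstrap replicates whose mean improvement
is non-positive, and Benjamini–Hochberg adjustment is applied across genes.
Two boundary cases pin the construction: identical error arrays give
$p = 1$, and a uniform improvement gives the bootstrap floor
$p = 1/(B+1)$. The test needs several clusters per partition to have
resolution — with $C$ test clusters the attainable false-positive rate of
an all-positive fluke is $2^{-C}$, so we recommend at least 6 test
tissues.

## The synthetic benchmarks

Real data carry no ground truth, so the package ships generators with a
*planted* interaction radius $r^\* = 30$ µm, used by the test suite and the
acceptance script. Both place cells uniformly at density
$5 \times 10^{-3}$ cells/µm² (5,000 cells on a 1 mm² field, ≈ 14 neighbors
within 30 µm for an interior cell).

* **Thresholded sum.** Predictors are i.i.d. $\mathrm{Exp}(10)$ (mean
  0.1). With $S_c$ the sum of gene-1 expression over neighbors within
  $r^\*$ (self excluded), the response is $Y_c = S_c\,\mathbf{1}(S_c > 1) +
  \varepsilon_c$, $\varepsilon_c \sim \mathrm{Exp}(10)$ — noise floor
  $\mathrm{Var}(\varepsilon) = 0.01$. The rate-10 reading of the
  exponential is the only one under which the threshold at 1 is meaningful
  for realistic neighbor counts.
* **Distance-weighted.** Per-gene levels $\mu_g \sim N(20, \sigma = 2)$
  (non-positive draws resampled); expression
  $X_{c,g} \sim \mathrm{NB}(\mathrm{round}(\mu_g), 0.5)/60$ in the
  number-of-failures parameterization — the standard parameterization under
  which $\mathrm{NB}(\mu, 0.5)$ has mean $\mu$. The response sums
  $\sqrt{X_{c',1}}$ over neighbors, weighted by the arcsinh decay
  $1 - \sinh^{-1}(c\,d)/c$ with $c = 5.863$, whose root sits at 30.0 µm —
  that constant *is* the planted radius. The square root follows the
  generator's narrative description (emphasizing weak signals); a config
  switch (`sqrt_contrib`) disables it. Negative weights (possible in the
  last few nm before the root) are clamped to zero.
* **Null.** Response $j$ is the cell's own gene-$j$ expression plus
  exponential noise — no spatial signal at all, for false-positive
  calibration.
* $G = 20$ predictor genes by default, only gene 1 causal; the remaining
  genes are pure distractors (the generators do not state a gene count, so
  a typical curated-panel predictor count was fixed once).

What these generators deliberately do **not** emulate: technical dropout,
segmentation errors, cell-type structure, or the near-regular packing of
real tissue. Passing the benchmark therefore shows that the machinery
detects a planted signal under idealized sampling — not that real-data
rankings are correct.

### Benchmark scale and what the mean-normalized operator can and cannot do

The package's benchmark studies use 5,000 cells as 20 independent tissues
of 250 cells (12/4/4 tissues for train/validation/test), hidden width 64,
at most 50 epochs — sizes chosen so a full radius sweep runs on one CPU in
minutes while keeping ≈ 14 neighbors per interior cell.

One property of the operator deserves emphasis, because the benchmarks
expose it. The convolution *averages* messages ($1/|N(i)|$). Every
aggregated quantity therefore carries an exactly cancelling factor of the
neighbor count, and no stack of mean-aggregated layers can recover
$|N(i)|$ itself. But both planted responses are unnormalized *sums* over
the neighborhood, $Y \approx n_i \cdot \bar m_i$: under uniformly random
positions the count $n_i$ is Poisson-variable, so the best achievable MSE
of any mean-normalized predictor is bounded below by
$E[\bar m^2]\,\mathrm{Var}(n)$, far above the additive-noise floor, and
the $r$-profile acquires a mild dilution penalty at radii beyond the true
one (enlarging the radius divides a correctly gated signal by a larger,
noisier count). In tissue-like, near-regularly packed positions $n_i$ is
almost deterministic given $r$ and the distinction disappears — which is
why degree-blindness goes unnoticed in practice on real data. The
benchmarks on uniform positions show exactly this signature: a strong but
floor-bounded recovery of the thresholded sum
(≈ 32% loss reduction at $r = 30$, stable out to $r = 45$, while the
mean-feature ridge and boosting baselines degrade markedly at 45), and a
distance-weighted profile that improves steeply to $r = 10$ and then
flattens with a small dilution ripple rather than decreasing strictly to
$r^\* = 30$. If recovering unnormalized totals under irregular density is
the goal, a sum-aggregating or degree-augmented variant would be the
remedy; this package keeps the mean-normalized operator as its defined
model.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_cells = 250, extent = c(223.6, 223.6),
                         n_genes = 20, r_star = 30,
                         model = "thresholded_sum", seed = 101)
study <- simulate_study(cfg, n_slices = 20, seed = 101)
cells <- preprocess_cells(study$cells, study$roles)
split <- split_by_group(cells, "slice_id", c(0.6, 0.2, 0.2), seed = 101)
sweep <- radius_sweep(cells, study$roles, split, radii = c(0, 30, 45),
                      model = "spice",
                      cfg = list(hidden = 64, K = 10,
                                 train = train_config(max_epochs = 50)),
                      seed = 101)
rank_genes(sweep, r = 30)
paired_error_test(sweep$errors[["0"]], sweep$errors[["30"]],
                  sweep$clusters, seed = 101)
```

The same pipeline is scripted end to end (simulate → build-graphs → train →
sweep → rank) by the executable in
`system.file("cli", "spice.R", package = "spice")`.

## Known limitations

* Mean aggregation cannot represent neighborhood totals under variable
  local density (discussed above); rankings remain valid as *relative*
  evidence, but absolute recovery of sum-type signals is bounded away from
  the noise floor.
* The hypothesis test is a cluster bootstrap on squared-error differences —
  a pragmatic substitute for a parametric treatment; it needs enough
  held-out tissues to resolve small p-values.
* Loss reductions are predictive, not causal: shared lineage, donor
  effects, or any confounder correlated with space can produce genuine
  predictive gains without intercellular signaling.
* Supported input is delimited text (CSV/TSV) cell tables; HDF5-based
  containers are not read directly.
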