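# spice

**Spatial inference of communication effects from single-cell spatial
transcriptomics, in R.**

Imaging-based spatial transcriptomics (MERFISH, Xenium) measures gene
expression per cell while keeping each cell's position. `spice` uses that
to identify genes whose expression is shaped by cell-cell communication
(CCC): for each response gene it compares a **spatially ignorant**
predictor, which sees only a cell's own ligand/receptor expression
(neighborhood radius *r* = 0), against a **spatially informed** predictor
that also sees every cell within *r* µm. Writing σ̂²<sub>r,g</sub> for the
held-out mean squared error of the radius-*r* model on gene *g*, the
per-gene evidence for spatial regulation is the loss reduction

    LR(g, r) = 100 · (σ̂²₀,g − σ̂²ᵣ,g) / σ̂²₀,g

ranked across genes and tested with a cluster bootstrap on paired per-cell
errors.

The spatially informed model is a graph convolutional network over the
radius-neighborhood graph of each tissue: a Gaussian-mixture-kernel
convolution (each kernel owns a linear map Θₖ and a Gaussian bump (μₖ, Σₖ)
on polar edge descriptors (distance, angle)), three residual hidden blocks
`ReLU(GMMConv(H) + HW)`, and a dense output over all response genes
jointly. Because a fixed neighborhood summary (e.g. the neighbor mean) can
make a spatial model fail for representational rather than biological
reasons, the package also ships the fixed-summary comparison class — ridge,
lasso, elastic net and gradient boosting on mean-aggregated neighborhood
features. The network's forward pass, backpropagation and Adam optimizer
are implemented natively on sparse matrices: no deep-learning runtime is
required, and training is bit-reproducible from a seed.

Also included: strict radius-graph construction with a grid spatial index
(verified against exhaustive search), animal-level and buffered spatial
train/validation/test splitting, semi-synthetic benchmark generators with a
planted interaction radius (30 µm), and a command-line pipeline.

## Worked example

Simulate 20 tissues (250 cells each) in which a single ligand drives the
response of neighbors within 30 µm through a thresholded sum, then sweep
radii and rank genes:

```r
library(spice)

cfg   <- simulation_config(n_cells = 250, extent = c(223.6, 223.6),
                           n_genes = 20, r_star = 30,
                           model = "thresholded_sum", seed = 101)
study <- simulate_study(cfg, n_slices = 20, seed = 101)
cells <- preprocess_cells(study$cells, study$roles)   # log1p on predictors
split <- split_by_group(cells, "slice_id", c(0.6, 0.2, 0.2), seed = 101)

sweep <- radius_sweep(cells, study$roles, split, radii = c(0, 30, 45),
                      model = "spice",
                      cfg = list(hidden = 64, K = 10,
                                 train = train_config(max_epochs = 50)),
                      seed = 101)
sweep
#> sweep_result (spice): 3 radii x 1 genes
#>        gene     mse.0   mse.30    mse.45
#>  response_0 0.6481885 0.436027 0.4696629

rank_genes(sweep, r = 30)
#>         gene    mse_r0    mse_r loss_reduction_pct rank
#> 1 response_0 0.6481885 0.436027           32.73145    1
```

The spatially informed network cuts the held-out error of the planted
response gene by ≈ 33% relative to the spatially ignorant model, and keeps
that performance when handed a broader-than-necessary radius (45 µm) — in
the same setting the mean-feature ridge baseline degrades from 0.431 to
0.507 between r = 30 and r = 45. Uncertainty for a comparison comes from
the paired cluster bootstrap:

```r
paired_error_test(sweep$errors[["0"]], sweep$errors[["30"]],
                  sweep$clusters, seed = 101)
#>         gene mean_diff            p            q
#> 1 response_0 0.2121615 0.0004997501 0.0004997501
```

The same pipeline runs from a shell via the bundled executable:

```sh
Rscript inst/cli/spice.R simulate --model thresholded-sum --n-cells 250 \
    --n-slices 20 --r-true 30 --seed 1 --out sim/
Rscript inst/cli/spice.R sweep --cells sim/cells.csv --roles sim/gene_roles.tsv \
    --radii 0,15,30,45 --model spice --split by-slice --seed 1 --out out/
Rscript inst/cli/spice.R rank --sweep out/ --radius 30 --baseline 0
```

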