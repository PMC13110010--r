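# Shared benchmark fixtures for the heavier end-to-end checks. The planted
# studies use 5,000 cells as 20 independent tissues of 250 cells at a density
# of 0.005 cells/µm^2 (5,000 cells per mm^2, ~14 neighbors within 30 µm),
# split by tissue 12/4/4; networks use hidden width 64, K = 10, at most 50
# epochs (patience 10). Computed lazily and memoized so the radius-robustness
# checks reuse the recovery sweep.

.bench <- new.env(parent = emptyenv())

bench_sweeps <- function(model) {
  key <- paste0("sweep_", model)
  if (!is.null(.bench[[key]])) return(.bench[[key]])
  seed <- if (model == "thresholded_sum") 101 else 202
  radii <- if (model == "thresholded_sum") c(0, 30, 45) else c(0, 10, 20, 30, 45)
  cfg <- simulation_config(n_cells = 250, extent = c(223.6, 223.6),
                           n_genes = 20, r_star = 30, model = model,
                           seed = seed)
  st <- simulate_study(cfg, n_slices = 20, seed = seed)
  cells <- preprocess_cells(st$cells, st$roles)
  split <- split_by_group(cells, "slice_id", c(0.6, 0.2, 0.2), seed = seed)
  spice_sw <- radius_sweep(cells, st$roles, split, radii, model = "spice",
                           cfg = list(hidden = 64, K = 10,
                                      train = train_config(max_epochs = 50,
                                                           patience = 10)),
                           seed = seed)
  ridge_sw <- radius_sweep(cells, st$roles, split, radii, model = "ridge",
                           seed = seed)
  .bench[[key]] <- list(spice = spice_sw, ridge = ridge_sw)
  .bench[[key]]
}

bench_mse <- function(sweep, r) {
  sweep$mse$mse[sweep$mse$radius == r & sweep$mse$gene == "response_0"]
}
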