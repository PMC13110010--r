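# Semi-synthetic benchmark generators with a planted cell-cell-communication
# structure: predictor genes are i.i.d. noise, and a single signal ligand
# (gene 1) drives the response of neighboring cells within a known true
# radius r*. Because the generating mechanism is known, the generators give
# ground truth for testing radius sweeps and gene rankings.

with_seed <- function(seed, expr) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  expr
}

#' Configuration for the semi-synthetic generators
#'
#' @param n_cells number of cells per simulated tissue.
#' @param extent spatial extent in µm, length 2 (or 3 for a 3D tissue).
#' @param positions `"uniform"` (fixed n, uniform in the extent),
#'   `"poisson_process"` (Poisson-distributed n with the same intensity), or
#'   `"external_table"` (caller supplies coordinates).
#' @param n_genes number of predictor (ligand) genes `G`; only gene 1 is
#'   causal, the rest are distractors.
#' @param r_star true interaction radius in µm.
#' @param model `"thresholded_sum"`, `"distance_weighted"`, or `"null"` (a
#'   calibration model whose responses depend only on the cell's own
#'   expression, with no spatial signal).
#' @param noise_rate rate of the exponential observation noise (mean
#'   `1/noise_rate`); also the rate of the i.i.d. predictor expression in the
#'   thresholded-sum model.
#' @param decay_const constant `c` of the arcsinh distance decay
#'   `1 - asinh(c d)/c`, chosen so the weight falls from 1 at contact to 0 at
#'   30 µm.
#' @param nb_mean_mean,nb_mean_sd mean and standard deviation of the normal
#'   prior on per-gene expression levels in the distance-weighted model.
#' @param nb_prob,nb_scale success probability and scale divisor of the
#'   rescaled negative-binomial expression draws.
#' @param sqrt_contrib if `TRUE` (default) each neighbor contributes the
#'   square root of its ligand expression in the distance-weighted model.
#' @param n_null_responses number of own-cell-only response genes in the
#'   `"null"` model.
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 5000, extent = c(1000, 1000),
                              positions = c("uniform", "poisson_process",
                                            "external_table"),
                              n_genes = 20, r_star = 30,
                              model = c("thresholded_sum", "distance_weighted",
                                        "null"),
                              noise_rate = 10, decay_const = 5.863,
                              nb_mean_mean = 20, nb_mean_sd = 2,
                              nb_prob = 0.5, nb_scale = 60,
                              sqrt_contrib = TRUE, n_null_responses = 20,
                              seed = 1) {
  positions <- match.arg(positions)
  model <- match.arg(model)
  stopifnot(n_cells >= 1, n_genes >= 1, r_star > 0, noise_rate > 0,
            decay_const > 0, nb_prob > 0, nb_prob < 1, nb_scale > 0,
            all(extent > 0), length(extent) %in% c(2, 3))
  structure(list(n_cells = n_cells, extent = extent, positions = positions,
                 n_genes = n_genes, signal_gene = 1L, r_star = r_star,
                 model = model, noise_rate = noise_rate,
                 decay_const = decay_const, nb_mean_mean = nb_mean_mean,
                 nb_mean_sd = nb_mean_sd, nb_prob = nb_prob,
                 nb_scale = nb_scale, sqrt_contrib = sqrt_contrib,
                 n_null_responses = n_null_responses, seed = seed),
            class = "simulation_config")
}

#' Sample synthetic cell positions
#'
#' @param cfg a [simulation_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return numeric matrix of positions (µm), one row per cell.
#' @export
sample_positions <- function(cfg, seed = cfg$seed) {
  d <- length(cfg$extent)
  with_seed(seed, {
    n <- switch(cfg$positions,
                uniform = cfg$n_cells,
                poisson_process = stats::rpois(1, cfg$n_cells),
                external_table = spice_error(
                  "positions = 'external_table': supply coordinates directly",
                  "spice_validation_error"))
    m <- matrix(stats::runif(n * d), ncol = d)
    m <- sweep(m, 2, cfg$extent, `*`)
    colnames(m) <- c("x", "y", "z")[seq_len(d)]
    m
  })
}

#' Arcsinh distance-decay weight
#'
#' `1 - asinh(c d) / c`: equals 1 at distance 0 and decreases strictly,
#' crossing 0 near 30 µm for the default constant `c = 5.863`, which is what
#' fixes the planted interaction radius of the distance-weighted generator.
#'
#' @param d distance(s) in µm.
#' @param c decay constant.
#' @return numeric weight(s).
#' @export
#' @examples
#' decay_weight(0)   # 1
#' decay_weight(30)  # ~0
decay_weight <- function(d, c = 5.863) {
  1 - asinh(c * d) / c
}

# neighbor pairs within the true radius (strict, self excluded), both directions
.sim_neighbors <- function(positions, r_star) {
  pairs <- radius_pairs(positions, r_star)
  cbind(i = c(pairs[, 1], pairs[, 2]), j = c(pairs[, 2], pairs[, 1]))
}

.sim_table <- function(positions, X, Y, slice_id) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  resp <- as.data.frame(Y)
  df <- data.frame(cell_id = sprintf("c%06d", seq_len(nrow(positions))),
                   slice_id = slice_id, animal_id = slice_id,
                   as.data.frame(positions), check.names = FALSE)
  colnames(X) <- sprintf("gene_%d", seq_len(ncol(X)))
  cell_table(cbind(df, as.data.frame(X), resp))
}

#' Thresholded-sum simulator
#'
#' Predictor expression is i.i.d. exponential with rate `noise_rate`
#' (default 10, mean 0.1). For each cell the signal `S_c` sums gene-1
#' expression over all neighbors strictly within `r_star` (self excluded),
#' and the response is `S_c 1(S_c > 1) + eps_c` with exponential noise
#' `eps_c` of the same rate: sub-threshold neighborhoods produce pure noise,
#' supra-threshold neighborhoods transmit the full sum.
#'
#' @param positions matrix of cell positions (µm).
#' @param cfg a [simulation_config()].
#' @param seed overrides `cfg$seed`.
#' @param slice_id slice label for the emitted table.
#' @return a [cell_table()] with columns `gene_1..gene_G` and `response_0`.
#' @export
simulate_thresholded_sum <- function(positions, cfg, seed = cfg$seed,
                                     slice_id = "sim_1") {
  n <- nrow(positions)
  with_seed(seed, {
    X <- matrix(stats::rexp(n * cfg$n_genes, rate = cfg$noise_rate), nrow = n)
    edges <- .sim_neighbors(positions, cfg$r_star)
    S <- numeric(n)
    if (nrow(edges) > 0) {
      agg <- rowsum(X[edges[, 2], cfg$signal_gene], group = edges[, 1])
      S[as.integer(rownames(agg))] <- agg[, 1]
    }
    eps <- stats::rexp(n, rate = cfg$noise_rate)
    Y <- ifelse(S > 1, S, 0) + eps
    .sim_table(positions, X, data.frame(response_0 = Y), slice_id)
  })
}

#' Distance-weighted simulator
#'
#' A hierarchical expression model: per-gene levels `mu_g ~ N(20, sd 2)`
#' (redrawn in the unlikely event of a non-positive draw), per-cell counts
#' `NB(round(mu_g), 0.5) / 60` — the number-of-failures parameterization, the
#' one under which the negative binomial has mean `mu_g` before rescaling.
#' The response of a cell is the sum over neighbors within `r_star` of the
#' square root of the neighbor's gene-1 expression, weighted by the arcsinh
#' distance decay [decay_weight()]; neighbors whose weight is not positive
#' contribute nothing.
#'
#' @inheritParams simulate_thresholded_sum
#' @return a [cell_table()] with columns `gene_1..gene_G` and `response_0`.
#' @export
simulate_distance_weighted <- function(positions, cfg, seed = cfg$seed,
                                       slice_id = "sim_1") {
  n <- nrow(positions)
  with_seed(seed, {
    mu <- stats::rnorm(cfg$n_genes, cfg$nb_mean_mean, cfg$nb_mean_sd)
    while (any(mu <= 0)) {
      mu[mu <= 0] <- stats::rnorm(sum(mu <= 0), cfg$nb_mean_mean, cfg$nb_mean_sd)
    }
    X <- sapply(seq_len(cfg$n_genes), function(g) {
      stats::rnbinom(n, size = round(mu[g]), prob = cfg$nb_prob) / cfg$nb_scale
    })
    X <- matrix(X, nrow = n)
    edges <- .sim_neighbors(positions, cfg$r_star)
    Y <- numeric(n)
    if (nrow(edges) > 0) {
      d <- sqrt(rowSums((positions[edges[, 1], , drop = FALSE] -
                           positions[edges[, 2], , drop = FALSE])^2))
      w <- pmax(decay_weight(d, cfg$decay_const), 0)
      contrib <- if (cfg$sqrt_contrib) sqrt(X[edges[, 2], cfg$signal_gene])
                 else X[edges[, 2], cfg$signal_gene]
      agg <- rowsum(contrib * w, group = edges[, 1])
      Y[as.integer(rownames(agg))] <- agg[, 1]
    }
    .sim_table(positions, X, data.frame(response_0 = Y), slice_id)
  })
}

#' Null (own-cell-only) simulator
#'
#' A calibration model with no spatial signal: predictor expression is i.i.d.
#' exponential, and response gene `j` is the cell's own gene-`j` expression
#' plus exponential noise. Any method that reports spatial regulation on this
#' data is reporting a false positive.
#'
#' @inheritParams simulate_thresholded_sum
#' @return a [cell_table()] with `gene_1..gene_G` and
#'   `response_1..response_K` (`K = n_null_responses`, capped at `G`).
#' @export
simulate_null <- function(positions, cfg, seed = cfg$seed, slice_id = "sim_1") {
  n <- nrow(positions)
  k <- min(cfg$n_null_responses, cfg$n_genes)
  with_seed(seed, {
    X <- matrix(stats::rexp(n * cfg$n_genes, rate = cfg$noise_rate), nrow = n)
    eps <- matrix(stats::rexp(n * k, rate = cfg$noise_rate), nrow = n)
    Y <- X[, seq_len(k), drop = FALSE] + eps
    colnames(Y) <- sprintf("response_%d", seq_len(k))
    .sim_table(positions, X, as.data.frame(Y), slice_id)
  })
}

#' Simulate a multi-tissue study
#'
#' Draws `n_slices` independent tissues from the configured generator, each
#' with its own positions and expression, labelled `sim_1..sim_n` with
#' matching `animal_id` so the by-group splitter can hold out whole tissues.
#'
#' @param cfg a [simulation_config()]; `cfg$n_cells` is the cell count per
#'   slice.
#' @param n_slices number of independent tissues.
#' @param seed master seed; per-slice seeds are derived with [derive_seed()].
#' @return list with elements `cells` (combined [cell_table()]), `roles`
#'   (the matching [gene_role_map()]), and `cfg`.
#' @export
simulate_study <- function(cfg, n_slices = 1, seed = cfg$seed) {
  sim_fun <- switch(cfg$model,
                    thresholded_sum = simulate_thresholded_sum,
                    distance_weighted = simulate_distance_weighted,
                    null = simulate_null)
  tabs <- lapply(seq_len(n_slices), function(s) {
    s_seed <- derive_seed(seed, paste0("slice_", s))
    pos <- sample_positions(cfg, seed = derive_seed(s_seed, "positions"))
    sim_fun(pos, cfg, seed = derive_seed(s_seed, "expression"),
            slice_id = sprintf("sim_%d", s))
  })
  cells <- cell_table(do.call(rbind, lapply(tabs, as.data.frame)))
  list(cells = cells, roles = sim_gene_roles(cfg), cfg = cfg)
}

#' @rdname simulate_study
#' @export
sim_gene_roles <- function(cfg) {
  genes <- sprintf("gene_%d", seq_len(cfg$n_genes))
  if (cfg$model == "null") {
    k <- min(cfg$n_null_responses, cfg$n_genes)
    resp <- sprintf("response_%d", seq_len(k))
  } else {
    resp <- "response_0"
  }
  gene_role_map(c(genes, resp),
                c(rep("ligand", length(genes)), rep("response", length(resp))))
}

#' Write a simulated study to disk
#'
#' Emits the cell table (CSV), gene-role map (TSV) and a ground-truth JSON
#' manifest (model, true radius, parameters, seed) into `dir`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param seed the master seed used, recorded in the manifest.
#' @return invisibly, the file paths.
#' @export
write_simulation <- function(study, dir, seed = study$cfg$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- file.path(dir, "cells.csv")
  rp <- file.path(dir, "gene_roles.tsv")
  write_cell_table(study$cells, cp)
  write_gene_roles(study$roles, rp)
  write_manifest(file.path(dir, "ground_truth.json"),
                 config = unclass(study$cfg), seed = seed)
  invisible(c(cells = cp, roles = rp,
              truth = file.path(dir, "ground_truth.json")))
}
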