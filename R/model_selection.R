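# The inference layer: train one predictor per neighborhood radius on the
# same data split, estimate per-gene held-out MSE (sigma^2_{r,g}), convert
# MSE differences against the spatially ignorant r = 0 baseline into
# per-gene loss reductions, and attach uncertainty through a cluster
# bootstrap on paired per-cell squared errors.

#' Per-gene mean squared error
#'
#' @param predictions numeric matrix of predictions, one column per gene.
#' @param targets matching matrix of observed expression.
#' @return named numeric vector: per-gene mean of squared differences over
#'   all cells.
#' @export
evaluate_mse <- function(predictions, targets) {
  predictions <- as.matrix(predictions)
  targets <- as.matrix(targets)
  if (nrow(targets) == 0) spice_error("zero test cells", "spice_validation_error")
  stopifnot(all(dim(predictions) == dim(targets)))
  out <- colMeans((predictions - targets)^2)
  names(out) <- colnames(targets) %||% colnames(predictions)
  out
}

#' Sweep neighborhood radii and estimate per-gene test MSE
#'
#' For every radius, builds tissue graphs on a fixed train/validation/test
#' split, fits the requested predictor (the SPICE network or a
#' pre-aggregated baseline), and records per-gene test MSE together with the
#' per-cell squared errors (for the paired bootstrap test). Using one split
#' for all radii makes the per-radius MSEs paired comparisons.
#'
#' @param cells a preprocessed [cell_table()].
#' @param roles the matching [gene_role_map()].
#' @param split a `data_split`.
#' @param radii numeric vector of radii (µm); include 0 for the spatially
#'   ignorant baseline.
#' @param model `"spice"`, `"ridge"`, `"lasso"`, `"elastic_net"` or
#'   `"boosting"`.
#' @param cfg named list of settings: `hidden`, `K`, `train` (a
#'   [train_config()]) for `"spice"`; `hyperparams` for baselines;
#'   `use_cell_types` for both.
#' @param seed master seed; per-radius seeds are derived from it.
#' @param keep_models keep the fitted model objects in the result.
#' @return a `sweep_result`: `mse` (data.frame gene/radius/mse), `errors`
#'   (per-radius matrices of per-cell squared errors on the test set),
#'   `clusters` (test-cell slice labels, for clustered resampling),
#'   `failed` (named logical), and `models` if requested.
#' @export
radius_sweep <- function(cells, roles, split, radii,
                         model = c("spice", "ridge", "lasso", "elastic_net",
                                   "boosting"),
                         cfg = list(), seed = 1, keep_models = FALSE) {
  model <- match.arg(model)
  radii <- sort(unique(radii))
  if (any(radii < 0)) spice_error("radii must be non-negative", "spice_validation_error")
  use_ct <- isTRUE(cfg$use_cell_types)
  mse_rows <- list()
  errors <- list()
  models <- list()
  failed <- logical(0)
  clusters <- NULL
  for (r in radii) {
    key <- format(r)
    res <- tryCatch({
      ds <- build_dataset(cells, roles, split, r, use_cell_types = use_ct)
      r_seed <- derive_seed(seed, paste0("radius_", key))
      if (model == "spice") {
        net <- gmm_gcn(d_in = length(ds$feature_names),
                       d_out = length(ds$response_names),
                       hidden = cfg$hidden %||% 256, K = cfg$K %||% 10,
                       r = r, edge_dim = ncol(ds$train[[1]]$eattr),
                       seed = r_seed)
        tcfg <- cfg$train %||% train_config()
        tcfg$seed <- derive_seed(r_seed, "train")
        net <- train_gmm_gcn(net, ds$train, ds$validation, tcfg)
        pred <- do.call(rbind, lapply(ds$test, function(g) predict(net, g)))
        fit <- net
      } else {
        agg <- function(gl) .stack_features(
          lapply(gl, aggregate_neighborhood_features,
                 use_cell_types = use_ct, type_levels = ds$type_levels))
        tr <- agg(ds$train); va <- agg(ds$validation); te <- agg(ds$test)
        fit <- fit_baseline(tr$design, tr$Y, kind = model,
                            hyperparams = cfg$hyperparams %||% list(),
                            seed = r_seed,
                            val_features = va$design, val_targets = va$Y)
        pred <- predict(fit, te$design)
      }
      Yte <- do.call(rbind, lapply(ds$test, `[[`, "Y"))
      cl <- unlist(lapply(ds$test, function(g) rep(g$slice_id, g$n)))
      list(pred = pred, Y = Yte, clusters = cl, fit = fit,
           response_names = ds$response_names)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("radius %s failed: %s", key, conditionMessage(res)))
      failed[key] <- TRUE
      next
    }
    failed[key] <- FALSE
    sq <- (res$pred - res$Y)^2
    colnames(sq) <- res$response_names
    errors[[key]] <- sq
    clusters <- res$clusters
    if (keep_models) models[[key]] <- res$fit
    mse_rows[[key]] <- data.frame(gene = res$response_names, radius = r,
                                  mse = colMeans(sq), row.names = NULL)
  }
  if (length(mse_rows) == 0) {
    spice_error("every radius failed", "spice_numeric_error")
  }
  structure(list(radii = radii, model = model,
                 mse = do.call(rbind, c(mse_rows, list(make.row.names = FALSE))),
                 errors = errors, clusters = clusters, failed = failed,
                 models = if (keep_models) models else NULL,
                 seed = seed, cfg = cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result (%s): %d radii x %d genes\n", x$model,
              length(unique(x$mse$radius)), length(unique(x$mse$gene))))
  print(stats::reshape(x$mse, idvar = "gene", timevar = "radius",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}

.sweep_mse <- function(sweep, r) {
  sub <- sweep$mse[sweep$mse$radius == r, ]
  if (nrow(sub) == 0) {
    spice_error(sprintf("radius %g not present in sweep result", r),
                "spice_validation_error")
  }
  stats::setNames(sub$mse, sub$gene)
}

#' Rank genes by loss reduction between two radii
#'
#' The per-gene loss reduction,
#' `100 * (mse(r0, g) - mse(r, g)) / mse(r0, g)`, measures how much better a
#' spatially informed model (radius `r`) predicts gene `g` than the baseline
#' radius `r0` (default 0, the spatially ignorant model). Genes are sorted
#' by descending reduction; ties break alphabetically for determinism.
#'
#' @param sweep a `sweep_result`.
#' @param r spatially informed radius (µm).
#' @param r0 baseline radius (µm), default 0.
#' @return data.frame with columns `gene`, `mse_r0`, `mse_r`,
#'   `loss_reduction_pct`, `rank`.
#' @export
rank_genes <- function(sweep, r, r0 = 0) {
  m0 <- .sweep_mse(sweep, r0)
  mr <- .sweep_mse(sweep, r)[names(m0)]
  red <- 100 * (m0 - mr) / m0
  ord <- order(-red, names(m0))
  data.frame(gene = names(m0)[ord], mse_r0 = unname(m0[ord]),
             mse_r = unname(mr[ord]), loss_reduction_pct = unname(red[ord]),
             rank = seq_along(ord), row.names = NULL)
}

#' Cluster-bootstrap paired test of per-gene error reduction
#'
#' Tests, per gene, the one-sided null that the radius-`r` model is no
#' better than the baseline: `H0: E[d_c] <= 0` with
#' `d_c = err_r0(c) - err_r(c)` the per-cell squared-error difference.
#' Cells within a tissue are dependent, so whole clusters (slices or
#' animals) are resampled with replacement; the p-value is the
#' add-one-corrected fraction of bootstrap replicates in which the mean
#' improvement vanishes (`mean(d*) <= 0`). Benjamini-Hochberg adjustment is
#' applied across genes.
#'
#' @param err_r0,err_r matrices of per-cell squared errors (cells x genes)
#'   for the same test cells under the two radii.
#' @param clusters cluster label per cell (slice or animal).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `mean_diff`, `p`, `q`.
#' @export
paired_error_test <- function(err_r0, err_r, clusters, n_boot = 2000, seed = 1) {
  err_r0 <- as.matrix(err_r0); err_r <- as.matrix(err_r)
  stopifnot(all(dim(err_r0) == dim(err_r)), nrow(err_r0) == length(clusters))
  d <- err_r0 - err_r
  cl <- as.character(clusters)
  ucl <- sort(unique(cl))
  if (length(ucl) < 2) {
    spice_error("need at least 2 clusters for the cluster bootstrap",
                "spice_validation_error")
  }
  idx <- match(cl, ucl)
  S <- rowsum(d, group = idx) # per-cluster sums, clusters x genes
  nc <- tabulate(idx, nbins = length(ucl))
  boot_means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(length(ucl), replace = TRUE)
      colSums(S[take, , drop = FALSE]) / sum(nc[take])
    }, numeric(ncol(d)))
  })
  boot_means <- matrix(boot_means, nrow = ncol(d)) # genes x n_boot
  p <- (1 + rowSums(boot_means <= 0)) / (n_boot + 1)
  genes <- colnames(d) %||% paste0("gene_", seq_len(ncol(d)))
  data.frame(gene = genes, mean_diff = colMeans(d), p = p,
             q = stats::p.adjust(p, method = "BH"), row.names = NULL)
}

#' Write a sweep result to plain-text files
#'
#' Emits `mse.tsv` (gene, radius, mse), `ranking.tsv` for the requested
#' comparison (with bootstrap p/q values when per-cell errors are
#' available), and `manifest.json`.
#'
#' @param sweep a `sweep_result`.
#' @param dir output directory.
#' @param r,r0 radii compared in the ranking (defaults: largest radius vs 0).
#' @param n_boot bootstrap replicates for the paired test; 0 disables it.
#' @return invisibly, the output paths.
#' @export
write_sweep_result <- function(sweep, dir, r = max(sweep$radii), r0 = 0,
                               n_boot = 2000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(dir, "mse.tsv")
  utils::write.table(sweep$mse, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  rk <- rank_genes(sweep, r, r0)
  if (n_boot > 0 && !is.null(sweep$errors[[format(r)]]) &&
      !is.null(sweep$errors[[format(r0)]]) &&
      length(unique(sweep$clusters)) >= 2) {
    tst <- paired_error_test(sweep$errors[[format(r0)]],
                             sweep$errors[[format(r)]],
                             sweep$clusters, n_boot = n_boot,
                             seed = derive_seed(sweep$seed, "paired_test"))
    rk <- merge(rk, tst[, c("gene", "p", "q")], by = "gene", sort = FALSE)
    rk <- rk[order(rk$rank), ]
  }
  rp <- file.path(dir, "ranking.tsv")
  utils::write.table(rk, rp, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(file.path(dir, "manifest.json"),
                 config = list(model = sweep$model, radii = sweep$radii,
                               compare = c(r = r, r0 = r0),
                               failed = as.list(sweep$failed)),
                 seed = sweep$seed)
  invisible(c(mse = mp, ranking = rp))
}
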