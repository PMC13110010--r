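# Pre-aggregated baseline predictors: the comparison class whose neighborhood
# representation is fixed a priori — each cell is described by its own
# ligand/receptor expression, the arithmetic mean of its neighbors'
# expression, and (optionally) the cell-type composition of its
# neighborhood. The regressors on top (ridge, lasso, elastic net, gradient
# boosting) are standard; their limitation is the featurization, which is
# exactly the point of comparing them against the graph network.

#' Aggregate neighborhood features for baseline regressors
#'
#' For every cell: its own node features, the mean of its neighbors' node
#' features (zero-filled for isolated cells), the neighbor count, and —
#' when `use_cell_types` is set and the graph carries cell-type labels —
#' the neighborhood cell-type proportions (summing to 1 for cells with
#' neighbors, all-zero otherwise).
#'
#' @param graph a `tissue_graph` with a feature matrix.
#' @param use_cell_types append neighborhood cell-type proportion columns.
#' @param type_levels category levels for the proportion columns; defaults
#'   to the levels present in the graph.
#' @return an `aggregated_features` object: list with `design` (numeric
#'   matrix of predictors), `n_neighbors`, `cell_id`, `slice_id`, and the
#'   target matrix `Y` carried over from the graph.
#' @export
aggregate_neighborhood_features <- function(graph, use_cell_types = FALSE,
                                            type_levels = NULL) {
  stopifnot(inherits(graph, "tissue_graph"))
  if (is.null(graph$X)) {
    spice_error("graph has no feature matrix; build it with a gene-role map",
                "spice_validation_error")
  }
  n <- graph$n
  X <- graph$X
  deg <- graph$deg
  nbr <- matrix(0, n, ncol(X))
  if (nrow(graph$edges) > 0) {
    agg <- rowsum(X[graph$edges[, 2], , drop = FALSE], group = graph$edges[, 1])
    idx <- as.integer(rownames(agg))
    nbr[idx, ] <- agg / deg[idx]
  }
  colnames(nbr) <- paste0("nbr_", colnames(X))
  design <- cbind(X, nbr)
  if (use_cell_types) {
    if (is.null(graph$cell_type)) {
      spice_error("use_cell_types = TRUE but the graph has no cell-type labels",
                  "spice_schema_error")
    }
    lv <- type_levels %||% sort(unique(graph$cell_type))
    onehot <- matrix(0, n, length(lv))
    hit <- match(graph$cell_type, lv)
    ok <- !is.na(hit)
    onehot[cbind(which(ok), hit[ok])] <- 1
    prop <- matrix(0, n, length(lv),
                   dimnames = list(NULL, paste0("nbrprop_", lv)))
    if (nrow(graph$edges) > 0) {
      agg <- rowsum(onehot[graph$edges[, 2], , drop = FALSE],
                    group = graph$edges[, 1])
      idx <- as.integer(rownames(agg))
      prop[idx, ] <- agg / deg[idx]
    }
    design <- cbind(design, prop)
  }
  structure(list(design = design, n_neighbors = deg, cell_id = graph$cell_id,
                 slice_id = rep(graph$slice_id, n), Y = graph$Y,
                 response_names = graph$response_names),
            class = "aggregated_features")
}

# stack aggregated tables from several graphs into one design/target pair
.stack_features <- function(feature_list) {
  list(design = do.call(rbind, lapply(feature_list, `[[`, "design")),
       Y = do.call(rbind, lapply(feature_list, `[[`, "Y")),
       slice_id = unlist(lapply(feature_list, `[[`, "slice_id")),
       response_names = feature_list[[1]]$response_names)
}

#' Fit a baseline regressor on aggregated features
#'
#' Linear kinds (`ridge`, `lasso`, `elastic_net`) are penalized multi-response
#' linear models fit with `glmnet`; the penalty is chosen on the validation
#' set when one is supplied, otherwise taken from `hyperparams$lambda`.
#' `boosting` fits one gradient-boosted tree model per response gene
#' (requires the `xgboost` package).
#'
#' @param features design matrix, or an `aggregated_features` object.
#' @param targets response matrix (one column per gene); taken from
#'   `features$Y` when omitted and available.
#' @param kind one of `"ridge"`, `"lasso"`, `"elastic_net"`, `"boosting"`.
#' @param hyperparams named list: `lambda` (linear kinds), `nrounds`,
#'   `max_depth`, `eta` (boosting).
#' @param seed integer seed (boosting row subsampling and any internal
#'   randomness).
#' @param val_features,val_targets optional validation design/targets for
#'   penalty or round selection.
#' @return a `spice_baseline` model with a `predict` method.
#' @export
fit_baseline <- function(features, targets = NULL,
                         kind = c("ridge", "lasso", "elastic_net", "boosting"),
                         hyperparams = list(), seed = 1,
                         val_features = NULL, val_targets = NULL) {
  kind <- match.arg(kind)
  if (inherits(features, "aggregated_features")) {
    targets <- targets %||% features$Y
    features <- features$design
  }
  if (inherits(val_features, "aggregated_features")) {
    val_targets <- val_targets %||% val_features$Y
    val_features <- val_features$design
  }
  x <- as.matrix(features)
  y <- as.matrix(targets)
  stopifnot(nrow(x) == nrow(y))
  if (all(apply(x, 2, stats::var) == 0)) {
    spice_error("degenerate design: every feature column is constant",
                "spice_validation_error")
  }
  if (kind == "boosting") {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      spice_error("kind = 'boosting' requires the xgboost package",
                  "spice_dependency_error")
    }
    nrounds <- hyperparams$nrounds %||% 200
    fits <- lapply(seq_len(ncol(y)), function(g) {
      with_seed(derive_seed(seed, paste0("xgb_", g)), {
        pars <- list(objective = "reg:squarederror",
                     max_depth = hyperparams$max_depth %||% 6,
                     eta = hyperparams$eta %||% 0.1, nthread = 1)
        if (!is.null(val_features)) {
          xgboost::xgb.train(pars,
                             xgboost::xgb.DMatrix(x, label = y[, g]),
                             nrounds = nrounds,
                             evals = list(val = xgboost::xgb.DMatrix(
                               as.matrix(val_features), label = val_targets[, g])),
                             early_stopping_rounds = 10, verbose = 0)
        } else {
          xgboost::xgb.train(pars, xgboost::xgb.DMatrix(x, label = y[, g]),
                             nrounds = nrounds, verbose = 0)
        }
      })
    })
    model <- list(kind = kind, fits = fits)
  } else {
    alpha <- switch(kind, ridge = 0, lasso = 1, elastic_net = 0.5)
    lambda <- hyperparams$lambda
    fam <- if (ncol(y) == 1) "gaussian" else "mgaussian"
    fit <- glmnet::glmnet(x, if (ncol(y) == 1) y[, 1] else y, family = fam,
                          alpha = alpha, standardize = TRUE, thresh = 1e-10,
                          lambda = if (!is.null(lambda) && length(lambda) == 1)
                            sort(unique(c(lambda, max(lambda, 1e-3) * c(2, 4, 8))),
                                 decreasing = TRUE) else lambda)
    if (!is.null(val_features)) {
      pred <- predict(fit, as.matrix(val_features)) # n x (G x) n_lambda
      yv <- as.matrix(val_targets)
      mses <- if (length(dim(pred)) == 3) {
        apply(pred, 3, function(p) mean((p - yv)^2))
      } else {
        colMeans((pred - yv[, 1])^2)
      }
      lambda <- fit$lambda[which.min(mses)]
    } else {
      lambda <- lambda %||% min(fit$lambda)
    }
    model <- list(kind = kind, fit = fit, lambda = lambda)
  }
  model$feature_names <- colnames(x)
  model$response_names <- colnames(y)
  structure(model, class = "spice_baseline")
}

#' @export
predict.spice_baseline <- function(object, features, ...) {
  if (inherits(features, "aggregated_features")) features <- features$design
  x <- as.matrix(features)
  if (object$kind == "boosting") {
    pred <- sapply(object$fits, function(f) {
      stats::predict(f, xgboost::xgb.DMatrix(x))
    })
    pred <- matrix(pred, nrow = nrow(x))
  } else {
    pred <- predict(object$fit, x, s = object$lambda)
    pred <- matrix(pred, nrow = nrow(x))
  }
  colnames(pred) <- object$response_names
  pred
}

#' Per-gene mean squared error of a baseline model
#'
#' @param model a `spice_baseline`.
#' @param features design matrix or `aggregated_features`.
#' @param targets response matrix; taken from `features$Y` when omitted.
#' @return named numeric vector of per-gene MSEs.
#' @export
evaluate_baseline <- function(model, features, targets = NULL) {
  if (inherits(features, "aggregated_features")) {
    targets <- targets %||% features$Y
  }
  pred <- predict(model, features)
  evaluate_mse(pred, as.matrix(targets))
}
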