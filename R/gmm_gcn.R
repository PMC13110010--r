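# The spatially informed predictor: a graph convolutional network whose
# message passing uses a Gaussian-mixture kernel over polar edge attributes.
# Each of K kernels carries a linear map Theta_k plus a Gaussian bump
# (mu_k, diagonal Sigma_k) on edge-attribute space; a neighbor j contributes
# Theta_k x_j weighted by how close the displacement descriptor e_ij lies to
# the kernel's center. Messages are averaged over the neighborhood and over
# kernels, so an isolated node receives a zero message and the r = 0 network
# collapses exactly to a per-cell dense network.
#
# Forward, backpropagation and the Adam optimizer are implemented directly
# on base matrices and Matrix sparse operators.

#' Gaussian kernel weight on edge-attribute space
#'
#' Evaluates `exp(-1/2 (e - mu)' Sigma^-1 (e - mu))` for one kernel with
#' diagonal covariance: 1 exactly at the kernel center, decaying with
#' Mahalanobis distance.
#'
#' @param e numeric edge-attribute vector (e.g. `(distance, angle)`).
#' @param mu kernel mean vector, same length as `e`.
#' @param sigma2 diagonal of the kernel covariance; all entries must be
#'   strictly positive.
#' @return a scalar in `(0, 1]`.
#' @export
#' @examples
#' kernel_weight(c(1, 0), c(0, 0), c(1, 1)) # exp(-0.5)
kernel_weight <- function(e, mu, sigma2) {
  stopifnot(length(e) == length(mu), length(mu) == length(sigma2))
  if (any(sigma2 <= 0)) {
    spice_error("kernel covariance must be positive definite (all sigma2 > 0)",
                "spice_validation_error")
  }
  exp(-0.5 * sum((e - mu)^2 / sigma2))
}

# E x K matrix of kernel weights for all edges
.kernel_weights <- function(eattr, mu, logvar) {
  K <- nrow(mu)
  w <- matrix(0, nrow(eattr), K)
  for (k in seq_len(K)) {
    diff2 <- sweep(eattr, 2, mu[k, ])^2
    w[, k] <- exp(-0.5 * as.vector(diff2 %*% (1 / exp(logvar[k, ]))))
  }
  w
}

#' Gaussian-mixture graph convolution
#'
#' Computes, for every node `i`,
#' `(1/|N(i)|) sum_{j in N(i)} (1/K) sum_k w_k(e_ij) Theta_k x_j`,
#' the neighborhood average of kernel-weighted linear transforms of neighbor
#' features. Nodes without neighbors receive the zero vector.
#'
#' @param H node feature matrix, one row per node.
#' @param edges 2-column integer matrix of directed edges `(i, j)`: node `i`
#'   receives from neighbor `j`.
#' @param eattr edge-attribute matrix, one row per edge.
#' @param kernels list of `K` kernels, each a list with elements `Theta`
#'   (`d_out x d_in`), `mu` and `sigma2` (length = edge-attribute dimension).
#' @return transformed node feature matrix (`nrow(H) x d_out`).
#' @export
gmm_conv <- function(H, edges, eattr, kernels) {
  n <- nrow(H)
  K <- length(kernels)
  d_out <- nrow(kernels[[1]]$Theta)
  if (nrow(edges) > 0 && max(edges) > n) {
    spice_error("edge list references a node beyond the feature matrix",
                "spice_validation_error")
  }
  out <- matrix(0, n, d_out)
  if (nrow(edges) == 0) return(out)
  deg <- tabulate(edges[, 1], nbins = n)
  for (k in seq_len(K)) {
    kk <- kernels[[k]]
    if (any(kk$sigma2 <= 0)) {
      spice_error("kernel covariance must be positive definite", "spice_validation_error")
    }
    diff2 <- sweep(eattr, 2, kk$mu)^2
    w <- exp(-0.5 * as.vector(diff2 %*% (1 / kk$sigma2)))
    msg <- w * (H[edges[, 2], , drop = FALSE] %*% t(kk$Theta))
    agg <- rowsum(msg, group = edges[, 1])
    out[as.integer(rownames(agg)), ] <- out[as.integer(rownames(agg)), ] + agg
  }
  scale <- ifelse(deg > 0, 1 / (K * deg), 0)
  out * scale
}

#' Construct an untrained SPICE network
#'
#' Three hidden blocks, each the ReLU of a GMM graph convolution plus a dense
#' (residual) transform of the previous layer, followed by a plain dense
#' output layer mapping to the response genes.
#'
#' Initialization: `Theta` and dense weights use fan-in-scaled uniform draws;
#' kernel centers spread the distance component uniformly over `[0, r]` and
#' the angular components over `(-pi, pi]`; kernel log-variances start at the
#' squared half-radius (distance) and `pi^2` (angles) so that, at
#' initialization, kernels cover the whole range of realizable edge
#' attributes rather than isolated slivers of it.
#'
#' @param d_in number of node features (predictor genes + one-hot columns).
#' @param d_out number of response genes.
#' @param hidden width of the three hidden layers.
#' @param K number of Gaussian kernels per convolution.
#' @param r neighborhood radius (µm) the network is built for; used to scale
#'   kernel initialization.
#' @param edge_dim edge-attribute dimension (2 polar, 3 spherical).
#' @param seed integer seed fixing the initialization.
#' @return a `gmm_gcn` model object.
#' @export
gmm_gcn <- function(d_in, d_out, hidden = 256, K = 10, r = 0, edge_dim = 2,
                    seed = 1) {
  stopifnot(d_in >= 1, d_out >= 1, hidden >= 1, K >= 1, edge_dim %in% 2:3)
  dims <- c(d_in, hidden, hidden, hidden)
  rr <- max(r, 1) # keep the r = 0 model initializable
  params <- with_seed(seed, {
    layers <- lapply(1:3, function(l) {
      fi <- dims[l]; fo <- dims[l + 1]
      s <- 1 / sqrt(fi)
      lv <- c(log((rr / 2)^2), rep(log(pi^2), edge_dim - 1))
      list(Theta = matrix(stats::runif(K * fo * fi, -s, s), K * fo, fi),
           mu = cbind(stats::runif(K, 0, rr),
                      matrix(stats::runif(K * (edge_dim - 1), -pi, pi), K)),
           logvar = matrix(rep(lv, each = K), K, edge_dim),
           W = matrix(stats::runif(fi * fo, -s, s), fi, fo),
           b = numeric(fo))
    })
    s <- 1 / sqrt(hidden)
    list(layers = layers,
         out = list(W = matrix(stats::runif(hidden * d_out, -s, s), hidden, d_out),
                    b = numeric(d_out)))
  })
  structure(list(d_in = d_in, d_out = d_out, hidden = hidden, K = K, r = r,
                 edge_dim = edge_dim, seed = seed, params = params,
                 feature_names = NULL, response_names = NULL),
            class = "gmm_gcn")
}

#' @export
print.gmm_gcn <- function(x, ...) {
  cat(sprintf("gmm_gcn: %d -> %d/%d/%d -> %d, K = %d kernels, r = %g µm\n",
              x$d_in, x$hidden, x$hidden, x$hidden, x$d_out, x$K, x$r))
  invisible(x)
}

#' Training configuration for the SPICE network
#'
#' @param lr Adam learning rate.
#' @param patience number of epochs without validation improvement before
#'   early stopping.
#' @param max_epochs hard epoch cap.
#' @param graphs_per_step number of tissue graphs whose gradients are
#'   averaged per optimizer step.
#' @param seed integer seed controlling the per-epoch graph order.
#' @param init_output_bias `"target_mean"` (start the output bias at the
#'   per-gene training mean, the regression analogue of an intercept-only
#'   warm start) or `"zero"`.
#' @param verbose print per-epoch losses.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, patience = 10, max_epochs = 100,
                         graphs_per_step = 1, seed = 1,
                         init_output_bias = c("target_mean", "zero"),
                         verbose = FALSE) {
  stopifnot(lr > 0, patience >= 1, max_epochs >= 1, graphs_per_step >= 1)
  list(lr = lr, patience = patience, max_epochs = max_epochs,
       graphs_per_step = graphs_per_step, seed = seed,
       init_output_bias = match.arg(init_output_bias), verbose = verbose)
}

# --- internal: per-graph sparse templates -----------------------------------

# Precompute block-sparse CSC templates so each layer's K kernel-weighted
# adjacencies are applied in a single sparse product: the forward template
# is the n x (K n) block row [A_1 ... A_K], the backward template its
# transpose, and ordA/ordT map the (kernel-major) edge-weight vector into
# the templates' internal CSC slot order.
.graph_cache <- function(graph, K) {
  E <- nrow(graph$edges)
  n <- graph$n
  cache <- list(E = E, n = n, edges = graph$edges, eattr = graph$eattr,
                X = graph$X, Y = graph$Y)
  if (E > 0) {
    ii <- rep(graph$edges[, 1], K)
    jj <- rep(graph$edges[, 2], K) + n * rep(0:(K - 1), each = E)
    A0 <- Matrix::sparseMatrix(i = ii, j = jj, x = seq_len(K * E),
                               dims = c(n, K * n))
    T0 <- Matrix::sparseMatrix(i = jj, j = ii, x = seq_len(K * E),
                               dims = c(K * n, n))
    cache$A <- A0; cache$ordA <- as.integer(A0@x)
    cache$Tm <- T0; cache$ordT <- as.integer(T0@x)
    deg <- tabulate(graph$edges[, 1], nbins = n)
    cache$invdegK <- ifelse(deg > 0, 1 / (K * deg), 0)
  }
  cache
}

# Forward pass through the full network. Returns predictions and, when
# keep = TRUE, the intermediate quantities needed by the backward pass.
.forward <- function(params, cache, K, keep = FALSE) {
  H <- cache$X
  E <- cache$E
  n <- cache$n
  acts <- vector("list", 3)
  for (l in 1:3) {
    p <- params$layers[[l]]
    d_out <- ncol(p$W)
    if (E > 0) {
      w <- .kernel_weights(cache$eattr, p$mu, p$logvar)
      B <- H %*% t(p$Theta) # n x (K * d_out), kernel blocks side by side
      Bstack <- matrix(0, K * n, d_out) # kernel blocks stacked vertically
      for (k in seq_len(K)) {
        Bstack[((k - 1) * n + 1):(k * n), ] <-
          B[, ((k - 1) * d_out + 1):(k * d_out)]
      }
      A <- cache$A
      A@x <- as.vector(w)[cache$ordA]
      M <- as.matrix(A %*% Bstack) * cache$invdegK
    } else {
      w <- NULL; Bstack <- NULL
      M <- matrix(0, n, d_out)
    }
    Z <- M + H %*% p$W
    Z <- sweep(Z, 2, p$b, `+`)
    Hout <- pmax(Z, 0)
    if (keep) acts[[l]] <- list(H_in = H, w = w, B = if (E > 0) B else NULL,
                                mask = Z > 0)
    H <- Hout
  }
  pred <- sweep(H %*% params$out$W, 2, params$out$b, `+`)
  if (keep) list(pred = pred, H3 = H, acts = acts) else list(pred = pred)
}

# Backward pass: gradient of mean squared error over all cells x genes.
.backward <- function(params, cache, K, fw) {
  n <- cache$n
  E <- cache$E
  resid <- fw$pred - cache$Y
  loss <- mean(resid^2)
  dpred <- 2 * resid / length(resid)
  g_out <- list(W = crossprod(fw$H3, dpred), b = colSums(dpred))
  dH <- dpred %*% t(params$out$W)
  g_layers <- vector("list", 3)
  for (l in 3:1) {
    p <- params$layers[[l]]
    a <- fw$acts[[l]]
    d_out <- ncol(p$W)
    dZ <- dH * a$mask
    g <- list(Theta = matrix(0, nrow(p$Theta), ncol(p$Theta)),
              mu = matrix(0, nrow(p$mu), ncol(p$mu)),
              logvar = matrix(0, nrow(p$logvar), ncol(p$logvar)),
              W = crossprod(a$H_in, dZ), b = colSums(dZ))
    dH <- dZ %*% t(p$W)
    if (E > 0) {
      C <- dZ * cache$invdegK
      Tm <- cache$Tm
      Tm@x <- as.vector(a$w)[cache$ordT]
      dBstack <- as.matrix(Tm %*% C) # (K n) x d_out
      ii <- cache$edges[, 1]; jj <- cache$edges[, 2]
      CE <- C[ii, , drop = FALSE]
      # dL/dw for all edges and kernels in one BLAS call: row-wise dot
      # products of CE with each kernel block of B[jj, ] via a 0/1
      # block-summing matrix
      blocksum <- kronecker(diag(K), matrix(1, d_out, 1))
      ge_all <- (a$B[jj, , drop = FALSE] *
                   CE[, rep.int(seq_len(d_out), K), drop = FALSE]) %*% blocksum
      gw_all <- ge_all * a$w # E x K
      for (k in seq_len(K)) {
        cols <- ((k - 1) * d_out + 1):(k * d_out)
        rows <- ((k - 1) * n + 1):(k * n)
        dBk <- dBstack[rows, , drop = FALSE]
        g$Theta[cols, ] <- crossprod(dBk, a$H_in)
        dH <- dH + dBk %*% p$Theta[cols, , drop = FALSE]
        diff <- sweep(cache$eattr, 2, p$mu[k, ])
        s2 <- exp(p$logvar[k, ])
        g$mu[k, ] <- .colSums(gw_all[, k] * diff, E, ncol(diff)) / s2
        g$logvar[k, ] <- 0.5 * .colSums(gw_all[, k] * diff^2, E, ncol(diff)) / s2
      }
    }
    g_layers[[l]] <- g
  }
  list(loss = loss, grads = list(layers = g_layers, out = g_out))
}

# elementwise recursion over mirrored nested lists of numeric leaves
.map_leaves <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- args[[1]]
    for (nm in seq_along(out)) {
      out[[nm]] <- do.call(.map_leaves, c(list(f), lapply(args, `[[`, nm)))
    }
    out
  } else {
    do.call(f, args)
  }
}

.zeros_like <- function(p) .map_leaves(function(x) x * 0, p)

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- .map_leaves(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .map_leaves(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 / (1 - beta1^t)
  c2 <- 1 / (1 - beta2^t)
  params <- .map_leaves(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                        params, state$m, state$v)
  list(params = params, state = state)
}

# pooled MSE over a list of graphs (mean over all cells and genes)
.pooled_mse <- function(params, caches, K) {
  se <- 0; nobs <- 0
  for (cc in caches) {
    pred <- .forward(params, cc, K)$pred
    se <- se + sum((pred - cc$Y)^2)
    nobs <- nobs + length(cc$Y)
  }
  se / nobs
}

#' Train a SPICE network with Adam and early stopping
#'
#' Minimizes the mean squared error over all response genes jointly, taking
#' one optimizer step per `graphs_per_step` training graphs, evaluating the
#' pooled validation MSE after every epoch, and returning the parameters
#' from the best validation epoch. Training stops after `patience` epochs
#' without validation improvement, or at `max_epochs`. The run is
#' deterministic given the seeds.
#'
#' @param model a [gmm_gcn()] (or `NULL` to build one from the graphs with
#'   `hidden`/`K` defaults).
#' @param train_graphs,val_graphs lists of `tissue_graph` objects sharing
#'   one feature/response schema.
#' @param cfg a [train_config()].
#' @return the trained `gmm_gcn`, with a `log` data.frame (epoch, train MSE,
#'   validation MSE) and `best_epoch` attached.
#' @export
train_gmm_gcn <- function(model, train_graphs, val_graphs, cfg = train_config()) {
  stopifnot(length(train_graphs) >= 1, length(val_graphs) >= 1)
  d_in <- ncol(train_graphs[[1]]$X)
  d_out <- ncol(train_graphs[[1]]$Y)
  if (is.null(model)) {
    model <- gmm_gcn(d_in, d_out, r = train_graphs[[1]]$r,
                     edge_dim = ncol(train_graphs[[1]]$eattr), seed = cfg$seed)
  }
  if (model$d_in != d_in) {
    spice_error(sprintf("model expects %d features, graphs carry %d (layer 1)",
                        model$d_in, d_in), "spice_schema_error")
  }
  if (model$d_out != d_out) {
    spice_error(sprintf("model predicts %d responses, graphs carry %d (output layer)",
                        model$d_out, d_out), "spice_schema_error")
  }
  K <- model$K
  tr <- lapply(train_graphs, .graph_cache, K = K)
  va <- lapply(val_graphs, .graph_cache, K = K)
  params <- model$params
  if (cfg$init_output_bias == "target_mean") {
    Yall <- do.call(rbind, lapply(tr, `[[`, "Y"))
    params$out$b <- colMeans(Yall)
  }
  state <- list(m = .zeros_like(params), v = .zeros_like(params))
  best <- list(params = params, val = .pooled_mse(params, va, K), epoch = 0L)
  log <- data.frame(epoch = 0L, train_mse = NA_real_, val_mse = best$val)
  wait <- 0L
  t_adam <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch_", epoch)),
                     sample.int(length(tr)))
    step_losses <- numeric(0)
    acc <- NULL; acc_n <- 0L
    for (gi in ord) {
      cc <- tr[[gi]]
      fw <- .forward(params, cc, K, keep = TRUE)
      bw <- .backward(params, cc, K, fw)
      if (!is.finite(bw$loss)) {
        spice_error(sprintf("non-finite training loss at epoch %d", epoch),
                    "spice_numeric_error")
      }
      step_losses <- c(step_losses, bw$loss)
      acc <- if (is.null(acc)) bw$grads else .map_leaves(`+`, acc, bw$grads)
      acc_n <- acc_n + 1L
      if (acc_n == cfg$graphs_per_step || gi == ord[length(ord)]) {
        grads <- .map_leaves(function(g) g / acc_n, acc)
        t_adam <- t_adam + 1L
        upd <- .adam_step(params, grads, state, cfg$lr, t_adam)
        params <- upd$params; state <- upd$state
        acc <- NULL; acc_n <- 0L
      }
    }
    val <- .pooled_mse(params, va, K)
    log <- rbind(log, data.frame(epoch = epoch, train_mse = mean(step_losses),
                                 val_mse = val))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(step_losses), val))
    }
    if (val < best$val) {
      best <- list(params = params, val = val, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$feature_names <- train_graphs[[1]]$feature_names
  model$response_names <- train_graphs[[1]]$response_names
  model$log <- log
  model$best_epoch <- best$epoch
  model
}

#' Predict response expression for a tissue graph
#'
#' @param object a trained [gmm_gcn()].
#' @param graph a `tissue_graph` with the same feature schema.
#' @param ... unused.
#' @return prediction matrix, one row per cell, one column per response gene.
#' @export
predict.gmm_gcn <- function(object, graph, ...) {
  if (ncol(graph$X) != object$d_in) {
    spice_error(sprintf("graph carries %d features but model expects %d",
                        ncol(graph$X), object$d_in), "spice_schema_error")
  }
  cc <- .graph_cache(graph, object$K)
  pred <- .forward(object$params, cc, object$K)$pred
  colnames(pred) <- object$response_names %||% graph$response_names
  pred
}

#' Save / load a SPICE model
#'
#' `save_model` writes the parameter blob (`<stem>.rds`) plus a JSON sidecar
#' with the architecture and schema; `load_model` restores a model whose
#' predictions are identical to the saved one.
#'
#' @param model a `gmm_gcn`.
#' @param stem path stem (without extension).
#' @return `save_model` the paths, invisibly; `load_model` the model.
#' @export
save_model <- function(model, stem) {
  saveRDS(model$params, paste0(stem, ".rds"))
  meta <- model[c("d_in", "d_out", "hidden", "K", "r", "edge_dim", "seed",
                  "feature_names", "response_names", "best_epoch")]
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(params = paste0(stem, ".rds"), meta = paste0(stem, ".json")))
}

#' @rdname save_model
#' @export
load_model <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  model <- gmm_gcn(meta$d_in, meta$d_out, hidden = meta$hidden, K = meta$K,
                   r = meta$r, edge_dim = meta$edge_dim, seed = meta$seed)
  model$params <- readRDS(paste0(stem, ".rds"))
  model$feature_names <- meta$feature_names
  model$response_names <- meta$response_names
  model$best_epoch <- meta$best_epoch
  model
}
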