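# Independent reference implementations (deliberately naive) and small
# fixture builders used across the suite.

# O(n^2) brute-force radius neighbors: unordered pairs with 0 < d < r
brute_pairs <- function(coords, r) {
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2 || r <= 0) return(out)
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      d2 <- sum((coords[a, ] - coords[b, ])^2)
      if (d2 > 0 && d2 < r^2) out <- rbind(out, c(a, b))
    }
  }
  out
}

# explicit double-loop evaluation of the mixture-kernel convolution
naive_gmm_conv <- function(H, edges, eattr, kernels) {
  n <- nrow(H)
  K <- length(kernels)
  d_out <- nrow(kernels[[1]]$Theta)
  out <- matrix(0, n, d_out)
  for (i in seq_len(n)) {
    rows <- which(edges[, 1] == i)
    if (length(rows) == 0) next
    acc <- numeric(d_out)
    for (rr in rows) {
      j <- edges[rr, 2]
      e <- eattr[rr, ]
      for (k in seq_len(K)) {
        kk <- kernels[[k]]
        w <- exp(-0.5 * sum((e - kk$mu)^2 / kk$sigma2))
        acc <- acc + as.vector(w * (kk$Theta %*% H[j, ])) / K
      }
    }
    out[i, ] <- acc / length(rows)
  }
  out
}

# random planar cell table with g predictor-like gene columns
rand_cells <- function(n, g = 2, extent = 100, seed = 1, slice_id = "s1") {
  withr::with_seed(seed, {
    df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                     slice_id = slice_id,
                     x = runif(n, 0, extent), y = runif(n, 0, extent))
    for (k in seq_len(g)) df[[paste0("gene_", k)]] <- rexp(n, 10)
    cell_table(df)
  })
}

rand_kernels <- function(K, d_in, d_out, edge_dim = 2, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(K), function(k) {
      list(Theta = matrix(rnorm(d_out * d_in), d_out, d_in),
           mu = c(runif(1, 0, 10), runif(edge_dim - 1, -pi, pi)),
           sigma2 = runif(edge_dim, 0.5, 20))
    })
  })
}

# graphs for a toy supervised task: response = chosen function of own genes
toy_graph <- function(n, fun, r = 0, g = 2, seed = 1, slice_id = "s1",
                      extent = 1000) {
  cells <- rand_cells(n, g = g, extent = extent, seed = seed,
                      slice_id = slice_id)
  df <- as.data.frame(cells)
  df$response_0 <- fun(df)
  roles <- gene_role_map(c(paste0("gene_", seq_len(g)), "response_0"),
                         c(rep("ligand", g), "response"))
  ct <- preprocess_cells(cell_table(df), roles)
  build_radius_graph(ct, r, roles = roles)
}
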