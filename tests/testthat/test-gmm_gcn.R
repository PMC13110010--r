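test_that("kernel weights follow the Gaussian closed form", {
  expect_equal(kernel_weight(c(2, 1), c(2, 1), c(1, 1)), 1) # at the center
  expect_equal(kernel_weight(c(1, 0), c(0, 0), c(1, 1)), exp(-0.5))
  expect_equal(kernel_weight(c(2, 0), c(0, 0), c(4, 1)), exp(-0.5))
  expect_lt(kernel_weight(c(5, 0), c(0, 0), c(1, 1)), 1e-5)
  expect_error(kernel_weight(c(1, 0), c(0, 0), c(1, 0)),
               class = "spice_validation_error")
})

test_that("the vectorized convolution matches the explicit double loop", {
  for (s in 1:25) {
    n <- sample(2:10, 1)
    K <- sample(1:3, 1)
    d_in <- sample(1:4, 1)
    d_out <- sample(1:4, 1)
    ct <- rand_cells(n, seed = s, extent = 15)
    g <- build_radius_graph(ct, r = sample(c(4, 8, 20), 1))
    H <- withr::with_seed(1000 + s, matrix(rnorm(n * d_in), n))
    kernels <- rand_kernels(K, d_in, d_out, seed = 2000 + s)
    expect_equal(gmm_conv(H, g$edges, g$eattr, kernels),
                 naive_gmm_conv(H, g$edges, g$eattr, kernels),
                 tolerance = 1e-10)
  }
})

test_that("convolution conventions: empty neighborhoods and identity limit", {
  # isolated nodes receive the zero vector
  empty <- matrix(integer(0), ncol = 2)
  H <- diag(3)
  out <- gmm_conv(H, empty, matrix(numeric(0), ncol = 2),
                  rand_kernels(2, 3, 3))
  expect_equal(out, matrix(0, 3, 3))
  # K = 1, huge variance (w ~ 1), Theta = I, single neighbor passes through
  v <- c(0.3, -1.2)
  H2 <- rbind(c(0, 0), v)
  edges <- cbind(1L, 2L)
  eattr <- cbind(5, 0.3)
  kernels <- list(list(Theta = diag(2), mu = c(0, 0), sigma2 = c(1e12, 1e12)))
  expect_equal(as.vector(gmm_conv(H2, edges, eattr, kernels)[1, ]), v,
               tolerance = 1e-9)
  expect_error(gmm_conv(H2, cbind(1L, 5L), eattr, kernels),
               class = "spice_validation_error")
})

test_that("the r = 0 network is an exact per-cell function", {
  g <- toy_graph(30, function(df) df$gene_1, r = 0, seed = 11)
  net <- gmm_gcn(2, 1, hidden = 8, K = 3, r = 0, seed = 2)
  base <- predict(net, g)
  g2 <- g
  g2$X[-5, ] <- g2$X[-5, ] + 100 # perturb every cell except cell 5
  expect_identical(predict(net, g2)[5, ], base[5, ])
})

test_that("forward is permutation-equivariant and respects locality", {
  ct <- rand_cells(25, g = 3, seed = 21, extent = 50)
  roles <- gene_role_map(c("gene_1", "gene_2", "gene_3"),
                         c("ligand", "ligand", "response"))
  cells <- preprocess_cells(ct, roles)
  g <- build_radius_graph(cells, 20, roles = roles)
  net <- gmm_gcn(2, 1, hidden = 6, K = 2, r = 20, seed = 5)
  base <- predict(net, g)
  perm <- withr::with_seed(3, sample(25))
  df <- as.data.frame(cells)[perm, ]
  gp <- build_radius_graph(cell_table(df), 20, roles = roles)
  attr(df, "preprocessed") <- TRUE
  expect_equal(predict(net, gp), base[perm, , drop = FALSE], tolerance = 1e-12)

  # all-zero parameters give all-zero predictions (biases included)
  net0 <- net
  net0$params <- spice:::.zeros_like(net$params)
  expect_equal(predict(net0, g), matrix(0, 25, 1), ignore_attr = TRUE)

  # 3 message-passing hops: a cell 7 hops away cannot influence predictions
  dfl <- data.frame(cell_id = sprintf("c%d", 1:8), slice_id = "s1",
                    x = 20 * (0:7), y = 0,
                    gene_1 = rexp(8), gene_2 = rexp(8), gene_3 = rexp(8))
  chain <- preprocess_cells(cell_table(dfl), roles)
  gl <- build_radius_graph(chain, 25, roles = roles)
  netl <- gmm_gcn(2, 1, hidden = 6, K = 2, r = 25, seed = 6)
  p1 <- predict(netl, gl)[1, ]
  dfl2 <- dfl
  dfl2$gene_1[8] <- dfl2$gene_1[8] + 50
  gl2 <- build_radius_graph(preprocess_cells(cell_table(dfl2), roles), 25,
                            roles = roles)
  expect_identical(predict(netl, gl2)[1, ], p1)
})

test_that("training learns a realizable own-cell function at r = 0", {
  graphs <- lapply(1:30, function(s) {
    toy_graph(60, function(df) 3 * df$gene_1, r = 0, seed = 400 + s,
              slice_id = paste0("s", s))
  })
  net <- gmm_gcn(2, 1, hidden = 16, K = 2, r = 0, seed = 1)
  cfg <- train_config(max_epochs = 150, patience = 25, seed = 9)
  net <- train_gmm_gcn(net, graphs[1:24], graphs[25:27], cfg)
  test_pred <- do.call(rbind, lapply(graphs[28:30], function(g) predict(net, g)))
  test_y <- do.call(rbind, lapply(graphs[28:30], `[[`, "Y"))
  expect_lte(mean((test_pred - test_y)^2), 1e-2)
})

test_that("early stopping halts on non-improving validation and keeps best weights", {
  # validation targets are identically zero while training targets are
  # large and positive, so with a zero output-bias start every training
  # step pushes predictions up and away from the validation optimum
  tr <- toy_graph(50, function(df) 10 * df$gene_1, r = 0, seed = 81)
  va <- toy_graph(50, function(df) 0 * df$gene_1, r = 0, seed = 82)
  net <- gmm_gcn(2, 1, hidden = 8, K = 2, r = 0, seed = 3)
  out <- train_gmm_gcn(net, list(tr), list(va),
                       train_config(max_epochs = 50, patience = 1, seed = 4,
                                    init_output_bias = "zero"))
  expect_equal(out$best_epoch, 0)
  expect_equal(nrow(out$log), 2) # initial evaluation + one epoch
  expect_gt(out$log$val_mse[2], out$log$val_mse[1])
  # best weights = the untrained initialization
  expect_equal(out$params, net$params)
})

test_that("training is deterministic given seeds", {
  graphs <- lapply(1:4, function(s) {
    toy_graph(40, function(df) df$gene_1 + 0.5 * df$gene_2, r = 0,
              seed = 500 + s, slice_id = paste0("s", s))
  })
  cfg <- train_config(max_epochs = 5, patience = 10, seed = 77)
  run <- function() {
    train_gmm_gcn(gmm_gcn(2, 1, hidden = 8, K = 2, r = 0, seed = 12),
                  graphs[1:3], graphs[4], cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$log, b$log)
  expect_identical(a$params, b$params)
})

test_that("models round-trip through disk and predict consistently", {
  ct <- rand_cells(15, g = 3, seed = 61, extent = 40)
  roles <- gene_role_map(c("gene_1", "gene_2", "gene_3"),
                         c("ligand", "receptor", "response"))
  cells <- preprocess_cells(ct, roles)
  g <- build_radius_graph(cells, 18, roles = roles)
  net <- gmm_gcn(2, 1, hidden = 5, K = 2, r = 18, seed = 8)
  net$response_names <- "gene_3"
  dir <- withr::local_tempdir()
  save_model(net, file.path(dir, "m"))
  back <- load_model(file.path(dir, "m"))
  expect_identical(predict(back, g), predict(net, g))
  # schema mismatch is caught
  g_bad <- g
  g_bad$X <- cbind(g$X, extra = 1)
  expect_error(predict(back, g_bad), class = "spice_schema_error")
})
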