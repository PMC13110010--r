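fake_sweep <- function(mse_by_radius) {
  # mse_by_radius: named list radius -> named gene vector
  rows <- do.call(rbind, lapply(names(mse_by_radius), function(r) {
    data.frame(gene = names(mse_by_radius[[r]]), radius = as.numeric(r),
               mse = unname(mse_by_radius[[r]]))
  }))
  structure(list(radii = as.numeric(names(mse_by_radius)), mse = rows,
                 errors = list(), clusters = NULL, seed = 1L),
            class = "sweep_result")
}

test_that("per-gene MSE pools cells correctly", {
  expect_equal(unname(evaluate_mse(cbind(1, 2), cbind(1, 2))), c(0, 0))
  expect_equal(unname(evaluate_mse(cbind(c(1, 1)), cbind(c(0, 2)))), 1)
  # pooling two graphs equals the cell-count-weighted combination
  p1 <- cbind(a = c(1, 2, 3)); y1 <- cbind(a = c(1, 1, 1))
  p2 <- cbind(a = c(0, 0)); y2 <- cbind(a = c(2, 2))
  pooled <- evaluate_mse(rbind(p1, p2), rbind(y1, y2))
  expect_equal(unname(pooled),
               unname((3 * evaluate_mse(p1, y1) + 2 * evaluate_mse(p2, y2)) / 5))
  expect_error(evaluate_mse(matrix(0, 0, 1), matrix(0, 0, 1)),
               class = "spice_validation_error")
})

test_that("gene ranking applies the loss-reduction formula and tie rules", {
  sw <- fake_sweep(list(`0` = c(gA = 2, gB = 1, gC = 1, gD = 4),
                        `25` = c(gA = 1, gB = 1, gC = 1.5, gD = 2)))
  rk <- rank_genes(sw, r = 25, r0 = 0)
  expect_equal(rk$gene, c("gA", "gD", "gB", "gC")) # 50, 50, 0, -50
  expect_equal(rk$loss_reduction_pct, c(50, 50, 0, -50))
  # ties broken alphabetically; worse-than-baseline genes ranked last
  expect_equal(rk$rank, 1:4)
  # self-comparison: all reductions exactly zero
  rk0 <- rank_genes(sw, r = 0, r0 = 0)
  expect_true(all(rk0$loss_reduction_pct == 0))
  # invariance to common rescaling of all squared errors
  sw10 <- fake_sweep(list(`0` = 10 * c(gA = 2, gB = 1, gC = 1, gD = 4),
                          `25` = 10 * c(gA = 1, gB = 1, gC = 1.5, gD = 2)))
  expect_equal(rank_genes(sw10, 25)$loss_reduction_pct, rk$loss_reduction_pct)
  expect_error(rank_genes(sw, r = 30), class = "spice_validation_error")
})

test_that("the paired cluster-bootstrap test behaves at its boundary cases", {
  set.seed(1)
  n <- 200
  clusters <- rep(paste0("s", 1:10), each = 20)
  base <- matrix(rexp(n), ncol = 1, dimnames = list(NULL, "g1"))
  # identical error arrays: no evidence, p at the top of the scale
  same <- paired_error_test(base, base, clusters, n_boot = 500, seed = 2)
  expect_gte(same$p, 0.5)
  # uniform improvement of +1 in every cell: p at the bootstrap floor
  improved <- paired_error_test(base + 1, base, clusters, n_boot = 500, seed = 2)
  expect_lte(improved$p, 1 / 501)
  # determinism under a fixed seed
  noisy <- base + rnorm(n)
  a <- paired_error_test(noisy, base, clusters, n_boot = 300, seed = 5)
  b <- paired_error_test(noisy, base, clusters, n_boot = 300, seed = 5)
  expect_identical(a$p, b$p)
  expect_error(paired_error_test(base, base, rep("s1", n)),
               class = "spice_validation_error")
  # BH adjustment is applied across genes
  errs <- matrix(rexp(n * 4), ncol = 4, dimnames = list(NULL, paste0("g", 1:4)))
  multi <- paired_error_test(errs + 1, errs, clusters, n_boot = 200, seed = 3)
  expect_equal(multi$q, p.adjust(multi$p, "BH"))
})

test_that("a radius sweep detects a planted interaction and not its absence", {
  # planted signal at r* = 30: the informed ridge model must beat r = 0
  cfg <- simulation_config(n_cells = 150, extent = c(173, 173), n_genes = 8,
                           r_star = 30, model = "thresholded_sum", seed = 71)
  st <- simulate_study(cfg, n_slices = 12, seed = 71)
  cells <- preprocess_cells(st$cells, st$roles)
  split <- split_by_group(cells, "slice_id", c(0.5, 0.25, 0.25), seed = 71)
  sw <- radius_sweep(cells, st$roles, split, c(0, 25), model = "ridge",
                     seed = 71)
  expect_lt(sw$mse$mse[sw$mse$radius == 25], sw$mse$mse[sw$mse$radius == 0])
  rk <- rank_genes(sw, r = 25)
  expect_gt(rk$loss_reduction_pct[rk$gene == "response_0"], 10)

  # single-radius sweep: self-comparison yields exactly zero reductions
  sw0 <- radius_sweep(cells, st$roles, split, 0, model = "ridge", seed = 71)
  expect_true(all(rank_genes(sw0, 0)$loss_reduction_pct == 0))

  # per-cell errors and clusters are retained for the paired test
  expect_equal(sort(names(sw$errors)), c("0", "25"))
  expect_equal(nrow(sw$errors[["0"]]), length(sw$clusters))
  tst <- paired_error_test(sw$errors[["0"]], sw$errors[["25"]], sw$clusters,
                           n_boot = 500, seed = 1)
  expect_lt(tst$p[tst$gene == "response_0"], 0.05)

  # null data: the spatially informed model should show no material gain
  ncfg <- simulation_config(n_cells = 150, extent = c(173, 173), n_genes = 6,
                            model = "null", n_null_responses = 6, seed = 72)
  nst <- simulate_study(ncfg, n_slices = 12, seed = 72)
  ncells <- preprocess_cells(nst$cells, nst$roles)
  nsplit <- split_by_group(ncells, "slice_id", c(0.5, 0.25, 0.25), seed = 72)
  nsw <- radius_sweep(ncells, nst$roles, nsplit, c(0, 25), model = "ridge",
                      seed = 72)
  nrk <- rank_genes(nsw, r = 25)
  expect_lt(max(abs(nrk$loss_reduction_pct)), 10)
})

test_that("sweep results serialize with rankings and a manifest", {
  cfg <- simulation_config(n_cells = 80, extent = c(126, 126), n_genes = 4,
                           r_star = 30, model = "thresholded_sum", seed = 55)
  st <- simulate_study(cfg, n_slices = 8, seed = 55)
  cells <- preprocess_cells(st$cells, st$roles)
  split <- split_by_group(cells, "slice_id", c(0.5, 0.25, 0.25), seed = 55)
  sw <- radius_sweep(cells, st$roles, split, c(0, 20), model = "ridge",
                     seed = 55)
  dir <- withr::local_tempdir()
  write_sweep_result(sw, dir, r = 20)
  expect_true(file.exists(file.path(dir, "mse.tsv")))
  rk <- read.table(file.path(dir, "ranking.tsv"), header = TRUE, sep = "\t")
  expect_true(all(c("gene", "loss_reduction_pct", "p", "q") %in% names(rk)))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$config$model, "ridge")
})
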