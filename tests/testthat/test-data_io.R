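test_that("cell tables load from delimited files with schema validation", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,slice_id,x,y,GeneA",
               "a,s1,0,0,1.5", "b,s1,3,4,0", "c,s1,10,0,2"), p)
  ct <- load_cell_table(p)
  expect_s3_class(ct, "cell_table")
  expect_equal(nrow(ct), 3)
  expect_equal(gene_names(ct), "GeneA")
  expect_equal(attr(ct, "coords"), c("x", "y"))

  # missing required column named in the error
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,x,y,GeneA", "a,0,0,1"), p2)
  expect_error(load_cell_table(p2), "slice_id", class = "spice_schema_error")

  # negative expression rejected
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,slice_id,x,y,GeneA", "a,s1,0,0,-1"), p3)
  expect_error(load_cell_table(p3), "negative", class = "spice_validation_error")

  # optional z column switches to 3D
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,slice_id,x,y,z,GeneA", "a,s1,0,0,5,1"), p4)
  expect_equal(attr(load_cell_table(p4), "coords"), c("x", "y", "z"))
})

test_that("cell tables round-trip through disk at full precision", {
  ct <- rand_cells(25, g = 3, seed = 42)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(ct, p)
  back <- load_cell_table(p)
  for (cc in c("x", "y", "gene_1", "gene_2", "gene_3")) {
    expect_identical(back[[cc]], ct[[cc]])
  }
})

test_that("gene role maps validate their role partition", {
  roles <- gene_role_map(c("L1", "R1", "Y1", "C1"),
                         c("ligand", "receptor", "response", "control"))
  expect_s3_class(roles, "gene_role_map")
  expect_error(gene_role_map("G1", "promoter"), "unknown gene role",
               class = "spice_validation_error")
  expect_error(gene_role_map(c("A", "B"), c("response", "response")),
               "ligand or receptor", class = "spice_validation_error")
  expect_error(gene_role_map(c("A", "A"), c("ligand", "response")),
               "more than once", class = "spice_validation_error")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gene_roles(roles, p)
  expect_equal(as.data.frame(load_gene_roles(p)), as.data.frame(roles))
})

test_that("preprocessing log1p-transforms predictors, leaves responses, drops controls", {
  df <- data.frame(cell_id = c("a", "b", "c"), slice_id = "s1",
                   x = c(0, 50, 100), y = 0,
                   L1 = c(0, exp(1) - 1, 3), Y1 = c(7.3, 0.2, 1),
                   C1 = c(1, 1, 1))
  roles <- gene_role_map(c("L1", "Y1", "C1"),
                         c("ligand", "response", "control"))
  out <- preprocess_cells(cell_table(df), roles)
  expect_equal(out$L1, c(0, 1, log1p(3)))     # log1p(0) = 0, log1p(e-1) = 1
  expect_equal(out$Y1, c(7.3, 0.2, 1))        # responses untouched
  expect_false("C1" %in% names(out))          # controls excluded entirely
  expect_true(attr(out, "preprocessed"))
  # strictly monotone on predictors
  expect_true(all(diff(order(out$L1)) == diff(order(df$L1))))
})

test_that("group splits keep groups whole and are deterministic", {
  df <- do.call(rbind, lapply(1:6, function(a) {
    data.frame(cell_id = sprintf("c%d_%d", a, 1:10), slice_id = paste0("s", a),
               animal_id = paste0("m", a), x = runif(10, 0, 100),
               y = runif(10, 0, 100), G1 = rexp(10))
  }))
  ct <- cell_table(df)
  sp <- split_by_group(ct, "animal_id", fractions = c(4, 1, 1) / 6, seed = 7)
  per_part <- tapply(df$animal_id, sp$partition,
                     function(a) length(unique(a)))
  expect_equal(as.vector(per_part[c("train", "validation", "test")]), c(4, 1, 1))
  # no animal spans two partitions
  expect_true(all(tapply(sp$partition, df$animal_id,
                         function(p) length(unique(p))) == 1))
  # deterministic given seed
  sp2 <- split_by_group(ct, "animal_id", fractions = c(4, 1, 1) / 6, seed = 7)
  expect_identical(as.data.frame(sp), as.data.frame(sp2))
  expect_false(identical(
    sp$partition,
    split_by_group(ct, "animal_id", fractions = c(4, 1, 1) / 6, seed = 8)$partition))
  # too few groups
  ct2 <- cell_table(df[df$animal_id %in% c("m1", "m2"), ])
  expect_error(split_by_group(ct2, "animal_id"), "at least 3",
               class = "spice_validation_error")
})

test_that("spatial partition drops buffer strips and disconnects partitions", {
  # cells on a line at x = 0..100: one internal boundary at x = 50
  df <- data.frame(cell_id = sprintf("c%03d", 0:100), slice_id = "s1",
                   x = as.numeric(0:100), y = 0, G1 = 1)
  ct <- cell_table(df)
  sp <- spatial_partition(ct, n_parts = 2, buffer = 10)
  kept_x <- df$x[match(sp$cell_id, df$cell_id)]
  expect_true(all(kept_x <= 45 | kept_x >= 55))
  left <- kept_x[sp$tile == 1]; right <- kept_x[sp$tile == 2]
  expect_gte(min(abs(outer(left, right, `-`))), 10)

  # buffer = 0: plain tiling, nothing dropped
  sp0 <- spatial_partition(ct, n_parts = 4, buffer = 0)
  expect_equal(nrow(sp0), nrow(df))

  expect_error(spatial_partition(ct, n_parts = 1, buffer = 10),
               class = "spice_validation_error")

  # brute-force cross-partition distances on a random 2D cloud
  ct2 <- rand_cells(400, seed = 3, extent = 500)
  buf <- 40
  sp2 <- spatial_partition(ct2, n_parts = 5, buffer = buf)
  xy <- as.matrix(as.data.frame(ct2)[match(sp2$cell_id, ct2$cell_id),
                                     c("x", "y")])
  for (pa in c("train", "validation", "test")) {
    for (pb in setdiff(c("train", "validation", "test"), pa)) {
      A <- xy[sp2$partition == pa, , drop = FALSE]
      B <- xy[sp2$partition == pb, , drop = FALSE]
      if (nrow(A) == 0 || nrow(B) == 0) next
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      expect_gte(sqrt(max(0, min(d2))), buf)
    }
  }
  expect_setequal(unique(sp2$partition), c("train", "validation", "test"))
})

test_that("splits round-trip through TSV files", {
  ct <- rand_cells(60, seed = 5)
  ct$animal_id <- rep(paste0("m", 1:6), each = 10)
  ct <- cell_table(as.data.frame(ct))
  sp <- split_by_group(ct, "animal_id", seed = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, p)
  back <- read_split(p)
  expect_equal(back$partition, sp$partition)
  expect_equal(back$cell_id, sp$cell_id)
})
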