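# Train/validation/test splitting. Two modes:
#  * by_group  — whole groups (animals) assigned to one partition each, so no
#    donor contributes cells to two partitions;
#  * spatial   — a single tissue is tiled along its longest axis and a buffer
#    strip is dropped at each internal boundary, so the retained partitions
#    are disconnected for every neighborhood radius up to the buffer width.

.PARTITIONS <- c("train", "validation", "test")

new_data_split <- function(df, mode, ...) {
  structure(df, class = c("data_split", "data.frame"), mode = mode, ...)
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split (%s): %s\n", attr(x, "mode"),
              paste(sprintf("%s=%d", .PARTITIONS,
                            sapply(.PARTITIONS, function(p) sum(x$partition == p))),
                    collapse = ", ")))
  invisible(x)
}

# Allocate n_items whole items to the three partitions, each non-empty,
# matching `fractions` as closely as possible (largest-remainder rounding).
allocate_counts <- function(n_items, fractions) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  fractions <- fractions / sum(fractions)
  raw <- fractions * n_items
  counts <- floor(raw)
  counts <- counts + (rank(-(raw - counts), ties.method = "first") <=
                        (n_items - sum(counts)))
  # every partition must receive at least one item
  while (any(counts == 0)) {
    i <- which.min(counts)
    j <- which.max(counts)
    counts[i] <- counts[i] + 1
    counts[j] <- counts[j] - 1
  }
  as.integer(counts)
}

#' Split cells into train/validation/test by a grouping column
#'
#' Groups (typically animals/donors) are assigned whole to partitions, so no
#' group ever spans two partitions; held-out performance then measures
#' generalization to unseen donors rather than unseen cells.
#'
#' @param cells a [cell_table()].
#' @param group_key column to group by (default `"animal_id"`; `"slice_id"`
#'   is the usual fallback when no animal identifier exists).
#' @param fractions length-3 positive vector of target train/validation/test
#'   fractions (of group counts), summing to 1.
#' @param seed integer; group shuffling is deterministic given the seed.
#' @return a `data_split` data.frame with columns `slice_id`, `cell_id`,
#'   `partition`.
#' @export
split_by_group <- function(cells, group_key = "animal_id",
                           fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(inherits(cells, "cell_table"))
  if (!group_key %in% names(cells)) {
    spice_error(sprintf("grouping column '%s' not present", group_key),
                "spice_schema_error")
  }
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    spice_error("fractions must be 3 positive numbers summing to 1",
                "spice_validation_error")
  }
  groups <- sort(unique(as.character(cells[[group_key]])))
  if (length(groups) < 3) {
    spice_error("need at least 3 groups to form train/validation/test partitions",
                "spice_validation_error")
  }
  counts <- allocate_counts(length(groups), fractions)
  perm <- local({
    old <- .Random.seed_safe()
    on.exit(.restore_seed(old))
    set.seed(seed)
    sample(groups)
  })
  assignment <- rep(.PARTITIONS, times = counts)
  names(assignment) <- perm
  df <- data.frame(slice_id = cells$slice_id, cell_id = cells$cell_id,
                   partition = unname(assignment[as.character(cells[[group_key]])]),
                   stringsAsFactors = FALSE)
  new_data_split(df, mode = "by_group", group_key = group_key, seed = seed)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Spatially partition a single tissue into disconnected subgraphs
#'
#' Tiles the tissue along its longest coordinate axis into `n_parts`
#' equal-count tiles and drops every cell within `buffer/2` of an internal
#' tile boundary. Retained cells in different tiles are therefore always more
#' than `buffer` apart, so tissue graphs with any radius `r <= buffer` never
#' connect two partitions. Tiles are then assigned to train/validation/test
#' in an interleaved deterministic order matching `fractions` by tile count.
#'
#' @param cells a [cell_table()]; intended for single-sample datasets.
#' @param n_parts number of tiles (>= 3).
#' @param buffer width in µm of the strip dropped at each internal boundary;
#'   must be at least the largest neighborhood radius you intend to sweep.
#' @param fractions length-3 target fractions over tiles.
#' @return a `data_split` with columns `slice_id`, `cell_id`, `partition`,
#'   `tile`. Dropped buffer cells are absent from the table.
#' @export
spatial_partition <- function(cells, n_parts, buffer,
                              fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(inherits(cells, "cell_table"))
  if (n_parts < 2) {
    spice_error("n_parts must be at least 2 (>= 3 for a three-way split)",
                "spice_validation_error")
  }
  if (buffer < 0) spice_error("buffer must be non-negative", "spice_validation_error")
  coords <- attr(cells, "coords")
  spans <- vapply(coords, function(cc) diff(range(cells[[cc]])), numeric(1))
  axis <- coords[which.max(spans)]
  v <- cells[[axis]]
  # equal-count tiles via quantile cuts of the chosen coordinate
  cuts <- stats::quantile(v, probs = seq(0, 1, length.out = n_parts + 1),
                          names = FALSE, type = 7)
  cuts <- unique(cuts)
  if (length(cuts) < n_parts + 1) {
    spice_error("spatial partition yields an empty tile; use fewer parts",
                "spice_validation_error")
  }
  tile <- findInterval(v, cuts, rightmost.closed = TRUE, all.inside = TRUE)
  internal <- cuts[2:n_parts]
  keep <- rep(TRUE, length(v))
  for (b in internal) keep <- keep & (abs(v - b) >= buffer / 2)
  if (any(tabulate(tile[keep], nbins = n_parts) == 0)) {
    spice_error("spatial partition yields an empty tile; use fewer parts",
                "spice_validation_error")
  }
  # with only two tiles a validation partition cannot be formed; fall back to
  # train/test so the buffered-tiling geometry itself remains usable
  parts <- if (n_parts >= 3) .PARTITIONS else c("train", "test")
  fr <- if (n_parts >= 3) fractions else fractions[c(1, 3)] / sum(fractions[c(1, 3)])
  counts <- if (n_parts >= 3) allocate_counts(n_parts, fr) else c(1L, 1L)
  # interleave: walk tiles left to right, always giving the next tile to the
  # partition currently furthest below its target share
  assigned <- integer(length(parts))
  tile_label <- character(n_parts)
  for (i in seq_len(n_parts)) {
    deficit <- (assigned + 1) / counts
    p <- which.min(deficit)
    tile_label[i] <- parts[p]
    assigned[p] <- assigned[p] + 1
  }
  df <- data.frame(slice_id = cells$slice_id[keep],
                   cell_id = cells$cell_id[keep],
                   partition = tile_label[tile[keep]],
                   tile = tile[keep], stringsAsFactors = FALSE)
  new_data_split(df, mode = "spatial", axis = axis, buffer = buffer,
                 cuts = cuts)
}

#' Read/write a data split as a TSV file
#' @param split a `data_split`.
#' @param path file path.
#' @return `read_split` returns a `data_split`; `write_split` returns `path`.
#' @export
write_split <- function(split, path) {
  utils::write.table(as.data.frame(split), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @param mode split mode recorded in the file's companion metadata; defaults
#'   to `"by_group"`.
#' @export
read_split <- function(path, mode = "by_group") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("slice_id", "cell_id", "partition") %in% names(df))) {
    spice_error("split file needs columns slice_id, cell_id, partition",
                "spice_schema_error")
  }
  bad <- setdiff(unique(df$partition), .PARTITIONS)
  if (length(bad) > 0) {
    spice_error(sprintf("unknown partition label(s): %s",
                        paste(bad, collapse = ", ")), "spice_validation_error")
  }
  new_data_split(df, mode = mode)
}
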