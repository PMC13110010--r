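# Radius-neighborhood tissue graphs: cells are nodes, and a bidirectional
# edge links every pair of cells strictly closer than r µm. Edge attributes
# are polar (2D) or spherical (3D) displacement descriptors; distances stay
# in raw µm.

# All unordered pairs {a, b} with 0 < d(a, b) < r, found with a uniform-grid
# spatial index (bucket side r, candidate pairs only from adjacent buckets).
# Returns a 2-column integer matrix with a < b; zero rows when r <= 0.
radius_pairs <- function(coords, r) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  if (n < 2 || r <= 0) return(empty)
  d <- ncol(coords)
  ix <- floor(sweep(coords, 2, apply(coords, 2, min)) / r) + 1
  # strides padded by 2 so off-grid neighbor offsets can never alias onto a
  # real bucket (keys stay unique for bucket coords in [0, dims + 1])
  dims <- apply(ix, 2, max) + 2
  key <- ix[, 1]
  if (d >= 2) key <- key + dims[1] * ix[, 2]
  if (d >= 3) key <- key + dims[1] * dims[2] * ix[, 3]
  buckets <- split(seq_len(n), key)
  bkey <- as.numeric(names(buckets))
  lookup <- new.env(hash = TRUE, size = length(buckets))
  for (t in seq_along(buckets)) assign(as.character(bkey[t]), buckets[[t]], envir = lookup)
  # half-space of neighbor offsets so each bucket pair is visited once
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  offs <- offs[apply(offs, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[length(nz)]] > 0
  }), , drop = FALSE]
  okey <- offs[, 1]
  if (d >= 2) okey <- okey + dims[1] * offs[, 2]
  if (d >= 3) okey <- okey + dims[1] * dims[2] * offs[, 3]
  acc_a <- vector("list", length(buckets) * (nrow(offs) + 1))
  acc_b <- acc_a
  slot <- 0L
  for (t in seq_along(buckets)) {
    ii <- buckets[[t]]
    m <- length(ii)
    if (m > 1) { # within-bucket pairs, a < b
      slot <- slot + 1L
      acc_a[[slot]] <- rep(ii[-m], times = (m - 1):1)
      acc_b[[slot]] <- ii[unlist(lapply(2:m, function(s) s:m), use.names = FALSE)]
    }
    for (t2 in seq_along(okey)) {
      jj <- get0(as.character(bkey[t] + okey[t2]), envir = lookup)
      if (!is.null(jj)) {
        slot <- slot + 1L
        acc_a[[slot]] <- rep(ii, times = length(jj))
        acc_b[[slot]] <- rep(jj, each = length(ii))
      }
    }
  }
  if (slot == 0L) return(empty)
  a <- unlist(acc_a[seq_len(slot)], use.names = FALSE)
  b <- unlist(acc_b[seq_len(slot)], use.names = FALSE)
  dd <- rowSums((coords[a, , drop = FALSE] - coords[b, , drop = FALSE])^2)
  keep <- dd > 0 & dd < r^2
  a <- a[keep]; b <- b[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cbind(a = a, b = b)
}

#' Polar/spherical edge attributes for a set of directed edges
#'
#' For an edge (i, j), with i the receiving cell and j its neighbor, the
#' attribute row describes the displacement from i to j: in `polar2d` mode
#' `(distance, angle)` with the angle computed by the two-argument
#' arctangent, so the full quadrant is resolved and angles lie in (-pi, pi];
#' in `spherical3d` mode `(distance, azimuth, inclination)` with the
#' inclination measured from the +z axis.
#'
#' @param positions numeric matrix of cell coordinates (µm), 2 or 3 columns.
#' @param edges 2-column integer matrix of directed edges `(i, j)`.
#' @param mode `"polar2d"` or `"spherical3d"`; must match the coordinate
#'   dimensionality.
#' @return numeric matrix with one row per edge; first column is the
#'   Euclidean distance.
#' @export
compute_edge_attributes <- function(positions, edges,
                                    mode = c("polar2d", "spherical3d")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  dim_needed <- if (mode == "polar2d") 2L else 3L
  if (ncol(positions) != dim_needed) {
    spice_error(sprintf("mode '%s' needs %d-column positions", mode, dim_needed),
                "spice_validation_error")
  }
  if (nrow(edges) == 0) {
    return(matrix(numeric(0), ncol = dim_needed,
                  dimnames = list(NULL, c("dist", "angle", "inclination")[seq_len(dim_needed)])))
  }
  disp <- positions[edges[, 2], , drop = FALSE] - positions[edges[, 1], , drop = FALSE]
  dimnames(disp) <- NULL
  dist <- sqrt(rowSums(disp^2))
  if (any(dist == 0)) {
    spice_error("zero-length displacement: self-edges are not allowed",
                "spice_validation_error")
  }
  ang <- atan2(disp[, 2], disp[, 1])
  if (mode == "polar2d") {
    cbind(dist = dist, angle = ang)
  } else {
    cbind(dist = dist, angle = ang, inclination = acos(pmin(1, pmax(-1, disp[, 3] / dist))))
  }
}

#' Build the radius-neighborhood graph for one tissue slice
#'
#' Connects every pair of cells whose Euclidean distance is strictly below
#' `r` with a pair of directed edges (one per direction), computes polar or
#' spherical edge attributes, and optionally attaches node feature and target
#' matrices when a gene-role map is supplied.
#'
#' @param cells a [cell_table()] whose rows all belong to one slice (or one
#'   spatial partition of a slice).
#' @param r neighborhood radius in µm; `r = 0` yields an edgeless graph.
#' @param roles optional [gene_role_map()]; when given, node features are the
#'   (preprocessed) ligand/receptor columns and targets the response columns.
#' @param use_cell_types append one-hot encoded `cell_type` columns to the
#'   node features.
#' @param type_levels category levels used for the one-hot encoding;
#'   defaults to the levels observed in `cells`. Unseen categories map to an
#'   all-zero row.
#' @return a `tissue_graph`: node ids, coordinates, directed edge list
#'   (columns `i` receiver, `j` neighbor, sorted by `(i, j)`), edge
#'   attributes, radius, and optional feature/target matrices.
#' @export
build_radius_graph <- function(cells, r, roles = NULL, use_cell_types = FALSE,
                               type_levels = NULL) {
  stopifnot(inherits(cells, "cell_table"))
  if (nrow(cells) == 0) spice_error("empty cell set", "spice_validation_error")
  if (r < 0) spice_error("radius must be non-negative", "spice_validation_error")
  if (length(unique(cells$slice_id)) > 1) {
    spice_error("build_radius_graph expects cells from a single slice",
                "spice_validation_error")
  }
  coords <- as.matrix(as.data.frame(cells)[, attr(cells, "coords"), drop = FALSE])
  dimnames(coords) <- list(NULL, attr(cells, "coords"))
  pairs <- radius_pairs(coords, r)
  edges <- cbind(i = c(pairs[, 1], pairs[, 2]), j = c(pairs[, 2], pairs[, 1]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  mode <- if (ncol(coords) == 3) "spherical3d" else "polar2d"
  eattr <- compute_edge_attributes(coords, edges, mode)
  X <- Y <- NULL
  feature_names <- response_names <- NULL
  if (!is.null(roles)) {
    check_roles_cover(cells, roles)
    preds <- intersect(gene_names(cells), predictor_genes(roles))
    resps <- intersect(gene_names(cells), response_genes(roles))
    X <- as.matrix(as.data.frame(cells)[, preds, drop = FALSE])
    Y <- as.matrix(as.data.frame(cells)[, resps, drop = FALSE])
    feature_names <- preds
    response_names <- resps
    if (use_cell_types) {
      if (!attr(cells, "has_cell_type")) {
        spice_error("use_cell_types = TRUE but no cell_type column",
                    "spice_schema_error")
      }
      lv <- type_levels %||% sort(unique(as.character(cells$cell_type)))
      onehot <- matrix(0, nrow(cells), length(lv),
                       dimnames = list(NULL, paste0("celltype:", lv)))
      hit <- match(as.character(cells$cell_type), lv)
      ok <- !is.na(hit)
      onehot[cbind(which(ok), hit[ok])] <- 1
      X <- cbind(X, onehot)
      feature_names <- c(feature_names, colnames(onehot))
    }
  }
  structure(list(cell_id = cells$cell_id, slice_id = cells$slice_id[1],
                 cell_type = if (attr(cells, "has_cell_type"))
                   as.character(cells$cell_type) else NULL,
                 coords = coords, edges = edges, eattr = eattr, r = r,
                 deg = tabulate(edges[, 1], nbins = nrow(cells)),
                 X = X, Y = Y, feature_names = feature_names,
                 response_names = response_names, n = nrow(cells)),
            class = "tissue_graph")
}

#' @export
print.tissue_graph <- function(x, ...) {
  cat(sprintf("tissue_graph: %d cells, %d directed edges, r = %g µm%s\n",
              x$n, nrow(x$edges), x$r,
              if (is.null(x$X)) "" else sprintf(", %d features, %d responses",
                                                ncol(x$X), ncol(x$Y))))
  invisible(x)
}

#' Build train/validation/test tissue graphs from a split cell table
#'
#' One graph is built per (slice, partition) — or per tile for spatial
#' splits — at the requested radius, with node features taken from the
#' preprocessed ligand/receptor columns (plus optional one-hot cell types)
#' and targets from the raw response columns.
#'
#' @param cells a preprocessed [cell_table()] (see [preprocess_cells()]).
#' @param roles the matching [gene_role_map()].
#' @param split a `data_split` from [split_by_group()] or
#'   [spatial_partition()].
#' @param r neighborhood radius in µm.
#' @param use_cell_types append one-hot cell-type features; encoding levels
#'   are fixed from the training partition.
#' @return a `graph_dataset`: list with elements `train`, `validation`,
#'   `test` (lists of `tissue_graph`), plus schema metadata.
#' @export
build_dataset <- function(cells, roles, split, r, use_cell_types = FALSE) {
  stopifnot(inherits(cells, "cell_table"), inherits(split, "data_split"))
  if (!isTRUE(attr(cells, "preprocessed"))) {
    spice_error("cells must be preprocessed (preprocess_cells) before graph building",
                "spice_validation_error")
  }
  df <- as.data.frame(cells)
  key <- paste(df$slice_id, df$cell_id, sep = "\r")
  skey <- paste(split$slice_id, split$cell_id, sep = "\r")
  hit <- match(key, skey)
  part <- split$partition[hit]
  tile <- if ("tile" %in% names(split)) split$tile[hit] else NULL
  if (attr(split, "mode") == "by_group" &&
      any(tapply(part[!is.na(part)], df$slice_id[!is.na(part)],
                 function(p) length(unique(p))) > 1)) {
    spice_error("a slice spans two partitions in by_group mode",
                "spice_schema_error")
  }
  keep <- which(!is.na(part))
  grp <- if (is.null(tile)) {
    paste(df$slice_id[keep], part[keep], sep = "\r")
  } else {
    paste(df$slice_id[keep], part[keep], tile[keep], sep = "\r")
  }
  type_levels <- NULL
  if (use_cell_types) {
    if (!attr(cells, "has_cell_type")) {
      spice_error("use_cell_types = TRUE but no cell_type column", "spice_schema_error")
    }
    type_levels <- sort(unique(as.character(df$cell_type[keep][part[keep] == "train"])))
  }
  out <- list(train = list(), validation = list(), test = list())
  for (g in unique(grp)) {
    rows <- keep[grp == g]
    sub <- cell_table(df[rows, , drop = FALSE])
    attr(sub, "preprocessed") <- TRUE
    gr <- build_radius_graph(sub, r, roles = roles,
                             use_cell_types = use_cell_types,
                             type_levels = type_levels)
    p <- part[rows[1]]
    out[[p]][[length(out[[p]]) + 1L]] <- gr
  }
  first <- c(out$train, out$validation, out$test)[[1]]
  structure(list(train = out$train, validation = out$validation,
                 test = out$test, r = r,
                 feature_names = first$feature_names,
                 response_names = first$response_names,
                 type_levels = type_levels),
            class = "graph_dataset")
}

#' Serialize a tissue graph to plain-text files
#'
#' Writes `<stem>_nodes.tsv` (ids, coordinates, features, targets),
#' `<stem>_edges.tsv` (edge list + attributes) and `<stem>.json` (radius and
#' column schema).
#'
#' @param graph a `tissue_graph`.
#' @param stem output path stem.
#' @return invisibly, the three paths.
#' @export
write_tissue_graph <- function(graph, stem) {
  nodes <- data.frame(cell_id = graph$cell_id, graph$coords, check.names = FALSE)
  if (!is.null(graph$X)) nodes <- cbind(nodes, as.data.frame(graph$X))
  if (!is.null(graph$Y)) nodes <- cbind(nodes, as.data.frame(graph$Y))
  np <- paste0(stem, "_nodes.tsv"); ep <- paste0(stem, "_edges.tsv")
  jp <- paste0(stem, ".json")
  utils::write.table(nodes, np, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(graph$edges, graph$eattr, check.names = FALSE),
                     ep, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(radius = graph$r, slice_id = graph$slice_id,
                            n = graph$n,
                            feature_names = graph$feature_names,
                            response_names = graph$response_names),
                       jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nodes = np, edges = ep, meta = jp))
}
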