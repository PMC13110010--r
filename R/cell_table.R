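# Cell tables: one row per cell with coordinates (µm), tissue identifiers and
# gene expression. Reserved (non-gene) columns:
.RESERVED_COLS <- c("cell_id", "slice_id", "animal_id", "x", "y", "z", "cell_type")

.GENE_ROLES <- c("ligand", "receptor", "response", "control")

#' Construct a validated cell table
#'
#' A cell table holds one row per cell: spatial coordinates in micrometres,
#' a tissue/slice identifier, optional animal/donor identifier and cell-type
#' label, and one column per measured gene. Columns other than the reserved
#' ones (`cell_id`, `slice_id`, `animal_id`, `x`, `y`, `z`, `cell_type`) are
#' treated as gene expression.
#'
#' @param df data.frame with at least `cell_id`, `slice_id`, `x`, `y` and one
#'   gene column. An optional `z` column switches the table to 3D.
#' @return a `cell_table`: the data.frame with gene/coordinate metadata
#'   attached.
#' @export
#' @examples
#' df <- data.frame(cell_id = c("a", "b"), slice_id = "s1",
#'                  x = c(0, 10), y = c(0, 0), GeneA = c(1, 2))
#' ct <- cell_table(df)
#' gene_names(ct)
cell_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("cell_id", "slice_id", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    spice_error(sprintf("cell table is missing required column(s): %s",
                        paste(missing, collapse = ", ")), "spice_schema_error")
  }
  genes <- setdiff(names(df), .RESERVED_COLS)
  if (length(genes) == 0) {
    spice_error("cell table has no gene expression columns", "spice_schema_error")
  }
  has_z <- "z" %in% names(df)
  coords <- if (has_z) c("x", "y", "z") else c("x", "y")
  for (cc in coords) {
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]]) || any(!is.finite(df[[cc]]))) {
      spice_error(sprintf("coordinate column '%s' must be finite numeric", cc),
                  "spice_validation_error")
    }
  }
  if (has_z && anyNA(df$z)) {
    spice_error("mixed 2D/3D coordinates: 'z' present but contains NA",
                "spice_validation_error")
  }
  for (g in genes) {
    v <- df[[g]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      spice_error(sprintf("expression column '%s' must be finite numeric", g),
                  "spice_validation_error")
    }
    if (any(v < 0)) {
      spice_error(sprintf("expression column '%s' contains negative values", g),
                  "spice_validation_error")
    }
  }
  df$cell_id <- as.character(df$cell_id)
  df$slice_id <- as.character(df$slice_id)
  dup <- stats::ave(seq_len(nrow(df)), df$slice_id, df$cell_id, FUN = length)
  if (any(dup > 1)) {
    spice_error("cell_id values must be unique within each slice",
                "spice_validation_error")
  }
  structure(df, class = c("cell_table", "data.frame"),
            genes = genes, coords = coords,
            has_cell_type = "cell_type" %in% names(df),
            has_animal = "animal_id" %in% names(df),
            preprocessed = isTRUE(attr(df, "preprocessed")))
}

#' @rdname cell_table
#' @export
gene_names <- function(df) attr(df, "genes")

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, %d slices, %d genes (%s)%s\n",
              nrow(x), length(unique(x$slice_id)), length(attr(x, "genes")),
              if (length(attr(x, "coords")) == 3) "3D" else "2D",
              if (isTRUE(attr(x, "preprocessed"))) ", preprocessed" else ""))
  invisible(x)
}

#' Read a cell table from a delimited text file
#'
#' @param path path to a CSV or TSV file with columns as described in
#'   [cell_table()].
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return a validated [cell_table()].
#' @export
load_cell_table <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) spice_error(sprintf("file not found: %s", path),
                                      "spice_io_error")
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cell_table(df)
}

#' Write a cell table to a delimited text file
#' @param cells a [cell_table()].
#' @param path output path; extension selects CSV vs TSV.
#' @return invisibly, `path`.
#' @export
write_cell_table <- function(cells, path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- as.data.frame(cells)
  for (cc in names(df)) { # 17 significant digits: lossless double round trip
    if (is.double(df[[cc]])) df[[cc]] <- sprintf("%.17g", df[[cc]])
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct or read a gene-role map
#'
#' Each measured gene is classified as `ligand`, `receptor`, `response` or
#' `control`. Ligands and receptors are the predictors, responses are the
#' prediction targets, and control genes are excluded from both.
#'
#' @param gene character vector of gene names, or a two-column data.frame.
#' @param role character vector of roles, recycled against `gene`.
#' @return a `gene_role_map` data.frame with columns `gene`, `role`.
#' @export
#' @examples
#' gene_role_map(c("L1", "R1", "Y1"), c("ligand", "receptor", "response"))
gene_role_map <- function(gene, role = NULL) {
  if (is.data.frame(gene)) {
    df <- gene
    if (!all(c("gene", "role") %in% names(df))) {
      spice_error("gene-role map needs columns 'gene' and 'role'",
                  "spice_schema_error")
    }
  } else {
    df <- data.frame(gene = as.character(gene), role = as.character(role),
                     stringsAsFactors = FALSE)
  }
  df$gene <- as.character(df$gene)
  df$role <- as.character(df$role)
  bad <- setdiff(unique(df$role), .GENE_ROLES)
  if (length(bad) > 0) {
    spice_error(sprintf("unknown gene role(s): %s", paste(bad, collapse = ", ")),
                "spice_validation_error")
  }
  if (anyDuplicated(df$gene)) {
    spice_error("gene-role map lists a gene more than once", "spice_validation_error")
  }
  if (!any(df$role %in% c("ligand", "receptor"))) {
    spice_error("gene-role map needs at least one ligand or receptor",
                "spice_validation_error")
  }
  if (!any(df$role == "response")) {
    spice_error("gene-role map needs at least one response gene",
                "spice_validation_error")
  }
  structure(df, class = c("gene_role_map", "data.frame"))
}

#' @rdname gene_role_map
#' @param path path to a two-column TSV (gene, role).
#' @export
load_gene_roles <- function(path) {
  if (!file.exists(path)) spice_error(sprintf("file not found: %s", path),
                                      "spice_io_error")
  gene_role_map(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE))
}

#' @rdname gene_role_map
#' @param roles a `gene_role_map`.
#' @export
write_gene_roles <- function(roles, path) {
  utils::write.table(as.data.frame(roles), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

predictor_genes <- function(roles) roles$gene[roles$role %in% c("ligand", "receptor")]
response_genes <- function(roles) roles$gene[roles$role == "response"]

check_roles_cover <- function(cells, roles) {
  genes <- gene_names(cells)
  missing <- setdiff(genes, roles$gene)
  if (length(missing) > 0) {
    spice_error(sprintf("gene column(s) absent from role map: %s",
                        paste(utils::head(missing, 5), collapse = ", ")),
                "spice_schema_error")
  }
  invisible(TRUE)
}

#' Apply model preprocessing to a cell table
#'
#' Ligand and receptor columns are replaced by `log(1 + value)`; response
#' columns are left on their raw scale (they are the prediction targets and
#' held-out errors are reported in original units); control genes are dropped
#' entirely.
#'
#' @param cells a [cell_table()] with raw, non-negative expression.
#' @param roles a [gene_role_map()] covering every gene column.
#' @return a preprocessed `cell_table` (attribute `preprocessed` set).
#' @export
preprocess_cells <- function(cells, roles) {
  stopifnot(inherits(cells, "cell_table"), inherits(roles, "gene_role_map"))
  if (isTRUE(attr(cells, "preprocessed"))) {
    spice_error("cell table is already preprocessed", "spice_validation_error")
  }
  check_roles_cover(cells, roles)
  df <- as.data.frame(cells)
  controls <- intersect(gene_names(cells), roles$gene[roles$role == "control"])
  if (length(controls) > 0) df <- df[, setdiff(names(df), controls), drop = FALSE]
  preds <- intersect(names(df), predictor_genes(roles))
  for (g in preds) df[[g]] <- log1p(df[[g]])
  attr(df, "preprocessed") <- TRUE
  out <- cell_table(df)
  attr(out, "preprocessed") <- TRUE
  out
}
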