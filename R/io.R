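#' Read an annotated expression dataset from a dataset directory
#'
#' Datasets live in a plain-text directory container: the count matrix as
#' either `counts.mtx` (MatrixMarket, cells x genes) or `counts.csv` (dense,
#' cells in rows), gene identifiers in `genes.tsv` (one per line, column
#' `gene_id`), and per-cell metadata in `cells.tsv` (tab-separated; column
#' `cell_id`, spatial coordinates in columns `x`/`y`, cell types in the
#' `label_key` column).
#'
#' A spatial dataset must provide `x`/`y` columns; a reference dataset must
#' provide the label column.
#'
#' @param path directory containing the container files.
#' @param role `"reference"` or `"spatial"`.
#' @param label_key name of the cell-metadata column holding cell-type labels
#'   (default `"cell_type"`).
#' @return an [expression_dataset].
#' @seealso [write_expression_dataset()]
#' @export
read_expression_dataset <- function(path, role = c("reference", "spatial"),
                                    label_key = "cell_type") {
  role <- match.arg(role)
  if (!dir.exists(path)) stop("dataset directory not found: ", path)
  mtx <- file.path(path, "counts.mtx")
  csv <- file.path(path, "counts.csv")
  if (file.exists(mtx)) {
    counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
  } else if (file.exists(csv)) {
    counts <- as.matrix(utils::read.csv(csv, header = FALSE))
    dimnames(counts) <- NULL
    if (!is.numeric(counts)) stop("counts.csv contains non-numeric entries")
  } else {
    stop("no counts.mtx or counts.csv in ", path)
  }
  gf <- file.path(path, "genes.tsv")
  cf <- file.path(path, "cells.tsv")
  if (!file.exists(gf)) stop("missing genes.tsv in ", path)
  if (!file.exists(cf)) stop("missing cells.tsv in ", path)
  genes <- utils::read.delim(gf, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cf, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes)) stop("genes.tsv must have a gene_id column")
  if (!"cell_id" %in% names(cells)) stop("cells.tsv must have a cell_id column")

  coords <- NULL
  if (role == "spatial") {
    if (!all(c("x", "y") %in% names(cells)))
      stop("spatial dataset is missing the coordinate slot: ",
           "cells.tsv must have `x` and `y` columns")
    coords <- as.matrix(cells[, c("x", "y")])
  }
  labels <- NULL
  if (label_key %in% names(cells)) labels <- cells[[label_key]]
  if (role == "reference" && is.null(labels))
    stop("reference dataset is missing the label column `", label_key,
         "` in cells.tsv")
  expression_dataset(counts, gene_ids = genes$gene_id, cell_ids = cells$cell_id,
                     coords = coords, labels = labels, role = role)
}

#' Write an expression dataset to a dataset directory
#'
#' @param x an [expression_dataset].
#' @param path output directory (created if needed).
#' @param format `"mtx"` (sparse MatrixMarket) or `"csv"` (dense).
#' @param label_key column name used for labels in `cells.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(x, path, format = c("mtx", "csv"),
                                     label_key = "cell_type") {
  stopifnot(inherits(x, "expression_dataset"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(as(as(x$counts, "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "counts.mtx"))
  } else {
    utils::write.table(as.matrix(x$counts), file.path(path, "counts.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(gene_id = x$gene_ids),
                     file.path(path, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cells <- data.frame(cell_id = x$cell_ids)
  if (!is.null(x$coords)) { cells$x <- x$coords[, 1]; cells$y <- x$coords[, 2] }
  if (!is.null(x$labels)) cells[[label_key]] <- x$labels
  utils::write.table(cells, file.path(path, "cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align two datasets on their shared genes
#'
#' Restricts the reference and the spatial dataset to the intersection of
#' their gene identifiers, in a common gene order (order of first appearance
#' in the reference). Cells are unchanged. Genes with zero counts in one
#' modality are retained; nothing beyond exact identifier matching is done.
#'
#' @param ref reference [expression_dataset].
#' @param spatial spatial [expression_dataset].
#' @param min_shared warn when fewer shared genes than this remain
#'   (default 50).
#' @param case_fold match gene identifiers case-insensitively (default
#'   `FALSE`; exact string match).
#' @return a list with elements `reference` and `spatial`, both restricted to
#'   the shared genes in identical order.
#' @examples
#' m <- matrix(1, 2, 3, dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
#' r <- expression_dataset(m, labels = c("A", "B"), role = "reference")
#' s <- expression_dataset(m[, 2:3, drop = FALSE], coords = cbind(1:2, 1:2),
#'                         role = "spatial")
#' al <- suppressWarnings(align_genes(r, s))
#' al$reference$gene_ids
#' @export
align_genes <- function(ref, spatial, min_shared = 50, case_fold = FALSE) {
  stopifnot(inherits(ref, "expression_dataset"),
            inherits(spatial, "expression_dataset"))
  rg <- ref$gene_ids; sg <- spatial$gene_ids
  key_r <- if (case_fold) tolower(rg) else rg
  key_s <- if (case_fold) tolower(sg) else sg
  keep <- key_r %in% key_s
  if (!any(keep))
    stop("no shared genes between the reference and the spatial dataset")
  shared_r <- which(keep)
  if (length(shared_r) < min_shared)
    warning(sprintf("only %d shared genes (< %d); downstream stages may be unstable",
                    length(shared_r), min_shared))
  pos_s <- match(key_r[shared_r], key_s)
  restrict <- function(x, j) {
    expression_dataset(x$counts[, j, drop = FALSE], x$gene_ids[j], x$cell_ids,
                       coords = x$coords, labels = x$labels, role = x$role)
  }
  list(reference = restrict(ref, shared_r), spatial = restrict(spatial, pos_s))
}
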