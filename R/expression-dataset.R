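#' Annotated expression dataset
#'
#' The basic container of the pipeline: a cells-by-genes matrix of raw counts
#' together with cell/gene identifiers, an optional 2-D coordinate matrix
#' (spatial datasets), optional per-cell type labels (reference datasets, or
#' spatial ground truth used for evaluation), and a modality role tag.
#'
#' Counts are kept raw (non-negative integers); any normalization is owned by
#' the downstream stage that needs it.
#'
#' @param counts numeric matrix (base or `Matrix` sparse), cells in rows,
#'   genes in columns. Entries must be non-negative and integral.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `colnames(counts)`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   `rownames(counts)`).
#' @param coords optional numeric matrix with `n` rows and 2 columns (`x`,
#'   `y`). Required when `role = "spatial"`, forbidden for the reference.
#' @param labels optional character/factor vector of per-cell type labels.
#'   Required when `role = "reference"`.
#' @param role `"reference"` or `"spatial"`; doubles as the batch tag of every
#'   cell in the dataset.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `gene_ids`, `cell_ids`, `coords`, `labels`, `role`.
#' @examples
#' m <- matrix(rpois(12, 3), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ref <- expression_dataset(m, labels = c("A", "A", "B"), role = "reference")
#' ref
#' @export
expression_dataset <- function(counts, gene_ids = colnames(counts),
                               cell_ids = rownames(counts),
                               coords = NULL, labels = NULL,
                               role = c("reference", "spatial")) {
  role <- match.arg(role)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!(is.matrix(counts) || is(counts, "Matrix")))
    stop("`counts` must be a matrix of cells x genes")
  if (!is.numeric(counts[1, 1]))
    stop("`counts` must be numeric (raw counts); got non-numeric entries")
  n <- nrow(counts); d <- ncol(counts)
  if (n < 1 || d < 1) stop("`counts` must have at least one cell and one gene")
  mn <- min(counts)
  if (is.na(mn)) stop("`counts` contains missing values")
  if (mn < 0) stop("`counts` has negative entries; raw counts expected")

  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != d) stop("`gene_ids` length must equal ncol(counts)")
  if (length(cell_ids) != n) stop("`cell_ids` length must equal nrow(counts)")
  if (anyDuplicated(gene_ids)) stop("`gene_ids` must be unique")
  if (anyDuplicated(cell_ids)) stop("`cell_ids` must be unique")

  if (role == "spatial") {
    if (is.null(coords))
      stop("spatial dataset is missing the `coords` slot (n x 2 coordinates)")
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2)
      stop("`coords` must be an n x 2 matrix of x/y positions")
    if (any(!is.finite(coords))) stop("`coords` must be finite")
    colnames(coords) <- c("x", "y")
    rownames(coords) <- cell_ids
  } else {
    if (!is.null(coords))
      stop("reference dataset must not carry coordinates; coords are spatial-only")
    if (is.null(labels))
      stop("reference dataset is missing the `labels` slot (cell types)")
  }
  if (!is.null(labels)) {
    labels <- trimws(as.character(labels))
    if (length(labels) != n) stop("`labels` length must equal the cell count")
    if (anyNA(labels)) stop("`labels` contains missing values")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 coords = coords, labels = labels, role = role),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d cells x %d genes\n",
              x$role, length(x$cell_ids), length(x$gene_ids)))
  if (!is.null(x$coords)) cat("  coords: present\n")
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d types (%s)\n", length(unique(x$labels)),
                paste(head(sort(unique(x$labels)), 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

#' Restrict a dataset to a subset of cells
#' @param x an `expression_dataset`
#' @param i cell index vector
#' @return the subset dataset (same role)
#' @keywords internal
subset_cells <- function(x, i) {
  expression_dataset(x$counts[i, , drop = FALSE], x$gene_ids, x$cell_ids[i],
                     coords = if (!is.null(x$coords)) x$coords[i, , drop = FALSE],
                     labels = if (!is.null(x$labels)) x$labels[i],
                     role = x$role)
}
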