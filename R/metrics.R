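#' Overall annotation accuracy
#'
#' Fraction of cells whose predicted label equals the ground-truth label.
#' Labels are compared as exact strings after whitespace trimming.
#'
#' @param truth,pred label vectors of equal, positive length.
#' @return scalar in `[0, 1]`.
#' @export
accuracy_score <- function(truth, pred) {
  truth <- trimws(as.character(truth)); pred <- trimws(as.character(pred))
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  mean(truth == pred)
}

# per-class F1 from a confusion matrix (square, shared label set)
.per_class_f1 <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Support-weighted F1 score
#'
#' Per-class F1 scores averaged with weights proportional to each class's
#' support in the ground truth (classes absent from the truth contribute
#' zero weight; classes with undefined precision or recall score 0).
#'
#' @param truth,pred label vectors of equal, positive length.
#' @return scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, pred) {
  truth <- trimws(as.character(truth)); pred <- trimws(as.character(pred))
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  classes <- sort(unique(c(truth, pred)))
  cm <- confusion_matrix(truth, pred, classes)
  f1 <- .per_class_f1(cm)
  support <- rowSums(cm)
  sum(f1 * support) / sum(support)
}

#' Confusion matrix of predicted vs true cell types
#'
#' Entry `(i, j)` counts cells with true type `i` predicted as type `j`.
#'
#' @param truth,pred label vectors.
#' @param classes label vocabulary (default: sorted union of both vectors).
#' @return C x C integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- trimws(as.character(truth)); pred <- trimws(as.character(pred))
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  classes <- classes %||% sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(truth = classes, pred = classes))
  m
}

#' Expression-profile correlation between predicted and reference types
#'
#' For every predicted type in the spatial data and every annotated type in
#' the reference, the Spearman rank correlation between their mean
#' `log1p(counts-per-10k)` expression profiles over the shared genes. A group
#' with a constant profile yields `NA` with a note.
#'
#' @param spatial spatial [expression_dataset].
#' @param pred predicted labels for the spatial cells.
#' @param reference labelled reference [expression_dataset].
#' @return matrix, rows = predicted types, columns = reference types.
#' @export
profile_spearman <- function(spatial, pred, reference) {
  stopifnot(inherits(spatial, "expression_dataset"),
            inherits(reference, "expression_dataset"))
  pred <- trimws(as.character(pred))
  if (length(pred) != nrow(spatial$counts))
    stop("pred length must match the spatial cell count")
  shared <- intersect(reference$gene_ids, spatial$gene_ids)
  if (length(shared) == 0) stop("no shared genes")
  prof <- function(counts, gene_ids, groups) {
    m <- as.matrix(counts)[, match(shared, gene_ids), drop = FALSE]
    cp10k <- m / pmax(rowSums(m), 1) * 1e4
    lgs <- sort(unique(groups))
    out <- vapply(lgs, function(g)
      colMeans(log1p(cp10k[groups == g, , drop = FALSE])), numeric(length(shared)))
    colnames(out) <- lgs
    out
  }
  ps <- prof(spatial$counts, spatial$gene_ids, pred)
  pr <- prof(reference$counts, reference$gene_ids, reference$labels)
  out <- matrix(NA_real_, ncol(ps), ncol(pr),
                dimnames = list(colnames(ps), colnames(pr)))
  for (i in seq_len(ncol(ps))) {
    if (stats::sd(ps[, i]) == 0) {
      message("profile_spearman: constant profile for predicted group '",
              colnames(ps)[i], "'; reporting NA")
      next
    }
    for (j in seq_len(ncol(pr))) {
      if (stats::sd(pr[, j]) == 0) {
        message("profile_spearman: constant profile for reference group '",
                colnames(pr)[j], "'; reporting NA")
        next
      }
      out[i, j] <- stats::cor(ps[, i], pr[, j], method = "spearman")
    }
  }
  out
}

#' Score predicted annotations against ground truth
#'
#' Bundles [accuracy_score()], [weighted_f1()], the per-class F1 vector and
#' the [confusion_matrix()] into one report.
#'
#' @param truth,pred label vectors.
#' @param classes label vocabulary (default: sorted union).
#' @return object of class `evaluation_report`: list with `accuracy`,
#'   `weighted_f1`, `per_class_f1`, `confusion`, `n`.
#' @export
evaluate_annotation <- function(truth, pred, classes = NULL) {
  cm <- confusion_matrix(truth, pred, classes)
  f1 <- .per_class_f1(cm)
  names(f1) <- rownames(cm)
  support <- rowSums(cm)
  structure(list(accuracy = accuracy_score(truth, pred),
                 weighted_f1 = sum(f1 * support) / sum(support),
                 per_class_f1 = f1, confusion = cm, n = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, accuracy = %.4f, weighted F1 = %.4f\n",
              x$n, x$accuracy, x$weighted_f1))
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 4))
  invisible(x)
}

#' Mean neighbour-label agreement over a spatial graph
#'
#' For every cell, the fraction of its graph neighbours sharing the cell's
#' label, averaged over cells (cells without neighbours are skipped). A
#' spatial-coherence statistic: higher means spatially smoother labels.
#'
#' @param labels per-cell labels.
#' @param g a [build_spatial_graph()] result over the same cells.
#' @return scalar in `[0, 1]`.
#' @export
neighbor_agreement <- function(labels, g) {
  stopifnot(inherits(g, "spatial_graph"))
  labels <- as.character(labels)
  a <- g$adjacency
  if (length(labels) != nrow(a)) stop("labels must match the graph size")
  trip <- Matrix::mat2triplet(a)
  same <- labels[trip$i] == labels[trip$j]
  agg <- tapply(same, trip$i, mean)
  mean(agg)
}
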