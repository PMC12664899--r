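#' Train the cell-type teacher on the annotated reference embedding
#'
#' Learns the mapping from the harmonized latent space to cell types on the
#' reference cells, to be distilled into the spatial student. The default
#' backend is a gradient-boosted tree ensemble (xgboost) with the softmax
#' multi-class objective in its probabilistic form (`multi:softprob`) and
#' tree-level dropout (DART booster). `k_n_fold`-fold cross-validation picks
#' the boosting-round count; the final model is refit on all reference cells
#' and the cross-validated accuracy is reported via `message()`.
#'
#' A linear multinomial-softmax backend (`backend = "linear"`) is available
#' as a lightweight alternative teacher.
#'
#' @param ssi reference [latent_embedding] (or plain matrix).
#' @param labels per-cell type labels, length matching the embedding rows.
#' @param k_n_fold number of cross-validation folds (default 5). Every class
#'   must have at least `k_n_fold` members.
#' @param seed RNG seed (deterministic training with `nthread = 1`).
#' @param backend `"xgboost"` (default) or `"linear"`.
#' @param nrounds maximum boosting rounds explored by cross-validation
#'   (default 150).
#' @param params named list overriding the default xgboost parameters
#'   (`eta = 0.3`, `max_depth = 6`, `rate_drop = 0.1`).
#' @return object of class `teacher_model` with elements `backend`, `fit`,
#'   `classes`, `k_n_fold`, `input_dim`, `cv_accuracy`, `nrounds`.
#' @seealso [predict_distribution()]
#' @export
train_teacher <- function(ssi, labels, k_n_fold = 5, seed = 0,
                          backend = c("xgboost", "linear"), nrounds = 150,
                          params = list()) {
  backend <- match.arg(backend)
  xm <- .emb_values(ssi)
  labels <- trimws(as.character(labels))
  if (length(labels) != nrow(xm))
    stop("`labels` length must match the embedding rows")
  classes <- sort(unique(labels))
  nc <- length(classes)
  if (nc < 2) stop("need at least 2 cell-type classes; got ", nc)
  tab <- table(labels)
  if (any(tab < k_n_fold))
    stop("class(es) ", paste(names(tab)[tab < k_n_fold], collapse = ", "),
         " have fewer than k_n_fold = ", k_n_fold,
         " members; merge or drop them before training")
  y <- as.integer(factor(labels, levels = classes)) - 1L

  if (backend == "linear") {
    set.seed(seed)
    df <- data.frame(.y = factor(labels, levels = classes), xm)
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                          MaxNWts = 1e6, maxit = 200)
    cv_acc <- NA_real_
    best <- NA_integer_
  } else {
    defaults <- list(objective = "multi:softprob", num_class = nc,
                     booster = "dart", rate_drop = 0.1, eta = 0.3,
                     max_depth = 6, nthread = 1, seed = seed)
    par <- utils::modifyList(defaults, params)
    dm <- xgboost::xgb.DMatrix(xm, label = y)
    set.seed(seed)
    cv <- xgboost::xgb.cv(params = par, data = dm, nrounds = nrounds,
                          nfold = k_n_fold, metrics = list("mlogloss", "merror"),
                          early_stopping_rounds = 15, stratified = TRUE,
                          verbose = 0)
    log <- cv$evaluation_log
    best <- cv$best_iteration %||% which.min(log$test_mlogloss_mean)
    cv_acc <- 1 - log$test_merror_mean[best]
    message(sprintf(
      "teacher: %d classes, %d-fold CV accuracy %.4f at %d rounds",
      nc, k_n_fold, cv_acc, best))
    set.seed(seed)
    fit <- xgboost::xgb.train(params = par, data = dm, nrounds = best,
                              verbose = 0)
  }
  structure(list(backend = backend, fit = fit, classes = classes,
                 k_n_fold = k_n_fold, input_dim = ncol(xm),
                 cv_accuracy = cv_acc, nrounds = best),
            class = "teacher_model")
}

#' @export
print.teacher_model <- function(x, ...) {
  cat(sprintf("<teacher_model> %s, %d classes, input dim %d",
              x$backend, length(x$classes), x$input_dim))
  if (!is.na(x$cv_accuracy))
    cat(sprintf(", CV accuracy %.3f", x$cv_accuracy))
  cat("\n")
  invisible(x)
}

#' Predict the teacher distribution for spatial cells
#'
#' Applies the trained teacher to the spatial embedding, returning a
#' row-stochastic cells-by-classes probability matrix (the distillation
#' target of the graph annotator).
#'
#' @param model a [train_teacher()] result.
#' @param tti spatial [latent_embedding] (or matrix) with the teacher's
#'   training dimensionality.
#' @return object of class `teacher_distribution`: list with `probs`
#'   (n x C, rows summing to 1), `classes`, `cell_ids`.
#' @export
predict_distribution <- function(model, tti) {
  stopifnot(inherits(model, "teacher_model"))
  xm <- .emb_values(tti)
  if (ncol(xm) != model$input_dim)
    stop("embedding has ", ncol(xm), " dims but the teacher was trained on ",
         model$input_dim)
  nc <- length(model$classes)
  if (model$backend == "linear") {
    p <- stats::predict(model$fit, newdata = data.frame(xm), type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p)  # 2-class multinom returns a vector
  } else {
    p <- stats::predict(model$fit, xgboost::xgb.DMatrix(xm))
    if (is.null(dim(p))) p <- matrix(p, ncol = nc, byrow = TRUE)
  }
  p <- pmin(pmax(p, 0), 1)
  p <- p / rowSums(p)
  dimnames(p) <- NULL
  ids <- if (inherits(tti, "latent_embedding")) tti$cell_ids
         else rownames(xm) %||% paste0("cell_", seq_len(nrow(xm)))
  structure(list(probs = p, classes = model$classes, cell_ids = ids),
            class = "teacher_distribution")
}

#' @export
print.teacher_distribution <- function(x, ...) {
  cat(sprintf("<teacher_distribution> %d cells x %d classes\n",
              nrow(x$probs), length(x$classes)))
  invisible(x)
}

#' Hard labels from a probability matrix
#'
#' Row-wise argmax with ties broken toward the lowest class index.
#'
#' @param dist a `teacher_distribution`, or a probability matrix.
#' @param classes class names (taken from `dist` when available).
#' @return character vector of labels.
#' @export
argmax_labels <- function(dist, classes = NULL) {
  if (inherits(dist, "teacher_distribution")) {
    classes <- dist$classes
    p <- dist$probs
  } else {
    p <- as.matrix(dist)
    classes <- classes %||% colnames(p) %||% paste0("class_", seq_len(ncol(p)))
  }
  classes[max.col(p, ties.method = "first")]
}
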