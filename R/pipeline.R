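#' Pipeline configuration
#'
#' Bundles the per-stage settings of the end-to-end annotation transfer. One
#' global `seed` fans out to per-stage seeds by fixed offsets (+1 VAE, +2
#' teacher, +3 annotator), recorded in the run manifest.
#'
#' @param label_key reference metadata column holding cell types (used when
#'   reading from disk; default `"cell_type"`).
#' @param vae a [vae_config()].
#' @param use_vae set `FALSE` to ablate the VAE: embeddings come from
#'   [joint_logcount_pca()] instead (default `TRUE`).
#' @param k_n_fold teacher cross-validation folds (default 5).
#' @param teacher_backend `"xgboost"` or `"linear"`.
#' @param k_neighbors spatial-graph neighbours (default 30).
#' @param theta spatial kernel decay, or `"auto"` (default).
#' @param annotator an [annotator_config()].
#' @param min_shared gene-alignment warning threshold (default 50).
#' @param seed global seed (default 0).
#' @param out_dir optional output directory: predictions TSV, report JSON
#'   and run manifest are written there.
#' @param cache_dir optional cache directory: VAE embeddings are saved there
#'   and reused on rerun, skipping the integration stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(label_key = "cell_type", vae = vae_config(),
                            use_vae = TRUE, k_n_fold = 5,
                            teacher_backend = "xgboost", k_neighbors = 30,
                            theta = "auto", annotator = annotator_config(),
                            min_shared = 50, seed = 0, out_dir = NULL,
                            cache_dir = NULL) {
  stopifnot(inherits(vae, "vae_config"), inherits(annotator, "annotator_config"))
  structure(list(label_key = label_key, vae = vae, use_vae = use_vae,
                 k_n_fold = k_n_fold, teacher_backend = teacher_backend,
                 k_neighbors = k_neighbors, theta = theta,
                 annotator = annotator, min_shared = min_shared, seed = seed,
                 out_dir = out_dir, cache_dir = cache_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full annotation-transfer pipeline
#'
#' Executes the five steps end to end: gene alignment, VAE batch
#' harmonization (or the PCA ablation), teacher training and prediction,
#' spatial-graph construction, graph-annotator training, and final label
#' prediction. If the spatial dataset carries ground-truth labels, an
#' [evaluate_annotation()] report is appended.
#'
#' @param ref reference [expression_dataset] (or a dataset-directory path).
#' @param spatial spatial [expression_dataset] (or a path).
#' @param config a [pipeline_config()].
#' @param verbose print stage progress (default `TRUE`).
#' @return object of class `pipeline_result`: list with `labels`, `probs`,
#'   `teacher_labels`, `teacher`, `embeddings`, `graph`, `state`, `report`
#'   (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(ref, spatial, config = pipeline_config(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  if (is.character(ref))
    ref <- .stage("read", read_expression_dataset(ref, "reference",
                                                  config$label_key))
  if (is.character(spatial))
    spatial <- .stage("read", read_expression_dataset(spatial, "spatial",
                                                      config$label_key))

  say("stage align: matching shared genes")
  al <- .stage("align", align_genes(ref, spatial, config$min_shared))

  cache_file <- if (!is.null(config$cache_dir))
    file.path(config$cache_dir, "embeddings.rds")
  emb <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    emb <- readRDS(cache_file)
    if (!identical(emb$spatial$cell_ids, al$spatial$cell_ids) ||
        !identical(emb$reference$cell_ids, al$reference$cell_ids)) {
      emb <- NULL
    } else say("stage integrate: reusing cached embeddings")
  }
  vae <- NULL
  if (is.null(emb)) {
    if (config$use_vae) {
      say("stage integrate: training the batch-harmonizing VAE")
      vcfg <- config$vae; vcfg$seed <- config$seed + 1
      vae <- .stage("integrate", fit_vae(al$reference, al$spatial, vcfg))
      emb <- list(reference = encode_cells(vae, al$reference),
                  spatial = encode_cells(vae, al$spatial))
    } else {
      say("stage integrate: VAE ablated, using joint log-count PCA")
      emb <- .stage("integrate",
                    joint_logcount_pca(al$reference, al$spatial,
                                       dim = config$vae$latent_dim))
    }
    if (!is.null(cache_file)) {
      dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(emb, cache_file)
    }
  }

  say("stage teach: training the teacher classifier")
  teacher <- .stage("teach", {
    if (is.null(al$reference$labels))
      stop("reference has no labels under label_key '", config$label_key, "'")
    train_teacher(emb$reference, al$reference$labels,
                  k_n_fold = config$k_n_fold, seed = config$seed + 2,
                  backend = config$teacher_backend)
  })
  d <- .stage("teach", predict_distribution(teacher, emb$spatial))

  say("stage graph: building the spatial neighbour graph")
  graph <- .stage("graph", {
    g <- build_spatial_graph(al$spatial$coords, config$k_neighbors,
                             config$theta)
    normalize_adjacency(g)
  })

  say("stage annotate: training the graph annotator")
  acfg <- config$annotator; acfg$seed <- config$seed + 3
  state <- .stage("annotate",
                  train_annotator(emb$spatial, graph, d, acfg))
  pred <- .stage("annotate", predict_labels(state, emb$spatial, graph))

  report <- NULL
  if (!is.null(al$spatial$labels))
    report <- evaluate_annotation(al$spatial$labels, pred$labels)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stgraft")),
    seed = config$seed,
    stage_seeds = list(vae = config$seed + 1, teacher = config$seed + 2,
                       annotator = config$seed + 3),
    use_vae = config$use_vae,
    n_reference = nrow(al$reference$counts),
    n_spatial = nrow(al$spatial$counts),
    n_shared_genes = length(al$reference$gene_ids),
    k_neighbors = config$k_neighbors, theta = graph$theta,
    vae = unclass(config$vae), annotator = unclass(acfg),
    k_n_fold = config$k_n_fold)

  res <- structure(list(labels = pred$labels, probs = pred$probs,
                        teacher_labels = argmax_labels(d), teacher = teacher,
                        embeddings = emb, graph = graph, state = state,
                        vae = vae, report = report, manifest = manifest,
                        cell_ids = al$spatial$cell_ids),
                   class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(cell_id = res$cell_ids, predicted = res$labels,
                 teacher = res$teacher_labels, round(res$probs, 6),
                 check.names = FALSE),
      file.path(config$out_dir, "predictions.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(report))
      jsonlite::write_json(
        list(accuracy = report$accuracy, weighted_f1 = report$weighted_f1,
             per_class_f1 = as.list(report$per_class_f1)),
        file.path(config$out_dir, "report.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d spatial cells, %d classes\n",
              length(x$labels), ncol(x$probs)))
  if (!is.null(x$report))
    cat(sprintf("  accuracy %.4f, weighted F1 %.4f\n",
                x$report$accuracy, x$report$weighted_f1))
  invisible(x)
}
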