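#' Specification of the synthetic single-cell reference
#'
#' The synthetic reference emulates an annotated scRNA-seq dataset with `K`
#' well-separated cell types plus one background type: overdispersed
#' negative-binomial counts, each non-background type overexpressing a
#' disjoint block of signature genes by a common fold change, and a flat
#' (signature-free) background profile. Per-gene baseline abundances are
#' lognormal; per-type gene proportions are renormalized so all cells share
#' the same expected sequencing depth.
#'
#' @param n_types non-background cell types (default 4; a background type is
#'   always added).
#' @param cells_per_type cells per type, background included (default 1000).
#' @param n_genes genes (default 500).
#' @param signature_genes_per_type disjoint signature genes per type
#'   (default 25).
#' @param signature_fold_change fold change of signature genes (default 4).
#' @param dispersion negative-binomial size (inverse dispersion; default 2).
#' @param depth_mean expected counts per cell (default 2000).
#' @param batch_shift_sd sd of the log-normal per-gene multiplicative shift
#'   applied to the spatial modality by [make_pseudo_st()] (default 0.3).
#' @param seed RNG seed.
#' @return object of class `synthetic_reference_spec`.
#' @export
synthetic_reference_spec <- function(n_types = 4, cells_per_type = 1000,
                                     n_genes = 500,
                                     signature_genes_per_type = 25,
                                     signature_fold_change = 4,
                                     dispersion = 2, depth_mean = 2000,
                                     batch_shift_sd = 0.3, seed = 0) {
  stopifnot(n_types >= 1, cells_per_type >= 1, n_genes >= 1,
            signature_genes_per_type >= 1, signature_fold_change > 1,
            dispersion > 0, depth_mean > 0, batch_shift_sd >= 0)
  if (signature_genes_per_type * n_types > n_genes)
    stop("signature_genes_per_type * n_types exceeds n_genes; ",
         "signature sets must be disjoint")
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 n_genes = n_genes,
                 signature_genes_per_type = signature_genes_per_type,
                 signature_fold_change = signature_fold_change,
                 dispersion = dispersion, depth_mean = depth_mean,
                 batch_shift_sd = batch_shift_sd, seed = seed),
            class = "synthetic_reference_spec")
}

#' Generate the synthetic annotated reference
#'
#' @param spec a [synthetic_reference_spec()].
#' @return a labelled reference [expression_dataset] with
#'   `(n_types + 1) * cells_per_type` cells. The signature gene indices per
#'   type are stored in `attr(, "signatures")`.
#' @examples
#' ref <- make_synthetic_reference(synthetic_reference_spec(
#'   n_types = 2, cells_per_type = 20, n_genes = 40,
#'   signature_genes_per_type = 5, depth_mean = 200))
#' table(ref$labels)
#' @export
make_synthetic_reference <- function(spec = synthetic_reference_spec()) {
  stopifnot(inherits(spec, "synthetic_reference_spec"))
  set.seed(spec$seed)
  d <- spec$n_genes
  types <- c(paste0("type", seq_len(spec$n_types)), "background")
  base <- stats::rlnorm(d, meanlog = 0, sdlog = 1)
  sig <- lapply(seq_len(spec$n_types), function(t)
    ((t - 1) * spec$signature_genes_per_type + 1):(t * spec$signature_genes_per_type))
  names(sig) <- types[seq_len(spec$n_types)]
  n_per <- spec$cells_per_type
  n <- n_per * length(types)
  counts <- matrix(0, n, d)
  labels <- rep(types, each = n_per)
  for (t in seq_along(types)) {
    w <- base
    if (t <= spec$n_types) w[sig[[t]]] <- w[sig[[t]]] * spec$signature_fold_change
    mu <- spec$depth_mean * w / sum(w)
    rows <- ((t - 1) * n_per + 1):(t * n_per)
    counts[rows, ] <- matrix(
      stats::rnbinom(n_per * d, size = spec$dispersion,
                     mu = rep(mu, each = n_per)),
      n_per, d)
  }
  ds <- expression_dataset(counts,
                           gene_ids = sprintf("gene_%03d", seq_len(d)),
                           cell_ids = sprintf("ref_%05d", seq_len(n)),
                           labels = labels, role = "reference")
  attr(ds, "signatures") <- sig
  attr(ds, "spec") <- spec
  ds
}

#' Pseudo spatial-transcriptomics layout
#'
#' The two benchmark layouts: `"hierarchical"` confines each non-background
#' type to a distinct unit-height horizontal row (rows stacked on
#' `[0,4] x [0,4]`) with 400 background cells dispersed uniformly over the
#' four rows; `"block"` confines each type to a distinct 100 x 100 square
#' (the four quadrants of a 200 x 200 field) with 300 uniformly dispersed
#' background cells.
#'
#' @param kind `"hierarchical"` or `"block"`.
#' @param cells_per_type non-background cells per type (default 1000).
#' @param n_background background cells (default 400 hierarchical, 300
#'   block).
#' @return object of class `pseudo_layout`.
#' @export
pseudo_layout <- function(kind = c("hierarchical", "block"),
                          cells_per_type = 1000, n_background = NULL) {
  kind <- match.arg(kind)
  n_background <- n_background %||% if (kind == "hierarchical") 400 else 300
  structure(list(kind = kind, n_nonbg_types = 4,
                 cells_per_nonbg_type = cells_per_type,
                 n_background = n_background),
            class = "pseudo_layout")
}

# uniform coordinates inside region r of a layout
.layout_coords <- function(layout, region, m) {
  if (layout$kind == "hierarchical") {
    cbind(x = stats::runif(m, 0, 4), y = stats::runif(m, region - 1, region))
  } else {
    off <- list(c(0, 0), c(100, 0), c(0, 100), c(100, 100))[[region]]
    cbind(x = stats::runif(m, off[1], off[1] + 100),
          y = stats::runif(m, off[2], off[2] + 100))
  }
}

#' Generate a pseudo spatial-transcriptomics dataset
#'
#' Builds a spatial dataset by sampling expression rows with replacement from
#' the reference cells of each type: every non-background type is confined to
#' its own region of the layout, background cells are placed uniformly across
#' all four regions, and a per-gene multiplicative log-normal batch shift
#' (counts rounded back to integers) is applied to the spatial modality. The
#' sampled source row indices, batch factors and region assignments are kept
#' as attributes, and the true type of every cell is stored in `labels` as
#' evaluation ground truth.
#'
#' @param reference a labelled reference [expression_dataset] whose labels
#'   include `type1..type4` and `background` (e.g.
#'   [make_synthetic_reference()]).
#' @param layout a [pseudo_layout()].
#' @param seed RNG seed.
#' @param batch_shift_sd log-scale sd of the per-gene shift; defaults to the
#'   generating spec's value when the reference carries one, else 0.3.
#' @return a spatial [expression_dataset] with ground-truth labels.
#' @export
make_pseudo_st <- function(reference, layout = pseudo_layout(), seed = 0,
                           batch_shift_sd = NULL) {
  stopifnot(inherits(reference, "expression_dataset"),
            inherits(layout, "pseudo_layout"))
  batch_shift_sd <- batch_shift_sd %||%
    (attr(reference, "spec")$batch_shift_sd %||% 0.3)
  types <- paste0("type", seq_len(layout$n_nonbg_types))
  need <- c(types, "background")
  missing <- setdiff(need, unique(reference$labels))
  if (length(missing) > 0)
    stop("reference is missing required type(s): ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  d <- length(reference$gene_ids)
  fac <- stats::rlnorm(d, meanlog = 0, sdlog = batch_shift_sd)

  src <- integer(0); labs <- character(0); regions <- integer(0)
  coords <- matrix(0, 0, 2)
  for (t in seq_along(types)) {
    pool <- which(reference$labels == types[t])
    m <- layout$cells_per_nonbg_type
    src <- c(src, sample(pool, m, replace = TRUE))
    labs <- c(labs, rep(types[t], m))
    regions <- c(regions, rep(t, m))
    coords <- rbind(coords, .layout_coords(layout, t, m))
  }
  bg_pool <- which(reference$labels == "background")
  nb <- layout$n_background
  bg_region <- sample.int(layout$n_nonbg_types, nb, replace = TRUE)
  src <- c(src, sample(bg_pool, nb, replace = TRUE))
  labs <- c(labs, rep("background", nb))
  regions <- c(regions, bg_region)
  bg_coords <- matrix(0, nb, 2)
  for (r in seq_len(layout$n_nonbg_types)) {
    idx <- which(bg_region == r)
    if (length(idx) > 0)
      bg_coords[idx, ] <- .layout_coords(layout, r, length(idx))
  }
  coords <- rbind(coords, bg_coords)

  counts <- as.matrix(reference$counts)[src, , drop = FALSE]
  counts <- round(counts * rep(fac, each = nrow(counts)))
  ds <- expression_dataset(counts, gene_ids = reference$gene_ids,
                           cell_ids = sprintf("st_%05d", seq_along(src)),
                           coords = coords, labels = labs, role = "spatial")
  attr(ds, "source_index") <- src
  attr(ds, "batch_factor") <- fac
  attr(ds, "region") <- regions
  attr(ds, "layout") <- layout
  ds
}
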