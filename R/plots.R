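#' Spatial scatter plot of cell labels
#'
#' One point per cell at its spatial position, coloured by label — the usual
#' way to eyeball predicted (or ground-truth) cell types on a tissue section.
#'
#' @param x a spatial [expression_dataset], a [build_spatial_graph()] result,
#'   or an n x 2 coordinate matrix.
#' @param labels per-cell labels (defaults to the dataset's labels).
#' @param point_size point size (default 0.8).
#' @return a `ggplot` object.
#' @export
plot_spatial_labels <- function(x, labels = NULL, point_size = 0.8) {
  coords <- if (inherits(x, "expression_dataset")) x$coords
            else if (inherits(x, "spatial_graph")) x$coords
            else as.matrix(x)
  if (is.null(coords)) stop("no coordinates to plot")
  labels <- labels %||% if (inherits(x, "expression_dataset")) x$labels
  if (is.null(labels)) stop("no labels to plot")
  df <- data.frame(x = coords[, 1], y = coords[, 2],
                   label = as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = label)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "cell type") +
    ggplot2::theme_minimal()
}

#' Loss trajectory of a trained annotator or VAE
#'
#' @param x a trained `annotator_state` or `vae_model`.
#' @return a `ggplot` object of per-epoch losses.
#' @export
plot_loss_history <- function(x) {
  h <- if (inherits(x, "annotator_state")) {
    if (is.null(x$history)) stop("no training history; train first")
    data.frame(epoch = rep(x$history$epoch, 4),
               loss = c(x$history$l_ae, x$history$l_gae, x$history$l_ssl,
                        x$history$total),
               term = rep(c("l_ae", "l_gae", "l_ssl", "total"),
                          each = nrow(x$history)))
  } else if (inherits(x, "vae_model")) {
    data.frame(epoch = x$history$epoch, loss = x$history$loss, term = "elbo")
  } else stop("expected an annotator_state or vae_model")
  ggplot2::ggplot(h, ggplot2::aes(x = epoch, y = loss,
                                  colour = term)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}
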