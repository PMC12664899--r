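# GAE loss + gradient with respect to Z, exact dense mode (small graphs).
# targets: dense n x n matrix in [0,1]; wpos: weight on positive entries.
.gae_exact_grad <- function(targets, z, wpos) {
  n <- nrow(targets)
  s <- tcrossprod(z)
  w <- matrix(1, n, n)
  w[targets > 0] <- wpos
  loss <- sum(.bce_logits(targets, s, w)) / n^2
  dS <- w * (.sigmoid(s) - targets) / n^2
  list(loss = loss, dz = (dS + t(dS)) %*% z)
}

# Stratified sampled mode: positives enumerated, negatives sampled.
# trip: triplet list of the sparse target (i, j, x). Draws from current RNG.
.gae_sampled_grad <- function(trip, n, z, wpos, n_neg) {
  npos <- length(trip$x)
  s_pos <- rowSums(z[trip$i, , drop = FALSE] * z[trip$j, , drop = FALSE])
  pos_loss <- sum(.bce_logits(trip$x, s_pos, wpos)) / n^2
  c_pos <- wpos * (.sigmoid(s_pos) - trip$x) / n^2
  neg <- .sample_zero_pairs(trip, n, n_neg)
  s_neg <- rowSums(z[neg$i, , drop = FALSE] * z[neg$j, , drop = FALSE])
  scale_neg <- (n^2 - npos) / n^2
  neg_loss <- scale_neg * mean(.bce_logits(0, s_neg))
  c_neg <- scale_neg * .sigmoid(s_neg) / n_neg
  cm <- Matrix::sparseMatrix(i = c(trip$i, neg$i), j = c(trip$j, neg$j),
                             x = c(c_pos, c_neg), dims = c(n, n))
  dz <- as.matrix(cm %*% z + Matrix::crossprod(cm, z))
  list(loss = pos_loss + neg_loss, dz = dz)
}

#' Train the dual autoencoder / graph-autoencoder annotator
#'
#' Full-batch gradient training of the total loss
#' `w_dae * L_AE + w_gae * L_GAE + w_cls * L_SSL`: the autoencoder
#' reconstructs the spatial embedding (MSE), the graph autoencoder
#' reconstructs the spatial adjacency from the fused latent
#' `Z = X + S` via the inner-product decoder (binary cross-entropy, positive
#' entries class-balanced), and the linear-softmax student is distilled
#' against the frozen teacher distribution. Optimized with Adam; the loss
#' trajectory is recorded per epoch. Deterministic for a fixed seed under
#' single-threaded execution.
#'
#' For graphs above `cfg$subsample_threshold` cells the GAE term uses the
#' stratified sampled estimator (all positive edges plus uniformly sampled
#' zero pairs, redrawn each epoch).
#'
#' @param tti spatial [latent_embedding] (or matrix).
#' @param g [build_spatial_graph()] result over the same cells.
#' @param d frozen teacher distribution ([predict_distribution()] result).
#' @param cfg an [annotator_config()].
#' @param state optional pre-initialized [init_annotator_state()] (defaults
#'   to a fresh state seeded by `cfg$seed`).
#' @param verbose print the loss every 50 epochs (default `FALSE`).
#' @return a trained `annotator_state`; `$history` holds the per-epoch
#'   `l_ae`, `l_gae`, `l_ssl` and `total` trajectory.
#' @seealso [predict_labels()]
#' @export
train_annotator <- function(tti, g, d, cfg = annotator_config(), state = NULL,
                            verbose = FALSE) {
  x_in <- .emb_values(tti)
  stopifnot(inherits(g, "spatial_graph"), inherits(cfg, "annotator_config"))
  if (inherits(d, "teacher_distribution")) {
    classes <- d$classes
    dmat <- d$probs
  } else {
    dmat <- as.matrix(d)
    classes <- colnames(dmat) %||% paste0("class_", seq_len(ncol(dmat)))
  }
  n <- nrow(x_in)
  if (nrow(g$adjacency) != n || nrow(dmat) != n)
    stop("embedding rows, graph size and teacher rows must all match")
  if (is.null(g$normalized)) g <- normalize_adjacency(g)

  set.seed(cfg$seed)
  if (is.null(state)) state <- init_annotator_state(ncol(x_in), classes, cfg)
  layers <- .annotator_layers(state)
  nc <- length(state$classes)

  # adjacency targets
  a <- as(as(g$adjacency, "CsparseMatrix"), "generalMatrix")
  trip <- Matrix::mat2triplet(a)
  if (cfg$gae_target == "binary") trip$x <- rep(1, length(trip$x))
  npos <- length(trip$x)
  wpos <- if (identical(cfg$pos_weight, "balanced")) (n^2 - npos) / max(1, npos)
          else as.numeric(cfg$pos_weight)
  exact <- n <= cfg$subsample_threshold
  if (exact) {
    targets <- matrix(0, n, n)
    targets[cbind(trip$i, trip$j)] <- trip$x
  }
  n_neg <- cfg$n_negative %||% npos

  hist <- matrix(NA_real_, cfg$epochs, 4,
                 dimnames = list(NULL, c("l_ae", "l_gae", "l_ssl", "total")))
  nd <- length(x_in)
  for (epoch in seq_len(cfg$epochs)) {
    x_lat <- ae_encode(x_in, state, training = TRUE)
    rec <- ae_decode(x_lat, state, training = TRUE)
    s_lat <- graph_encode(x_lat, g, state, training = TRUE)
    z <- x_lat + s_lat
    gae <- if (exact) .gae_exact_grad(targets, z, wpos)
           else .gae_sampled_grad(trip, n, z, wpos, n_neg)
    logits <- .lin_fwd(state$student, z)
    p <- .softmax_rows(logits)
    l_ae <- mean((x_in - rec)^2)
    l_ssl <- -sum(dmat * log(pmax(p, 1e-12))) / (n * nc)
    l_tot <- cfg$w_dae * l_ae + cfg$w_gae * gae$loss + cfg$w_cls * l_ssl
    if (!is.finite(l_tot))
      stop(sprintf(
        "annotator loss became NaN at epoch %d (learning_rate %.3g); %s",
        epoch, cfg$learning_rate, "reduce the learning rate or loss weights"))
    hist[epoch, ] <- c(l_ae, gae$loss, l_ssl, l_tot)

    # backward: Z feeds the GAE decoder and the student; X feeds the
    # AE decoder, the graph encoder, and Z directly.
    dlogits <- cfg$w_cls * (p - dmat) / (n * nc)
    dz <- cfg$w_gae * gae$dz + .lin_bwd(state$student, dlogits)
    drec <- cfg$w_dae * 2 * (rec - x_in) / nd
    dx <- .ae_decode_bwd(state, drec) + .graph_encode_bwd(state, dz, g) + dz
    .ae_encode_bwd(state, dx)
    .adam_step(layers, cfg$learning_rate, epoch)
    if (verbose && epoch %% 50 == 0)
      message(sprintf("annotator epoch %d: total %.4f (ae %.4f gae %.4f ssl %.4f)",
                      epoch, l_tot, l_ae, gae$loss, l_ssl))
  }
  state$trained <- TRUE
  state$history <- as.data.frame(hist)
  state$history$epoch <- seq_len(cfg$epochs)
  state
}

#' Predict final cell types for spatial cells
#'
#' Evaluation-mode forward pass (dropout off, batch norm on running
#' statistics): re-encodes the spatial embedding and the graph into the fused
#' latent `Z` and applies the student head. Labels are the row-wise argmax of
#' `softmax(Z W_student + b_student)`, ties broken toward the lowest class
#' index; repeated calls are identical.
#'
#' @param state a trained `annotator_state`.
#' @param tti spatial [latent_embedding] (or matrix).
#' @param g the spatial graph used in training.
#' @return list with `labels` (character, length n) and `probs`
#'   (row-stochastic n x C matrix with class columns).
#' @export
predict_labels <- function(state, tti, g) {
  stopifnot(inherits(state, "annotator_state"))
  if (!state$trained)
    stop("annotator state is untrained; run train_annotator() first")
  x_lat <- ae_encode(tti, state, training = FALSE)
  s_lat <- graph_encode(x_lat, g, state, training = FALSE)
  z <- x_lat + s_lat
  p <- .softmax_rows(.lin_fwd(state$student, z))
  colnames(p) <- state$classes
  list(labels = state$classes[max.col(p, ties.method = "first")], probs = p)
}
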