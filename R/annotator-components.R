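#' Annotator configuration
#'
#' Hyperparameters of the dual autoencoder / graph-autoencoder annotator.
#' The loss weights follow the `w_cls` / `w_dae` / `w_gae` naming: they weight
#' the teacher-distillation cross-entropy, the expression reconstruction MSE
#' and the adjacency reconstruction BCE in the total loss.
#'
#' @param k1 autoencoder hidden width (default 128).
#' @param k autoencoder latent width (default 30, matching the VAE latent so
#'   that the fusion `Z = X + S` is well-typed).
#' @param dropout_p dropout probability in `[0, 1)` (default 0.2).
#' @param epochs full-batch training epochs (default 200).
#' @param w_cls distillation loss weight (default 20).
#' @param w_dae expression reconstruction loss weight (default 1).
#' @param w_gae adjacency reconstruction loss weight (default 1).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed RNG seed.
#' @param use_batchnorm apply batch normalization after each fully connected
#'   layer (default `TRUE`, per the architecture; `FALSE` bypasses it).
#' @param gae_target `"binary"` (edge present = 1, the default) or `"kernel"`
#'   (Gaussian kernel weights as Bernoulli targets).
#' @param pos_weight weight on positive adjacency entries in the GAE loss:
#'   `"balanced"` (default, `(n^2 - npos)/npos`) or a positive number.
#' @param subsample_threshold above this many cells the GAE loss is the
#'   stratified positive-enumeration / negative-sampling estimator instead of
#'   the exact n^2 double sum (default 2000).
#' @param n_negative negative pairs sampled per epoch in subsampled mode
#'   (default: the number of positive entries).
#' @return object of class `annotator_config`.
#' @export
annotator_config <- function(k1 = 128, k = 30, dropout_p = 0.2, epochs = 200,
                             w_cls = 20, w_dae = 1, w_gae = 1,
                             learning_rate = 1e-3, seed = 0,
                             use_batchnorm = TRUE,
                             gae_target = c("binary", "kernel"),
                             pos_weight = "balanced",
                             subsample_threshold = 2000, n_negative = NULL) {
  gae_target <- match.arg(gae_target)
  stopifnot(k1 >= 1, k >= 1, dropout_p >= 0, dropout_p < 1, epochs >= 1,
            w_cls >= 0, w_dae >= 0, w_gae >= 0, learning_rate > 0)
  if (k > k1) stop("`k` must not exceed the hidden width `k1`")
  if (w_cls + w_dae + w_gae <= 0)
    stop("at least one of w_cls, w_dae, w_gae must be positive")
  structure(list(k1 = k1, k = k, dropout_p = dropout_p, epochs = epochs,
                 w_cls = w_cls, w_dae = w_dae, w_gae = w_gae,
                 learning_rate = learning_rate, seed = seed,
                 use_batchnorm = use_batchnorm, gae_target = gae_target,
                 pos_weight = pos_weight,
                 subsample_threshold = subsample_threshold,
                 n_negative = n_negative),
            class = "annotator_config")
}

#' Initialize an untrained annotator state
#'
#' Allocates all learnable parameters: the two-layer autoencoder encoder
#' (FC -> BN -> ELU -> dropout, twice), the mirrored decoder (one hidden
#' block plus a final linear map), the two sparse graph-convolution layers,
#' and the linear-softmax student head.
#'
#' @param input_dim dimensionality `d` of the embedding fed to the
#'   autoencoder (the VAE latent width).
#' @param classes character vector of cell-type names (length >= 2).
#' @param cfg an [annotator_config()].
#' @return object of class `annotator_state`.
#' @export
init_annotator_state <- function(input_dim, classes, cfg = annotator_config()) {
  stopifnot(inherits(cfg, "annotator_config"), input_dim >= 1)
  classes <- as.character(classes)
  if (length(classes) < 2) stop("need at least 2 classes")
  set.seed(cfg$seed)
  k1 <- cfg$k1; k <- cfg$k
  st <- list(
    enc1 = .nn_linear(input_dim, k1), bn1 = .nn_bn(k1),
    enc2 = .nn_linear(k1, k), bn2 = .nn_bn(k),
    dec1 = .nn_linear(k, k1), bn_d = .nn_bn(k1),
    dec2 = .nn_linear(k1, input_dim),
    gcn1 = .nn_gcn(k, k), gcn2 = .nn_gcn(k, k),
    student = .nn_linear(k, length(classes), scale = 0.01),
    cache = list(e1 = .nn_env(), dr1 = .nn_env(), e2 = .nn_env(),
                 dr2 = .nn_env(), de = .nn_env(), dd = .nn_env(),
                 gr = .nn_env(), gd = .nn_env()),
    cfg = cfg, input_dim = input_dim, classes = classes, trained = FALSE)
  class(st) <- "annotator_state"
  st
}

#' @export
print.annotator_state <- function(x, ...) {
  cat(sprintf("<annotator_state> d = %d, k1 = %d, k = %d, %d classes, %s\n",
              x$input_dim, x$cfg$k1, x$cfg$k, length(x$classes),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.annotator_layers <- function(state) {
  ls <- list(state$enc1, state$enc2, state$dec1, state$dec2,
             state$gcn1, state$gcn2, state$student)
  if (state$cfg$use_batchnorm)
    ls <- c(ls, list(state$bn1, state$bn2, state$bn_d))
  ls
}

# --- component forward/backward passes --------------------------------------

#' Autoencoder encoder: embedding to latent X
#'
#' Two FC -> batch-norm -> ELU -> dropout blocks mapping the cells-by-`d`
#' spatial embedding to the `k`-dimensional latent `X`. Dropout is active
#' only when `training = TRUE`; batch norm uses batch statistics in training
#' and running statistics otherwise, so evaluation calls are deterministic.
#'
#' @param tti spatial [latent_embedding] or matrix (n x d).
#' @param state an [init_annotator_state()] result.
#' @param training logical training flag.
#' @return n x k matrix `X`.
#' @export
ae_encode <- function(tti, state, training = FALSE) {
  x <- .emb_values(tti)
  if (ncol(x) != state$input_dim)
    stop("input has ", ncol(x), " dims; annotator expects ", state$input_dim)
  cfg <- state$cfg; ch <- state$cache
  h <- .lin_fwd(state$enc1, x)
  if (cfg$use_batchnorm) h <- .bn_fwd(state$bn1, h, training)
  h <- .drop_fwd(ch$dr1, .elu_fwd(ch$e1, h), cfg$dropout_p, training)
  h <- .lin_fwd(state$enc2, h)
  if (cfg$use_batchnorm) h <- .bn_fwd(state$bn2, h, training)
  .drop_fwd(ch$dr2, .elu_fwd(ch$e2, h), cfg$dropout_p, training)
}

.ae_encode_bwd <- function(state, g) {
  cfg <- state$cfg; ch <- state$cache
  g <- .elu_bwd(ch$e2, .drop_bwd(ch$dr2, g))
  if (cfg$use_batchnorm) g <- .bn_bwd(state$bn2, g)
  g <- .lin_bwd(state$enc2, g)
  g <- .elu_bwd(ch$e1, .drop_bwd(ch$dr1, g))
  if (cfg$use_batchnorm) g <- .bn_bwd(state$bn1, g)
  .lin_bwd(state$enc1, g)
}

#' Autoencoder decoder: latent X to reconstructed embedding
#'
#' One FC -> batch-norm -> ELU -> dropout block followed by a final linear
#' map back to the input dimensionality.
#'
#' @param x n x k latent matrix.
#' @param state an [init_annotator_state()] result.
#' @param training logical training flag.
#' @return n x d reconstruction.
#' @export
ae_decode <- function(x, state, training = FALSE) {
  x <- .emb_values(x)
  if (ncol(x) != state$cfg$k)
    stop("latent has ", ncol(x), " dims; annotator expects k = ", state$cfg$k)
  cfg <- state$cfg; ch <- state$cache
  h <- .lin_fwd(state$dec1, x)
  if (cfg$use_batchnorm) h <- .bn_fwd(state$bn_d, h, training)
  h <- .drop_fwd(ch$dd, .elu_fwd(ch$de, h), cfg$dropout_p, training)
  .lin_fwd(state$dec2, h)
}

.ae_decode_bwd <- function(state, g) {
  cfg <- state$cfg; ch <- state$cache
  g <- .lin_bwd(state$dec2, g)
  g <- .elu_bwd(ch$de, .drop_bwd(ch$dd, g))
  if (cfg$use_batchnorm) g <- .bn_bwd(state$bn_d, g)
  .lin_bwd(state$dec1, g)
}

#' Graph encoder: latent X plus spatial graph to spatial embedding S
#'
#' Sparse graph convolution -> ReLU -> dropout -> sparse graph convolution,
#' each convolution being `A_norm (input W) + b` with the symmetrically
#' normalized adjacency.
#'
#' @param x n x k latent matrix.
#' @param g a [build_spatial_graph()] result; [normalize_adjacency()] is
#'   applied if not done yet.
#' @param state an [init_annotator_state()] result.
#' @param training logical training flag.
#' @return n x k spatial embedding `S`.
#' @export
graph_encode <- function(x, g, state, training = FALSE) {
  x <- .emb_values(x)
  stopifnot(inherits(g, "spatial_graph"))
  if (is.null(g$normalized)) g <- normalize_adjacency(g)
  if (nrow(x) != nrow(g$adjacency))
    stop("graph has ", nrow(g$adjacency), " nodes but the embedding has ",
         nrow(x), " rows")
  cfg <- state$cfg; ch <- state$cache
  h <- .relu_fwd(ch$gr, .gcn_fwd(state$gcn1, x, g$normalized))
  h <- .drop_fwd(ch$gd, h, cfg$dropout_p, training)
  .gcn_fwd(state$gcn2, h, g$normalized)
}

.graph_encode_bwd <- function(state, g_out, g) {
  ch <- state$cache
  gg <- .gcn_bwd(state$gcn2, g_out, g$normalized)
  gg <- .relu_bwd(ch$gr, .drop_bwd(ch$gd, gg))
  .gcn_bwd(state$gcn1, gg, g$normalized)
}

#' Fuse expression and spatial latents
#'
#' `Z = X + S`, elementwise.
#'
#' @param x,s matrices of identical shape.
#' @return their sum.
#' @export
combine_latent <- function(x, s) {
  x <- .emb_values(x); s <- .emb_values(s)
  if (!identical(dim(x), dim(s)))
    stop("X and S must have identical shapes to be fused")
  x + s
}

#' Inner-product graph decoder
#'
#' Reconstructs the adjacency as `sigmoid(Z Z^T)`: symmetric, entries in
#' (0, 1).
#'
#' @param z n x k latent matrix.
#' @return n x n reconstruction.
#' @export
graph_decode <- function(z) {
  z <- .emb_values(z)
  if (any(!is.finite(z))) stop("`z` must be finite")
  .sigmoid(tcrossprod(z))
}

# --- losses -----------------------------------------------------------------

#' Mean squared reconstruction error
#'
#' `mean((tti - tti_rec)^2)` over all n*d entries.
#'
#' @param tti input matrix.
#' @param tti_rec reconstruction of the same shape.
#' @return non-negative scalar.
#' @export
loss_ae <- function(tti, tti_rec) {
  tti <- .emb_values(tti); tti_rec <- .emb_values(tti_rec)
  if (!identical(dim(tti), dim(tti_rec))) stop("shape mismatch")
  mean((tti - tti_rec)^2)
}

#' Mean binary cross-entropy between adjacency and reconstruction
#'
#' `-(1/n^2) sum[a log a' + (1 - a) log(1 - a')]` over all entry pairs.
#' Reconstruction values at exactly 0 or 1 are clamped to `[1e-7, 1 - 1e-7]`
#' with a note.
#'
#' @param a target matrix, entries in `[0, 1]` (sparse or dense).
#' @param a_prime reconstruction, entries in `(0, 1)`.
#' @return non-negative scalar.
#' @export
loss_gae <- function(a, a_prime) {
  a <- as.matrix(a); a_prime <- as.matrix(a_prime)
  if (!identical(dim(a), dim(a_prime))) stop("shape mismatch")
  if (any(a < 0 | a > 1)) stop("adjacency targets must lie in [0, 1]")
  if (any(a_prime <= 0 | a_prime >= 1)) {
    message("loss_gae: clamping reconstruction values to [1e-7, 1 - 1e-7]")
    a_prime <- pmin(pmax(a_prime, 1e-7), 1 - 1e-7)
  }
  -mean(a * log(a_prime) + (1 - a) * log(1 - a_prime))
}

# numerically stable BCE from logits: softplus(s) - t * s
.bce_logits <- function(t, s, w = 1) {
  w * (pmax(s, 0) + log1p(exp(-abs(s))) - t * s)
}

#' Subsampled estimator of the adjacency BCE
#'
#' Stratified estimator of [loss_gae()] evaluated from latent codes: the
#' positive (nonzero) entries of `a` are enumerated exactly while the zero
#' entries are estimated from `n_negative` uniformly sampled zero pairs.
#' Unbiased for the exact `n^2` double sum; used during training when the
#' graph is too large for the full matrix.
#'
#' @param a sparse target adjacency (zero diagonal).
#' @param z n x k latent matrix (`a_prime = sigmoid(z z^T)`).
#' @param n_negative zero pairs to sample (default: number of stored
#'   entries). Uses the current RNG state.
#' @param pos_weight weight applied to positive entries (default 1, matching
#'   [loss_gae()]).
#' @return scalar estimate.
#' @export
loss_gae_sampled <- function(a, z, n_negative = NULL, pos_weight = 1) {
  z <- .emb_values(z)
  a <- as(as(a, "CsparseMatrix"), "generalMatrix")
  n <- nrow(a)
  trip <- Matrix::mat2triplet(a)
  npos <- length(trip$x)
  if (npos == 0) stop("target adjacency has no positive entries")
  n_negative <- n_negative %||% npos
  s_pos <- rowSums(z[trip$i, , drop = FALSE] * z[trip$j, , drop = FALSE])
  pos_sum <- sum(.bce_logits(trip$x, s_pos, pos_weight))
  neg <- .sample_zero_pairs(trip, n, n_negative)
  s_neg <- rowSums(z[neg$i, , drop = FALSE] * z[neg$j, , drop = FALSE])
  neg_mean <- mean(.bce_logits(0, s_neg))
  pos_sum / n^2 + (n^2 - npos) / n^2 * neg_mean
}

# sample m ordered pairs uniformly from the zero entries of the sparse target
.sample_zero_pairs <- function(trip, n, m) {
  pos_key <- (as.numeric(trip$i) - 1) * n + as.numeric(trip$j)
  i <- integer(0); j <- integer(0)
  while (length(i) < m) {
    need <- m - length(i)
    ci <- sample.int(n, ceiling(need * 1.05), replace = TRUE)
    cj <- sample.int(n, length(ci), replace = TRUE)
    keep <- !((as.numeric(ci) - 1) * n + as.numeric(cj)) %in% pos_key
    i <- c(i, ci[keep]); j <- c(j, cj[keep])
  }
  list(i = i[seq_len(m)], j = j[seq_len(m)])
}

#' Distillation cross-entropy between teacher and student distributions
#'
#' `-(1/(n*c)) sum D[i,j] log P[i,j]`. Note the `1/(n*c)` normalization: the
#' value is smaller than the standard per-cell cross-entropy by the class
#' count, which the `w_cls` weight absorbs.
#'
#' @param d teacher distribution (`teacher_distribution` or row-stochastic
#'   matrix).
#' @param p student distribution, same shape, rows summing to 1.
#' @return non-negative scalar.
#' @export
loss_ssl <- function(d, p) {
  if (inherits(d, "teacher_distribution")) d <- d$probs
  d <- as.matrix(d); p <- as.matrix(p)
  if (!identical(dim(d), dim(p))) stop("shape mismatch between D and P")
  if (any(abs(rowSums(d) - 1) > 1e-5) || any(abs(rowSums(p) - 1) > 1e-5))
    stop("rows of D and P must sum to 1")
  -sum(d * log(pmax(p, 1e-12))) / length(d)
}

#' Weighted total loss
#'
#' `w_dae * l_ae + w_gae * l_gae + w_cls * l_ssl`.
#'
#' @param l_ae,l_gae,l_ssl component losses.
#' @param cfg an [annotator_config()] supplying the weights, or a named list
#'   / vector with `w_dae`, `w_gae`, `w_cls`.
#' @return scalar.
#' @export
total_loss <- function(l_ae, l_gae, l_ssl, cfg = annotator_config()) {
  w <- if (inherits(cfg, "annotator_config")) cfg
       else as.list(cfg)
  if (is.null(w$w_dae) || is.null(w$w_gae) || is.null(w$w_cls))
    stop("weights w_dae, w_gae, w_cls are required")
  if (w$w_dae + w$w_gae + w$w_cls <= 0)
    stop("at least one loss weight must be positive")
  w$w_dae * l_ae + w$w_gae * l_gae + w$w_cls * l_ssl
}
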