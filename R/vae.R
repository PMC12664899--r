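#' Latent embedding container
#'
#' Cells-by-dimensions real matrix produced by the VAE encoder (or by the
#' PCA fallback), tagged with its source modality.
#'
#' @param values n x k numeric matrix.
#' @param cell_ids length-n cell identifiers.
#' @param source `"reference"` or `"spatial"`.
#' @return object of class `latent_embedding`.
#' @export
latent_embedding <- function(values, cell_ids, source = c("reference", "spatial")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("embedding values must be finite")
  if (length(cell_ids) != nrow(values))
    stop("`cell_ids` must match the embedding rows")
  rownames(values) <- cell_ids
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 source = source),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("<latent_embedding> %s: %d cells x %d dims\n",
              x$source, nrow(x$values), ncol(x$values)))
  invisible(x)
}

.emb_values <- function(x) {
  if (inherits(x, "latent_embedding")) x$values else as.matrix(x)
}

#' VAE configuration
#'
#' @param latent_dim latent dimensionality (default 30).
#' @param hidden_dim encoder/decoder hidden width (default 128).
#' @param decoder_layers number of hidden decoder layers (default 2).
#' @param max_epochs training epoch cap (default 400; early stopping on a
#'   training-loss plateau usually stops much earlier).
#' @param batch_size minibatch size (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param kl_warmup_epochs epochs over which the KL weight anneals from 0 to
#'   1 (default 20).
#' @param patience early-stopping patience in epochs (default 15).
#' @param seed RNG seed for initialization, shuffling and the
#'   reparameterization noise.
#' @return object of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 30, hidden_dim = 128, decoder_layers = 2,
                       max_epochs = 400, batch_size = 256,
                       learning_rate = 1e-3, kl_warmup_epochs = 20,
                       patience = 15, seed = 0) {
  stopifnot(latent_dim >= 1, hidden_dim >= 1, decoder_layers >= 1,
            max_epochs >= 1, batch_size >= 1, learning_rate > 0)
  if (latent_dim >= hidden_dim)
    stop("`latent_dim` must be smaller than `hidden_dim`")
  structure(list(latent_dim = latent_dim, hidden_dim = hidden_dim,
                 decoder_layers = decoder_layers, max_epochs = max_epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 kl_warmup_epochs = kl_warmup_epochs, patience = patience,
                 seed = seed),
            class = "vae_config")
}

# negative-binomial log likelihood terms and gradients share these clamps
.VAE_LV_CLAMP <- 8
.VAE_LT_LO <- -8
.VAE_LT_HI <- 10

#' Fit the batch-harmonizing conditional VAE
#'
#' Trains one variational autoencoder jointly on the gene-aligned reference
#' and spatial count matrices, with the modality as a conditioning covariate
#' of both the encoder and the decoder. Counts are modelled with a
#' negative-binomial likelihood: the decoder emits per-gene proportions via a
#' softmax which are scaled by each cell's observed library size, with a
#' free gene-wise inverse-dispersion parameter. The encoder takes
#' `log1p(counts)` plus the batch one-hot and outputs the Gaussian posterior
#' mean and log-variance of the latent code.
#'
#' Training is minibatch Adam with KL warmup and early stopping on a
#' training-loss plateau, fully seeded via `cfg$seed`.
#'
#' @param ref gene-aligned reference [expression_dataset].
#' @param spatial gene-aligned spatial [expression_dataset].
#' @param cfg a [vae_config()].
#' @param verbose print per-epoch loss every 25 epochs (default `FALSE`).
#' @return object of class `vae_model`.
#' @seealso [encode_cells()]
#' @export
fit_vae <- function(ref, spatial, cfg = vae_config(), verbose = FALSE) {
  stopifnot(inherits(ref, "expression_dataset"),
            inherits(spatial, "expression_dataset"),
            inherits(cfg, "vae_config"))
  if (!identical(ref$gene_ids, spatial$gene_ids))
    stop("datasets are not gene-aligned; run align_genes() first")
  if (identical(ref$role, spatial$role))
    stop("fewer than 2 batches: both datasets carry the role '", ref$role,
         "'; there is nothing to harmonize")
  x <- rbind(as.matrix(ref$counts), as.matrix(spatial$counts))
  if (any(!is.finite(x))) stop("counts contain NaN/Inf entries")
  n <- nrow(x); d <- ncol(x)
  onehot <- cbind(c(rep(1, nrow(ref$counts)), rep(0, nrow(spatial$counts))),
                  c(rep(0, nrow(ref$counts)), rep(1, nrow(spatial$counts))))
  lib <- rowSums(x); lib[lib == 0] <- 1
  lx <- log1p(x)

  set.seed(cfg$seed)
  k <- cfg$latent_dim; hdim <- cfg$hidden_dim
  enc1 <- .nn_linear(d + 2, hdim)
  enc_mu <- .nn_linear(hdim, k, scale = 0.01)
  enc_lv <- .nn_linear(hdim, k, scale = 0.01)
  dec_hidden <- vector("list", cfg$decoder_layers)
  dec_hidden[[1]] <- .nn_linear(k + 2, hdim)
  if (cfg$decoder_layers > 1)
    for (j in 2:cfg$decoder_layers) dec_hidden[[j]] <- .nn_linear(hdim, hdim)
  dec_out <- .nn_linear(hdim, d, scale = 0.01)
  log_theta <- .nn_param(numeric(d))
  layers <- c(list(enc1, enc_mu, enc_lv), dec_hidden, list(dec_out, log_theta))

  step_batch <- function(rows, kl_w, t) {
    nb <- length(rows)
    xb <- x[rows, , drop = FALSE]
    bb <- onehot[rows, , drop = FALSE]
    lb <- lib[rows]
    scale <- 1 / nb
    # encoder
    c_er <- .nn_env()
    h <- .relu_fwd(c_er, .lin_fwd(enc1, cbind(lx[rows, , drop = FALSE], bb)))
    mu <- .lin_fwd(enc_mu, h)
    lv_raw <- .lin_fwd(enc_lv, h)
    lv <- pmin(pmax(lv_raw, -.VAE_LV_CLAMP), .VAE_LV_CLAMP)
    eps <- matrix(stats::rnorm(nb * k), nb, k)
    sd_z <- exp(lv / 2)
    z <- mu + sd_z * eps
    # decoder
    caches <- lapply(seq_along(dec_hidden), function(i) .nn_env())
    a <- cbind(z, bb)
    for (j in seq_along(dec_hidden))
      a <- .relu_fwd(caches[[j]], .lin_fwd(dec_hidden[[j]], a))
    o <- .lin_fwd(dec_out, a)
    rho <- .softmax_rows(o)
    m_raw <- rho * lb
    m <- pmax(m_raw, 1e-10)
    lt <- pmin(pmax(log_theta$v, .VAE_LT_LO), .VAE_LT_HI)
    th_g <- exp(lt)
    # NB log likelihood (compiled fused kernel) and KL
    nb_res <- .nb_loss_grad(xb, m, th_g, scale)
    kl <- 0.5 * sum(exp(lv) + mu^2 - 1 - lv)
    loss <- (nb_res$nll + kl_w * kl) * scale
    if (!is.finite(loss)) stop("VAE loss became non-finite (epoch step ", t, ")")
    # backward
    dm <- nb_res$dm
    dm[m_raw < 1e-10] <- 0
    gv <- nb_res$dtheta * th_g
    gv[log_theta$v <= .VAE_LT_LO | log_theta$v >= .VAE_LT_HI] <- 0
    log_theta$gv <- gv
    drho <- dm * lb
    do <- rho * (drho - rowSums(drho * rho))
    g <- .lin_bwd(dec_out, do)
    for (j in rev(seq_along(dec_hidden)))
      g <- .lin_bwd(dec_hidden[[j]], .relu_bwd(caches[[j]], g))
    dz <- g[, seq_len(k), drop = FALSE]
    dmu <- dz + kl_w * mu * scale
    dlv <- dz * eps * 0.5 * sd_z + kl_w * 0.5 * (exp(lv) - 1) * scale
    dlv[abs(lv_raw) > .VAE_LV_CLAMP] <- 0
    dh <- .lin_bwd(enc_mu, dmu) + .lin_bwd(enc_lv, dlv)
    .lin_bwd(enc1, .relu_bwd(c_er, dh))
    .adam_step(layers, cfg$learning_rate, t)
    loss
  }

  history <- numeric(0)
  best <- Inf; wait <- 0; t <- 0
  for (epoch in seq_len(cfg$max_epochs)) {
    kl_w <- min(1, epoch / max(1, cfg$kl_warmup_epochs))
    perm <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    tot <- 0
    for (s in starts) {
      rows <- perm[s:min(s + cfg$batch_size - 1, n)]
      t <- t + 1
      tot <- tot + step_batch(rows, kl_w, t) * length(rows)
    }
    epoch_loss <- tot / n
    history <- c(history, epoch_loss)
    if (verbose && epoch %% 25 == 0)
      message(sprintf("vae epoch %d: loss %.4f", epoch, epoch_loss))
    if (epoch > cfg$kl_warmup_epochs) {  # plateau detection after warmup
      if (!is.finite(best) || epoch_loss < best - 1e-3 * abs(best)) {
        best <- epoch_loss; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
  }

  structure(list(enc1 = enc1, enc_mu = enc_mu, enc_lv = enc_lv,
                 dec_hidden = dec_hidden, dec_out = dec_out,
                 log_theta = log_theta, cfg = cfg, gene_ids = ref$gene_ids,
                 history = data.frame(epoch = seq_along(history),
                                      loss = history)),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model> %d genes -> %d latent dims, trained %d epochs (final loss %.4f)\n",
              length(x$gene_ids), x$cfg$latent_dim, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Encode cells into the harmonized latent space
#'
#' Deterministic embedding: the Gaussian posterior mean of the trained VAE
#' encoder (no sampling), so repeated calls on the same data are identical.
#'
#' @param model a [fit_vae()] result.
#' @param data an [expression_dataset] gene-aligned to the model.
#' @return a [latent_embedding] with `model$cfg$latent_dim` columns.
#' @export
encode_cells <- function(model, data) {
  stopifnot(inherits(model, "vae_model"), inherits(data, "expression_dataset"))
  if (!identical(data$gene_ids, model$gene_ids))
    stop("gene order mismatch: dataset genes differ from the model's genes")
  x <- as.matrix(data$counts)
  n <- nrow(x)
  onehot <- if (data$role == "reference") cbind(rep(1, n), rep(0, n))
            else cbind(rep(0, n), rep(1, n))
  cache <- .nn_env()
  h <- .relu_fwd(cache, .lin_fwd(model$enc1, cbind(log1p(x), onehot)))
  mu <- .lin_fwd(model$enc_mu, h)
  latent_embedding(mu, data$cell_ids, source = data$role)
}

#' Joint log-count PCA embedding
#'
#' Principal-component embedding of the concatenated `log1p` count matrices,
#' with no batch modelling. This is both the comparison baseline for the
#' VAE's batch mixing and the embedding used by the no-VAE ablation of the
#' pipeline.
#'
#' @param ref,spatial gene-aligned [expression_dataset]s.
#' @param dim number of components (default 30).
#' @return list with [latent_embedding]s `reference` and `spatial`.
#' @export
joint_logcount_pca <- function(ref, spatial, dim = 30) {
  if (!identical(ref$gene_ids, spatial$gene_ids))
    stop("datasets are not gene-aligned; run align_genes() first")
  lx <- log1p(rbind(as.matrix(ref$counts), as.matrix(spatial$counts)))
  dim <- min(dim, ncol(lx), nrow(lx) - 1)
  pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE, rank. = dim)
  nr <- nrow(ref$counts)
  list(reference = latent_embedding(pc$x[seq_len(nr), , drop = FALSE],
                                    ref$cell_ids, "reference"),
       spatial = latent_embedding(pc$x[-seq_len(nr), , drop = FALSE],
                                  spatial$cell_ids, "spatial"))
}
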