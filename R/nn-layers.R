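# Minimal mutable-layer framework for the VAE and the AE/GAE annotator.
# Each layer is an environment holding parameters, gradients, Adam state and
# the forward cache needed by its backward pass. Backward passes are
# hand-derived and verified against finite differences in the test suite.

.nn_env <- function(...) {
  e <- list2env(list(...), parent = emptyenv())
  e
}

# --- linear -----------------------------------------------------------------

.nn_linear <- function(d_in, d_out, scale = sqrt(2 / d_in)) {
  .nn_env(W = matrix(stats::rnorm(d_in * d_out, sd = scale), d_in, d_out),
          b = numeric(d_out), params = c("W", "b"))
}

.lin_fwd <- function(l, x) {
  l$x <- x
  out <- x %*% l$W
  out + rep(l$b, each = nrow(out))
}

.lin_bwd <- function(l, g) {
  l$gW <- crossprod(l$x, g)
  l$gb <- colSums(g)
  g %*% t(l$W)
}

# --- batch normalization ----------------------------------------------------
# Training uses batch statistics (biased variance) and updates running
# statistics with momentum; inference uses the running statistics.

.nn_bn <- function(d, momentum = 0.1, eps = 1e-5) {
  .nn_env(gamma = rep(1, d), beta = numeric(d),
          run_mean = numeric(d), run_var = rep(1, d),
          momentum = momentum, eps = eps, params = c("gamma", "beta"))
}

.bn_fwd <- function(l, x, training) {
  n <- nrow(x)
  if (training && n > 1) {
    m <- colMeans(x)
    xc <- x - rep(m, each = n)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + l$eps)
    xhat <- xc * rep(inv, each = n)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * m
    l$run_var  <- (1 - l$momentum) * l$run_var  + l$momentum * v
    l$xhat <- xhat; l$inv <- inv
  } else {
    inv <- 1 / sqrt(l$run_var + l$eps)
    xhat <- (x - rep(l$run_mean, each = n)) * rep(inv, each = n)
    l$xhat <- xhat; l$inv <- inv
  }
  xhat * rep(l$gamma, each = n) + rep(l$beta, each = n)
}

.bn_bwd <- function(l, g) {
  n <- nrow(g)
  l$ggamma <- colSums(g * l$xhat)
  l$gbeta <- colSums(g)
  dxhat <- g * rep(l$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * l$xhat)
  (dxhat - rep(s1 / n, each = n) - l$xhat * rep(s2 / n, each = n)) *
    rep(l$inv, each = n)
}

# --- activations ------------------------------------------------------------

.elu_fwd <- function(cache, x) {
  neg <- x < 0
  out <- x
  out[neg] <- exp(x[neg]) - 1
  cache$neg <- neg; cache$out <- out
  out
}

.elu_bwd <- function(cache, g) {
  d <- g
  d[cache$neg] <- g[cache$neg] * (cache$out[cache$neg] + 1)
  d
}

.relu_fwd <- function(cache, x) {
  mask <- x > 0
  cache$mask <- mask
  x * mask
}

.relu_bwd <- function(cache, g) g * cache$mask

# --- dropout (inverted) -----------------------------------------------------

.drop_fwd <- function(cache, x, p, training) {
  if (!training || p <= 0) { cache$mask <- NULL; return(x) }
  mask <- matrix((stats::runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  cache$mask <- mask
  x * mask
}

.drop_bwd <- function(cache, g) {
  if (is.null(cache$mask)) g else g * cache$mask
}

# --- sparse graph convolution: out = A_norm %*% (x %*% W) + b ---------------

.nn_gcn <- function(d_in, d_out, scale = sqrt(2 / d_in)) {
  .nn_env(W = matrix(stats::rnorm(d_in * d_out, sd = scale), d_in, d_out),
          b = numeric(d_out), params = c("W", "b"))
}

.gcn_fwd <- function(l, x, a_norm) {
  l$x <- x
  out <- as.matrix(a_norm %*% (x %*% l$W))
  out + rep(l$b, each = nrow(out))
}

# a_norm symmetric, so A^T g = A g
.gcn_bwd <- function(l, g, a_norm) {
  ag <- as.matrix(a_norm %*% g)
  l$gW <- crossprod(l$x, ag)
  l$gb <- colSums(g)
  ag %*% t(l$W)
}

# --- free parameter vector (e.g. gene-wise dispersion) ----------------------

.nn_param <- function(init) .nn_env(v = init, params = "v")

# --- Adam -------------------------------------------------------------------

.adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in layers) {
    for (p in l$params) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      mk <- paste0("m_", p); vk <- paste0("v_", p)
      if (is.null(l[[mk]])) { l[[mk]] <- g * 0; l[[vk]] <- g * 0 }
      l[[mk]] <- beta1 * l[[mk]] + (1 - beta1) * g
      l[[vk]] <- beta2 * l[[vk]] + (1 - beta2) * g * g
      l[[p]] <- l[[p]] - lr * (l[[mk]] / bc1) / (sqrt(l[[vk]] / bc2) + eps)
    }
  }
  invisible(NULL)
}

.softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
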