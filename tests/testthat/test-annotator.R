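make_state <- function(d = 4, k1 = 4, k = 4, classes = c("A", "B"),
                       dropout = 0, bn = TRUE, seed = 1) {
  init_annotator_state(d, classes,
                       annotator_config(k1 = k1, k = k, dropout_p = dropout,
                                        use_batchnorm = bn, seed = seed))
}

test_that("reconstruction MSE matches hand values and is quadratic", {
  expect_equal(loss_ae(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(loss_ae(matrix(0), matrix(2)), 4)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(loss_ae(a, a + 3 * (b - a)), 9 * loss_ae(a, b))
  expect_error(loss_ae(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("adjacency BCE matches closed forms and clamps degenerate inputs", {
  half <- matrix(0.5, 3, 3)
  expect_equal(loss_gae(half, half), log(2), tolerance = 1e-12)
  # reconstruction approaching a binary target drives the loss to 0
  a <- diag(3)
  expect_lt(loss_gae(a, abs(a - 1e-9)), 1e-6)
  expect_message(v <- loss_gae(a, a), "clamp")
  expect_lt(v, 1e-4)
  expect_error(loss_gae(half * 3, half), "\\[0, 1\\]")
})

test_that("inner-product decoder matches closed forms and is symmetric", {
  expect_equal(graph_decode(matrix(0, 4, 3)), matrix(0.5, 4, 4))
  z <- rbind(c(1, 0), c(0, 1))   # orthonormal rows
  ap <- graph_decode(z)
  expect_equal(diag(ap), rep(1 / (1 + exp(-1)), 2), tolerance = 1e-12)
  expect_equal(ap[1, 2], 0.5)
  z2 <- matrix(rnorm(15), 5, 3)
  expect_identical(graph_decode(z2), t(graph_decode(z2)))
})

test_that("distillation cross-entropy matches the printed normalization", {
  # n = 1, c = 2, D = (1,0), P = (0.5,0.5): (1/2) ln 2
  expect_equal(loss_ssl(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               log(2) / 2, tolerance = 1e-12)
  d <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_lt(loss_ssl(d, pmax(d, 1e-9) / rowSums(pmax(d, 1e-9))), 1e-6)
  # Gibbs: for fixed D the loss over P is minimized at P = D
  set.seed(5)
  dmat <- matrix(runif(8), 4); dmat <- dmat / rowSums(dmat)
  at_d <- loss_ssl(dmat, dmat)
  for (i in 1:10) {
    p <- matrix(runif(8), 4); p <- p / rowSums(p)
    expect_gte(loss_ssl(dmat, p), at_d)
  }
  expect_error(loss_ssl(dmat, dmat * 2), "sum to 1")
})

test_that("total loss is the weighted sum and zero weights mask a term", {
  w <- list(w_dae = 1, w_gae = 1, w_cls = 1)
  expect_equal(total_loss(0.2, 0.3, 0.5, w), 1.0)
  expect_equal(total_loss(0.7, 123, 456, list(w_dae = 1, w_gae = 0, w_cls = 0)),
               0.7)
  # a zero-weight term is invariant to arbitrary perturbation of its input
  w2 <- list(w_dae = 2, w_gae = 0, w_cls = 3)
  expect_equal(total_loss(0.1, 0.9, 0.2, w2), total_loss(0.1, 1e6, 0.2, w2))
  expect_error(total_loss(1, 1, 1, list(w_dae = 0, w_gae = 0, w_cls = 0)),
               "positive")
  expect_error(annotator_config(w_cls = 0, w_dae = 0, w_gae = 0), "positive")
})

test_that("component shapes and eval-mode determinism hold", {
  set.seed(2)
  st <- make_state(d = 8, k1 = 6, k = 4, dropout = 0.3)
  x <- matrix(rnorm(50 * 8), 50, 8)
  g <- normalize_adjacency(build_spatial_graph(matrix(runif(100), 50, 2), 5))
  X <- ae_encode(x, st)
  expect_identical(dim(X), c(50L, 4L))
  expect_identical(ae_encode(x, st), X)            # dropout off in eval
  rec <- ae_decode(X, st)
  expect_identical(dim(rec), c(50L, 8L))
  S <- graph_encode(X, g, st)
  expect_identical(dim(S), c(50L, 4L))
  expect_identical(graph_encode(X, g, st), S)
  expect_error(ae_encode(matrix(0, 5, 3), st), "dims")
  expect_error(ae_decode(matrix(0, 5, 7), st), "dims")
  expect_error(graph_encode(matrix(0, 9, 4), g, st), "nodes")
})

test_that("identity-configured encoder is the identity on non-negative input", {
  st <- make_state(d = 4, k1 = 4, k = 4, bn = FALSE)
  st$enc1$W <- diag(4); st$enc1$b <- numeric(4)
  st$enc2$W <- diag(4); st$enc2$b <- numeric(4)
  x <- matrix(abs(rnorm(20)), 5, 4)     # ELU is the identity on x >= 0
  expect_equal(ae_encode(x, st), x, tolerance = 1e-12)
})

test_that("zero input with a zero final layer decodes to the broadcast bias", {
  st <- make_state(d = 4, k1 = 3, k = 2, bn = FALSE)
  st$dec2$W <- matrix(0, 3, 4)
  st$dec2$b <- c(1, 2, 3, 4)
  st$dec1$b <- numeric(3)
  out <- ae_decode(matrix(0, 6, 2), st)
  expect_equal(out, matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4),
               tolerance = 1e-12)
})

test_that("fusion Z = X + S is commutative with additive identities", {
  x <- matrix(rnorm(12), 3, 4); s <- matrix(rnorm(12), 3, 4)
  expect_identical(combine_latent(x, 0 * s), x)
  expect_identical(combine_latent(0 * x, s), s)
  expect_identical(combine_latent(x, s), combine_latent(s, x))
  expect_error(combine_latent(x, matrix(0, 4, 3)), "shape")
})

test_that("sparse graph encoding equals the dense-matrix oracle", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    st <- make_state(d = 4, k1 = 4, k = 4, seed = rep)
    g <- normalize_adjacency(
      build_spatial_graph(matrix(runif(2 * n), n, 2), k_neighbors = 4))
    x <- matrix(rnorm(n * 4), n, 4)
    expect_lt(max(abs(graph_encode(x, g, st) - dense_graph_encode(x, g, st))),
              1e-6)
  }
})

test_that("training reduces the total loss and is seed-deterministic", {
  set.seed(3)
  pair <- tiny_pair(seed = 21, cells_per_type = 25, n_genes = 40,
                    st_per_type = 30, n_background = 12)
  emb <- joint_logcount_pca(pair$ref, pair$st, dim = 10)
  g <- normalize_adjacency(build_spatial_graph(pair$st$coords, 8))
  tm <- train_teacher(emb$reference, pair$ref$labels, k_n_fold = 5, seed = 1)
  d <- predict_distribution(tm, emb$spatial)
  cfg <- annotator_config(k1 = 16, k = 10, epochs = 60, seed = 4)
  st1 <- train_annotator(emb$spatial, g, d, cfg)
  expect_lt(st1$history$total[60], st1$history$total[1])
  p1 <- predict_labels(st1, emb$spatial, g)
  expect_identical(p1, predict_labels(st1, emb$spatial, g))
  expect_equal(unname(rowSums(p1$probs)), rep(1, nrow(p1$probs)),
               tolerance = 1e-6)
  st2 <- train_annotator(emb$spatial, g, d, cfg)
  expect_identical(st1$student$W, st2$student$W)
  expect_identical(p1$labels, predict_labels(st2, emb$spatial, g)$labels)
})

test_that("a zero distillation weight leaves the student head untouched", {
  set.seed(4)
  pair <- tiny_pair(seed = 31, cells_per_type = 15, n_genes = 30,
                    st_per_type = 15, n_background = 8)
  emb <- joint_logcount_pca(pair$ref, pair$st, dim = 8)
  g <- normalize_adjacency(build_spatial_graph(pair$st$coords, 6))
  d <- matrix(0.2, nrow(emb$spatial$values), 5)
  cfg <- annotator_config(k1 = 12, k = 8, epochs = 20, w_cls = 0, seed = 9)
  st0 <- init_annotator_state(8, paste0("c", 1:5), cfg)
  w_before <- st0$student$W + 0
  b_before <- st0$student$b + 0
  trained <- train_annotator(emb$spatial, g, d, cfg, state = st0)
  expect_identical(trained$student$W, w_before)
  expect_identical(trained$student$b, b_before)
})

test_that("prediction requires a trained state", {
  st <- make_state()
  g <- normalize_adjacency(build_spatial_graph(matrix(runif(10), 5, 2), 2))
  expect_error(predict_labels(st, matrix(0, 5, 4), g), "untrained")
})
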