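# Shared fixture builders. Everything is generated in code at test time.

# A small annotated reference and matching pseudo-ST pair.
tiny_pair <- function(seed = 1, cells_per_type = 60, n_genes = 80,
                      st_per_type = 50, n_background = 20,
                      layout_kind = "hierarchical", depth = 400) {
  spec <- synthetic_reference_spec(
    n_types = 4, cells_per_type = cells_per_type, n_genes = n_genes,
    signature_genes_per_type = max(2, n_genes %/% 10),
    depth_mean = depth, seed = seed)
  ref <- make_synthetic_reference(spec)
  st <- make_pseudo_st(ref, pseudo_layout(layout_kind,
                                          cells_per_type = st_per_type,
                                          n_background = n_background),
                       seed = seed + 1)
  list(ref = ref, st = st)
}

# A 3-cell x 4-gene labelled toy dataset.
toy_reference <- function(labels = c("A", "A", "B")) {
  m <- matrix(c(5, 0, 1, 2,
                4, 1, 0, 3,
                0, 7, 2, 1), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  expression_dataset(m, labels = labels, role = "reference")
}

# Mean k-NN batch entropy of an embedding: higher = better batch mixing.
knn_batch_entropy <- function(values, batch, k = 15) {
  n <- nrow(values)
  dm <- as.matrix(dist(values))
  diag(dm) <- Inf
  ent <- vapply(seq_len(n), function(i) {
    nb <- batch[order(dm[i, ])[seq_len(k)]]
    p <- table(factor(nb, levels = unique(batch))) / k
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent)
}

# Mean silhouette width of labelled points in an embedding.
mean_silhouette <- function(values, labels) {
  dm <- as.matrix(dist(values))
  labs <- as.character(labels)
  n <- nrow(values)
  s <- vapply(seq_len(n), function(i) {
    own <- labs == labs[i]; own[i] <- FALSE
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(labs), labs[i]),
                    function(l) mean(dm[i, labs == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Matched-pair distance ratio: mean distance between paired rows divided by
# the mean distance between random pairs (scale-free across embeddings).
matched_pair_ratio <- function(values, n_pairs) {
  d_match <- sqrt(rowSums((values[seq_len(n_pairs), , drop = FALSE] -
                           values[n_pairs + seq_len(n_pairs), , drop = FALSE])^2))
  set.seed(99)
  i <- sample.int(nrow(values), 500, replace = TRUE)
  j <- sample.int(nrow(values), 500, replace = TRUE)
  d_rand <- sqrt(rowSums((values[i, , drop = FALSE] - values[j, , drop = FALSE])^2))
  mean(d_match) / mean(d_rand[i != j])
}

# Dense reference computation of the two-layer graph encoder, used as the
# oracle for the sparse implementation.
dense_graph_encode <- function(x, g, state) {
  an <- as.matrix(g$normalized)
  h <- an %*% (x %*% state$gcn1$W)
  h <- h + rep(state$gcn1$b, each = nrow(x))
  h[h < 0] <- 0
  out <- an %*% (h %*% state$gcn2$W)
  out + rep(state$gcn2$b, each = nrow(x))
}
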