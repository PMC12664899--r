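test_that("accuracy matches hand counts", {
  expect_equal(accuracy_score(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(accuracy_score(c("A", "A", "B", "B"), c("A", "B", "B", "B")),
               0.75)
  expect_error(accuracy_score(character(0), character(0)), "empty")
  expect_error(accuracy_score(c("A"), c("A", "B")), "differ")
})

test_that("weighted F1 matches the scikit-learn oracle values", {
  expect_equal(weighted_f1(c("A", "B"), c("A", "B")), 1.0)
  # truth AAAB, pred AABB: F1(A) = 0.8, F1(B) = 2/3, weights 3/4 and 1/4
  # (frozen against sklearn f1_score(average = "weighted") = 0.7666667)
  expect_equal(weighted_f1(c("A", "A", "A", "B"), c("A", "A", "B", "B")),
               0.75 * 0.8 + 0.25 * 2 / 3, tolerance = 1e-12)
  expect_equal(weighted_f1(c("A", "A", "B", "B"), c("A", "B", "B", "B")),
               0.7333333, tolerance = 1e-6)
  expect_equal(weighted_f1(c("A", "A"), c("A", "A")), 1.0)
})

test_that("confusion matrix counts truth-by-prediction cells", {
  cm <- confusion_matrix(c("A", "A", "A", "B"), c("A", "A", "B", "B"))
  expect_identical(unname(cm), matrix(c(2L, 0L, 1L, 1L), 2))
  cm0 <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_identical(unname(cm0), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_identical(rownames(cm), c("A", "B"))
  truth <- sample(c("x", "y", "z"), 60, replace = TRUE)
  pred <- sample(c("x", "y", "z"), 60, replace = TRUE)
  cm2 <- confusion_matrix(truth, pred)
  expect_identical(as.integer(rowSums(cm2)),
                   as.integer(table(factor(truth, levels = rownames(cm2)))))
  expect_equal(sum(diag(cm2)) / 60, accuracy_score(truth, pred))
  # perfect prediction gives a diagonal matrix
  cm3 <- confusion_matrix(truth, truth)
  expect_true(all(cm3[upper.tri(cm3) | lower.tri(cm3)] == 0))
})

test_that("evaluation report bundles the metrics consistently", {
  set.seed(1)
  truth <- sample(c("A", "B", "C"), 100, replace = TRUE)
  pred <- truth
  pred[1:20] <- sample(c("A", "B", "C"), 20, replace = TRUE)
  rep <- evaluate_annotation(truth, pred)
  expect_gte(rep$accuracy, 0); expect_lte(rep$accuracy, 1)
  expect_gte(rep$weighted_f1, 0); expect_lte(rep$weighted_f1, 1)
  expect_equal(rep$accuracy, accuracy_score(truth, pred))
  expect_equal(rep$weighted_f1, weighted_f1(truth, pred))
  expect_equal(sum(rep$confusion), rep$n)
  perfect <- evaluate_annotation(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$weighted_f1, 1)
})

test_that("profile correlation recovers matching cell types", {
  pair <- tiny_pair(seed = 17, cells_per_type = 40, n_genes = 60,
                    st_per_type = 30, n_background = 10)
  # reference correlated with itself: diagonal exactly 1
  fake_sp <- expression_dataset(pair$ref$counts, gene_ids = pair$ref$gene_ids,
                                cell_ids = paste0("f", seq_len(nrow(pair$ref$counts))),
                                coords = matrix(0, nrow(pair$ref$counts), 2),
                                labels = pair$ref$labels, role = "spatial")
  self_cor <- profile_spearman(fake_sp, fake_sp$labels, pair$ref)
  expect_equal(unname(diag(self_cor)), rep(1, 5))
  # groups copied from the reference peak at the matching type
  sp_cor <- profile_spearman(pair$st, pair$st$labels, pair$ref)
  expect_identical(colnames(sp_cor)[apply(sp_cor, 1, which.max)],
                   rownames(sp_cor))
})

test_that("constant profiles are reported as missing with a note", {
  counts <- rbind(matrix(1, 2, 4), matrix(rpois(8, 5) + 1, 2, 4))
  sp <- expression_dataset(counts, gene_ids = paste0("g", 1:4),
                           cell_ids = paste0("c", 1:4),
                           coords = matrix(0, 4, 2), role = "spatial")
  ref <- expression_dataset(counts, gene_ids = paste0("g", 1:4),
                            cell_ids = paste0("r", 1:4),
                            labels = c("flat", "flat", "ok", "ok"),
                            role = "reference")
  expect_message(out <- profile_spearman(sp, c("flat", "flat", "ok", "ok"), ref),
                 "constant")
  expect_true(all(is.na(out["flat", ])))
})

test_that("neighbour agreement reflects label smoothness on the graph", {
  # 4 points on a line; k = 1 links the two left and the two right points
  g <- build_spatial_graph(cbind(c(0, 1, 10, 11), 0), k_neighbors = 1)
  expect_equal(neighbor_agreement(c("A", "A", "B", "B"), g), 1)
  expect_equal(neighbor_agreement(c("A", "B", "A", "B"), g), 0)
  expect_equal(neighbor_agreement(c("A", "A", "A", "B"), g), 0.5)
})
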