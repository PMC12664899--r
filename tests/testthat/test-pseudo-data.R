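test_that("the default reference spec is echoed faithfully", {
  ref <- make_synthetic_reference(synthetic_reference_spec(seed = 1))
  expect_identical(dim(ref$counts), c(5000L, 500L))
  expect_setequal(unique(ref$labels),
                  c("type1", "type2", "type3", "type4", "background"))
  expect_identical(unname(table(ref$labels)["background"]), 1000L)
  expect_true(all(as.matrix(ref$counts) >= 0))
  expect_true(all(as.matrix(ref$counts) == floor(as.matrix(ref$counts))))
})

test_that("signature genes show the configured fold change", {
  ref <- make_synthetic_reference(synthetic_reference_spec(seed = 2))
  sig <- attr(ref, "signatures")
  m <- as.matrix(ref$counts)
  own <- colMeans(m[ref$labels == "type1", sig$type1, drop = FALSE])
  other <- colMeans(m[ref$labels != "type1", sig$type1, drop = FALSE])
  ratio <- mean(own) / mean(other)
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("reference generation is seed-deterministic and validates", {
  spec <- synthetic_reference_spec(n_types = 2, cells_per_type = 15,
                                   n_genes = 40, signature_genes_per_type = 5,
                                   seed = 7)
  r1 <- make_synthetic_reference(spec)
  r2 <- make_synthetic_reference(spec)
  expect_identical(as.matrix(r1$counts), as.matrix(r2$counts))
  expect_error(synthetic_reference_spec(n_types = 4, n_genes = 50,
                                        signature_genes_per_type = 20),
               "disjoint")
})

test_that("the hierarchical layout places each type in its own row", {
  ref <- make_synthetic_reference(
    synthetic_reference_spec(cells_per_type = 120, n_genes = 60,
                             signature_genes_per_type = 10, depth_mean = 300,
                             seed = 3))
  st <- make_pseudo_st(ref, pseudo_layout("hierarchical"), seed = 4)
  expect_identical(nrow(st$counts), 4400L)
  expect_identical(sum(st$labels == "background"), 400L)
  for (i in 1:4) {
    y <- st$coords[st$labels == paste0("type", i), "y"]
    expect_identical(sum(st$labels == paste0("type", i)), 1000L)
    expect_true(all(y >= i - 1 & y <= i))
  }
  expect_true(all(st$coords[, "x"] >= 0 & st$coords[, "x"] <= 4))
})

test_that("the block layout places each type in its own square", {
  ref <- make_synthetic_reference(
    synthetic_reference_spec(cells_per_type = 120, n_genes = 60,
                             signature_genes_per_type = 10, depth_mean = 300,
                             seed = 5))
  st <- make_pseudo_st(ref, pseudo_layout("block"), seed = 6)
  expect_identical(nrow(st$counts), 4300L)
  expect_identical(sum(st$labels == "background"), 300L)
  offs <- list(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  for (i in 1:4) {
    co <- st$coords[st$labels == paste0("type", i), , drop = FALSE]
    expect_true(all(co[, 1] >= offs[[i]][1] & co[, 1] <= offs[[i]][1] + 100))
    expect_true(all(co[, 2] >= offs[[i]][2] & co[, 2] <= offs[[i]][2] + 100))
  }
})

test_that("background cells are spread uniformly over the four regions", {
  ref <- make_synthetic_reference(
    synthetic_reference_spec(cells_per_type = 150, n_genes = 40,
                             signature_genes_per_type = 5, depth_mean = 200,
                             seed = 8))
  st <- make_pseudo_st(ref, pseudo_layout("hierarchical", cells_per_type = 100,
                                          n_background = 400), seed = 9)
  reg <- attr(st, "region")[st$labels == "background"]
  expect_gt(stats::chisq.test(table(factor(reg, levels = 1:4)))$p.value, 0.01)
  # region assignment matches the coordinates
  expect_true(all(ceiling(st$coords[st$labels == "background", "y"]) == reg))
})

test_that("every spatial row is a batch-shifted copy of a reference row", {
  pair <- tiny_pair(seed = 12, cells_per_type = 20, n_genes = 30,
                    st_per_type = 25, n_background = 10)
  src <- attr(pair$st, "source_index")
  fac <- attr(pair$st, "batch_factor")
  expected <- round(as.matrix(pair$ref$counts)[src, , drop = FALSE] *
                    rep(fac, each = length(src)))
  expect_identical(unname(as.matrix(pair$st$counts)), unname(expected))
  # type is preserved through sampling
  expect_identical(pair$st$labels, pair$ref$labels[src])
})

test_that("pseudo-ST generation is deterministic and checks required types", {
  pair <- tiny_pair(seed = 13, cells_per_type = 15, n_genes = 30,
                    st_per_type = 10, n_background = 5)
  st2 <- make_pseudo_st(pair$ref,
                        pseudo_layout("hierarchical", cells_per_type = 10,
                                      n_background = 5), seed = 14)
  expect_identical(as.matrix(pair$st$counts), as.matrix(st2$counts))
  ref_nobg <- stgraft:::subset_cells(pair$ref,
                                     which(pair$ref$labels != "background"))
  expect_error(make_pseudo_st(ref_nobg, pseudo_layout("block")), "background")
})
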