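test_that("gaussian_weight matches its closed form and contracts", {
  expect_equal(gaussian_weight(0, 1), 1)
  expect_equal(gaussian_weight(0, 17.3), 1)
  expect_equal(gaussian_weight(1, 1), exp(-1 / 2), tolerance = 1e-12)
  expect_equal(gaussian_weight(2, 1), exp(-2), tolerance = 1e-12)
  expect_error(gaussian_weight(1, 0), "positive")
  expect_error(gaussian_weight(1, -2), "positive")
  expect_error(gaussian_weight(-1, 1), "non-negative")
})

test_that("kernel weight is strictly decreasing in distance", {
  set.seed(1)
  for (theta in c(0.1, 1, 25)) {
    d <- sort(runif(50, 0, 10 * theta))
    w <- gaussian_weight(d, theta)
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("three collinear points produce exactly the hand-enumerated graph", {
  g <- build_spatial_graph(cbind(c(0, 1, 10), 0), k_neighbors = 1, theta = 1)
  a <- as.matrix(g$adjacency)
  # 1<->2 selected by both, weight exp(-1/2); 3's nearest is 2 (d = 9),
  # added by symmetrization; 1<->3 never selected
  expect_equal(a[1, 2], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(a[2, 1], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(a[2, 3], exp(-81 / 2), tolerance = 1e-15)
  expect_equal(a[3, 2], exp(-81 / 2), tolerance = 1e-15)
  expect_equal(a[1, 3], 0)
  expect_equal(a[3, 1], 0)
  expect_true(all(diag(a) == 0))
})

test_that("k >= n - 1 saturates to the complete graph with a warning", {
  set.seed(2)
  co <- matrix(runif(20), 10, 2)
  expect_warning(g <- build_spatial_graph(co, k_neighbors = 30, theta = 1),
                 "complete")
  a <- g$adjacency
  expect_equal(Matrix::nnzero(a), 90)   # 45 undirected edges stored twice
  expect_true(all(as.matrix(a) == t(as.matrix(a))))
})

test_that("adjacency is exactly symmetric and respects the sparsity bound", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(20:60, 1); k <- sample(3:8, 1)
    co <- matrix(runif(2 * n, 0, 50), n, 2)
    g <- build_spatial_graph(co, k_neighbors = k)
    expect_identical(as.matrix(g$adjacency), t(as.matrix(g$adjacency)))
    expect_lte(Matrix::nnzero(g$adjacency), 2 * n * k)
    expect_true(all(g$adjacency@x >= 0 & g$adjacency@x <= 1))
  }
})

test_that("scaling coordinates and theta together leaves the graph unchanged", {
  set.seed(4)
  co <- matrix(runif(80, 0, 10), 40, 2)
  g1 <- build_spatial_graph(co, k_neighbors = 5, theta = 2)
  g2 <- build_spatial_graph(co * 1000, k_neighbors = 5, theta = 2000)
  expect_lt(max(abs(g1$adjacency - g2$adjacency)), 1e-9)
  # theta = "auto" rescales with the coordinates by construction
  ga <- build_spatial_graph(co, k_neighbors = 5)
  gb <- build_spatial_graph(co * 1000, k_neighbors = 5)
  expect_equal(gb$theta / ga$theta, 1000, tolerance = 1e-9)
  expect_lt(max(abs(ga$adjacency - gb$adjacency)), 1e-9)
})

test_that("duplicate coordinates yield unit-weight edges", {
  g <- build_spatial_graph(rbind(c(0, 0), c(0, 0), c(5, 5)), k_neighbors = 1,
                           theta = 1)
  expect_equal(as.matrix(g$adjacency)[1, 2], 1)
})

test_that("normalize_adjacency matches hand computations", {
  # two coincident nodes, one unit-weight edge: A_norm all 0.5
  g <- build_spatial_graph(rbind(c(0, 0), c(0, 0)), k_neighbors = 1, theta = 1)
  g <- normalize_adjacency(g)
  expect_equal(as.matrix(g$normalized), matrix(0.5, 2, 2), tolerance = 1e-12)

  # single isolated node: self-loop only, A_norm = [1]
  iso <- structure(list(adjacency = Matrix::sparseMatrix(i = integer(0),
                                                         j = integer(0),
                                                         x = numeric(0),
                                                         dims = c(1, 1)),
                        theta = 1, k_neighbors = 1,
                        coords = matrix(0, 1, 2), normalized = NULL),
                   class = "spatial_graph")
  expect_equal(as.matrix(normalize_adjacency(iso)$normalized),
               matrix(1, 1, 1))

  # degree-regular unit-weight graph: all row sums of A_norm equal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  gr <- build_spatial_graph(sq, k_neighbors = 2, theta = 1)
  gr <- normalize_adjacency(gr)
  rs <- Matrix::rowSums(gr$normalized)
  expect_equal(max(rs) - min(rs), 0, tolerance = 1e-12)
})
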