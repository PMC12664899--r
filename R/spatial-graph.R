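#' Gaussian kernel weight of a spatial distance
#'
#' Converts a Euclidean distance between two cells into an edge weight
#' `exp(-d^2 / (2 theta^2))`: 1 at zero distance, strictly decreasing in `d`,
#' with decay scale set by `theta`.
#'
#' @param d non-negative distance(s).
#' @param theta positive decay coefficient.
#' @return weight(s) in `(0, 1]`.
#' @examples
#' gaussian_weight(0, 1)        # 1
#' gaussian_weight(1, 1)        # exp(-1/2)
#' @export
gaussian_weight <- function(d, theta) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("`theta` must be a single positive number")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (2 * theta^2))
}

# k nearest neighbours (excluding self) by blocked exact search.
# Returns list(idx = n x k integer, dist = n x k numeric).
.knn_euclidean <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  idx <- matrix(0L, n, k)
  dmat <- matrix(0, n, k)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances of this block to all points
    cross <- coords[rows, , drop = FALSE] %*% t(coords)
    d2 <- sq[rows] - 2 * cross
    d2 <- sweep(d2, 2, sq, "+")
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d2[r, ]
      di[i] <- Inf              # a cell is not its own neighbour
      ord <- order(di)[seq_len(k)]
      idx[i, ] <- ord
      dmat[i, ] <- sqrt(di[ord])
    }
  }
  list(idx = idx, dist = dmat)
}

#' Build the weighted spatial neighbour graph
#'
#' For every cell, edges to its `k_neighbors` nearest Euclidean neighbours are
#' created with Gaussian kernel weights [gaussian_weight()], and the directed
#' k-NN matrix is symmetrized by the elementwise maximum with its transpose
#' (so every selected edge keeps its kernel value). The diagonal is zero; self
#' loops are added only in the normalized form used by graph convolutions
#' (see [normalize_adjacency()]).
#'
#' @param coords n x 2 matrix of spatial positions (native units).
#' @param k_neighbors neighbours per cell (default 30). When
#'   `k_neighbors >= n - 1` the graph is complete and a warning is issued.
#' @param theta kernel decay coefficient, or `"auto"` (default) to use the
#'   median of all selected k-NN edge distances, which makes the kernel
#'   scale-free across coordinate units.
#' @return an object of class `spatial_graph`: list with `adjacency` (sparse
#'   symmetric `dgCMatrix`), `theta`, `k_neighbors`, `coords`, and
#'   `normalized` (`NULL` until [normalize_adjacency()] is called).
#' @examples
#' g <- build_spatial_graph(cbind(c(0, 1, 10), 0), k_neighbors = 1, theta = 1)
#' as.matrix(g$adjacency)
#' @export
build_spatial_graph <- function(coords, k_neighbors = 30, theta = "auto") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two cells to build a graph")
  if (ncol(coords) != 2) stop("`coords` must have two columns (x, y)")
  if (any(!is.finite(coords))) stop("`coords` must be finite")
  if (k_neighbors < 1) stop("`k_neighbors` must be positive")
  if (k_neighbors >= n)
    warning(sprintf("k_neighbors (%d) >= n (%d); building the complete graph",
                    k_neighbors, n))
  nn <- .knn_euclidean(coords, k_neighbors)
  if (identical(theta, "auto")) {
    theta <- stats::median(nn$dist)
    if (theta <= 0) theta <- 1  # all-duplicate coordinates: weights are 1 anyway
  }
  if (!is.numeric(theta) || theta <= 0)
    stop("`theta` must be positive or \"auto\"")
  k <- ncol(nn$idx)
  w <- gaussian_weight(nn$dist, theta)
  m <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                            j = as.vector(nn$idx), x = as.vector(w),
                            dims = c(n, n))
  mt <- Matrix::t(m)
  a <- (m + mt + abs(m - mt)) / 2  # elementwise max, sparse-safe
  a <- Matrix::drop0(a)
  structure(list(adjacency = as(a, "generalMatrix"), theta = theta,
                 k_neighbors = k_neighbors, coords = coords,
                 normalized = NULL),
            class = "spatial_graph")
}

#' Symmetrically normalize the adjacency for graph convolution
#'
#' Computes `A_norm = D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree
#' matrix of `A + I`, and stores it in the graph's `normalized` slot. Isolated
#' nodes end up with a unit self-loop.
#'
#' @param g a [build_spatial_graph()] result.
#' @return `g` with the `normalized` slot filled.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  n <- nrow(g$adjacency)
  ahat <- g$adjacency + Matrix::Diagonal(n)
  dg <- Matrix::rowSums(ahat)
  dinv <- Matrix::Diagonal(n, x = 1 / sqrt(dg))
  g$normalized <- as(dinv %*% ahat %*% dinv, "generalMatrix")
  g
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d cells, k = %d, theta = %.4g, %d edges%s\n",
              nrow(x$adjacency), x$k_neighbors, x$theta,
              length(x$adjacency@x) / 2,
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}
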