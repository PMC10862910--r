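# Spatial k-nearest-neighbour graph and the augmented propagation operator
# L = I + D^{-1/2} A D^{-1/2} used by every graph convolution.

#' Build the spot kNN graph and propagation matrix
#'
#' Computes the directed k-nearest-neighbour relation on spot centroids by
#' Euclidean distance (self excluded; ties broken by ascending spot index),
#' symmetrises it by logical OR into an undirected adjacency `A`, and forms
#' the augmented propagation operator `L = I + D^{-1/2} A D^{-1/2}` where `D`
#' is the degree of the symmetrised graph. The `+ I` term keeps each spot's
#' own signal in every propagation step; note this is not the conventional
#' normalised Laplacian `I - D^{-1/2} A D^{-1/2}`.
#'
#' @param coords N × 2 matrix of spot centroid coordinates.
#' @param k number of nearest neighbours (default 3, the setting with the
#'   best spatial-clustering performance on Visium lattices).
#' @return a `spatial_graph`: list with sparse `A`, degree vector `D`,
#'   sparse `L`, `k`, the directed neighbour index matrix `knn` (N × k, used
#'   by the contrastive read-out), and `coords`.
#' @export
build_knn_graph <- function(coords, k = 3) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop_proust("coordinates must be finite")
  if (k < 1) stop_proust("k must be >= 1")
  if (n <= k) stop_proust("need more spots (", n, ") than neighbours k = ", k)
  d2 <- as.matrix(stats::dist(coords))^2
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))                # ties by ascending index
    o <- o[o != i]
    knn[i, ] <- o[seq_len(k)]
  }
  A_dir <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                                j = as.vector(t(knn)),
                                x = 1, dims = c(n, n))
  A <- ((A_dir + Matrix::t(A_dir)) > 0) * 1        # OR-symmetrisation
  deg <- Matrix::rowSums(A)
  dinv <- Matrix::Diagonal(n, 1 / sqrt(deg))
  L <- Matrix::Diagonal(n) + dinv %*% A %*% dinv
  structure(list(A = A, D = deg, L = L, k = k, knn = knn, coords = coords),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d spots, k = %d, %d undirected edges\n",
              length(x$D), x$k, sum(x$A) / 2))
  invisible(x)
}
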