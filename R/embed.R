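## Per-view embedding: PCA on cells, shared-nearest-neighbor graph, and a
## UMAP layout for visualization (never used for clustering).

#' PCA embedding of cells
#'
#' Centers each feature (gene or wavelet coefficient) and computes principal
#' component scores for the cells, ordered by decreasing explained variance.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive, making the embedding fully deterministic.
#'
#' @param X Feature x cell matrix.
#' @param n_pcs Number of components to retain (clamped to what the data
#'   supports).
#' @return Cell x `n_pcs` score matrix with attribute `"sdev"` (component
#'   standard deviations) and `"rotation"`.
#' @export
embed_pca <- function(X, n_pcs = 30) {
  X <- as.matrix(X)
  n_pcs <- min(n_pcs, nrow(X), ncol(X) - 1)
  if (n_pcs < 1) stop("not enough cells/features for PCA")
  vars <- matrixStats::rowVars(X)
  if (all(vars < .Machine$double.eps)) {
    stop("constant matrix: no variance to decompose")
  }
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 1)
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- colnames(X)
  structure(scores, sdev = pc$sdev[seq_len(ncol(scores))],
            rotation = sweep(pc$rotation, 2, flip, `*`))
}

## Exact k-nearest-neighbour indices with stable index-order tie-breaking:
## among equidistant candidates the smaller column index wins.
.knn_indices <- function(scores, k) {
  p <- nrow(scores)
  if (k >= p) stop("k_neighbors = ", k, " must be below the number of cells (", p, ")")
  d <- as.matrix(stats::dist(scores))
  idx <- matrix(0L, p, k)
  for (i in seq_len(p)) {
    ord <- order(d[i, ], seq_len(p))   # ties broken by index
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  idx
}

#' Shared-nearest-neighbor graph of cells
#'
#' Connects each cell to its `k_neighbors` exact nearest neighbors in the
#' embedding (Euclidean; equidistant ties broken by stable cell-index
#' order), then weights each edge by the Jaccard overlap of the two cells'
#' neighborhoods (each neighborhood includes the cell itself). The result
#' is a symmetric, weighted, undirected graph; pairs with zero shared
#' neighbors carry no edge.
#'
#' @param scores Cell x feature score matrix (e.g. from [embed_pca()]).
#' @param k_neighbors Neighborhood size.
#' @return An [igraph::graph] with edge attribute `weight` in (0, 1].
#' @export
build_knn_graph <- function(scores, k_neighbors = 20) {
  scores <- as.matrix(scores)
  p <- nrow(scores)
  idx <- .knn_indices(scores, k_neighbors)
  nbr <- lapply(seq_len(p), function(i) c(i, idx[i, ]))
  ## candidate edges: knn pairs (either direction)
  from <- rep(seq_len(p), each = k_neighbors)
  to <- as.integer(t(idx))
  pair <- cbind(pmin(from, to), pmax(from, to))
  pair <- unique(pair)
  w <- vapply(seq_len(nrow(pair)), function(e) {
    a <- nbr[[pair[e, 1]]]
    b <- nbr[[pair[e, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * (k_neighbors + 1) - ov)
  }, 1)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pair[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, p - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  if (!is.null(rownames(scores))) igraph::V(g)$name <- rownames(scores)
  g
}

#' UMAP layout for visualization
#'
#' Two- or three-dimensional UMAP of the PCA scores, for plotting only:
#' cluster labels are never derived from these coordinates. Deterministic
#' for a fixed seed (single-threaded).
#'
#' @param scores Cell x feature matrix.
#' @param umap_dims 2 or 3.
#' @param n_neighbors UMAP neighborhood size.
#' @param seed Integer seed.
#' @return Tibble with columns `barcode` and `umap_1` .. `umap_<dims>`.
#' @export
embed_umap <- function(scores, umap_dims = 2, n_neighbors = 15, seed = 0) {
  scores <- as.matrix(scores)
  stopifnot(umap_dims %in% c(2, 3))
  if (nrow(scores) <= n_neighbors) {
    stop("fewer cells (", nrow(scores), ") than n_neighbors (", n_neighbors, ")")
  }
  set.seed(seed)
  coords <- uwot::umap(scores, n_components = umap_dims,
                       n_neighbors = n_neighbors,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  colnames(coords) <- paste0("umap_", seq_len(umap_dims))
  out <- tibble::as_tibble(coords)
  out$barcode <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  dplyr::relocate(out, "barcode")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
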