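test_that("decompose_views yields M+1 views that sum to the input", {
  set.seed(2)
  # 32 rows: divisible by 2 and 4, so reconstructions carry no pad rows and
  # component orthogonality holds exactly in gene space
  S <- matrix(abs(rnorm(32 * 12)), 32, 12,
              dimnames = list(sprintf("g%02d", 1:32), sprintf("c%02d", 1:12)))
  for (M in c(2, 4)) {
    vs <- decompose_views(S, M, if (M == 2) "haar" else NULL)
    expect_equal(names(vs$views),
                 c("original", "approx", paste0("detail-", seq_len(M - 1))))
    recon_sum <- Reduce(`+`, lapply(vs$views[-1], `[[`, "recon"))
    expect_lt(max(abs(recon_sum - S)), 1e-8)
    expect_equal(vs$views$original$recon, S)
    # distinct component reconstructions are orthogonal column-wise
    labs <- names(vs$views)[-1]
    for (i in seq_along(labs)[-1]) {
      for (j in seq_len(i - 1)) {
        ip <- colSums(vs$views[[labs[i]]]$recon * vs$views[[labs[j]]]$recon)
        expect_lt(max(abs(ip)), 1e-8)
      }
    }
  }
})

test_that("coefficient-space and reconstruction-space cell distances agree", {
  # holds exactly when no pad rows are stripped (the block columns of W^T
  # are orthonormal); decompose_views() therefore clusters on coefficients
  set.seed(9)
  S <- matrix(rnorm(28 * 15), 28, 15)
  vs <- decompose_views(S, 4)
  for (lab in c("approx", "detail-2")) {
    dc <- as.matrix(dist(t(vs$views[[lab]]$coef)))
    dr <- as.matrix(dist(t(vs$views[[lab]]$recon)))
    expect_equal(dc, dr, tolerance = 1e-8)
    # hence identical KNN graphs
    g1 <- build_knn_graph(t(vs$views[[lab]]$coef), 4)
    g2 <- build_knn_graph(t(vs$views[[lab]]$recon), 4)
    expect_equal(igraph::as_adjacency_matrix(g1, attr = "weight", sparse = FALSE),
                 igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("PCA recovers exactly planar data and orders variance", {
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
  load2 <- matrix(rnorm(2 * 40), 2, 40) * c(3, 1)
  X <- basis %*% load2          # features x cells, exact rank 2
  sc <- embed_pca(X, 2)
  # reconstruction from 2 PCs is exact
  rec <- sc %*% t(attr(sc, "rotation"))
  expect_lt(max(abs(rec - t(X - rowMeans(X)))), 1e-8)
  expect_true(all(diff(attr(sc, "sdev")) <= 1e-12))
  expect_error(embed_pca(matrix(1, 5, 6)), "constant")
  # deterministic, including sign convention
  expect_equal(embed_pca(X, 2), embed_pca(X, 2))
})

test_that("KNN ties break by stable index order and the graph is symmetric", {
  # collinear points: the middle one is exactly equidistant from both ends
  pts <- cbind(c(0, 1, 2), 0)
  idx <- wmclust:::.knn_indices(pts, 1)
  expect_equal(as.vector(idx), c(2L, 1L, 2L))  # tie of node 2 -> lower index
  g <- build_knn_graph(pts, 1)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(A, t(A))
})

test_that("well-separated blobs produce no cross-blob edges", {
  b <- blob_matrix(2, 25, dim = 5, sep = 50, seed = 3)
  g <- build_knn_graph(t(b$X), 5)
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- b$labels[el[, 1]] == b$labels[el[, 2]]
  expect_true(all(same))
  expect_error(build_knn_graph(t(b$X), 50), "below the number of cells")
})

test_that("Louvain finds disconnected cliques exactly and is seed-stable", {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(8)
  igraph::E(g)$weight <- 1
  cl <- cluster_graph(g, seed = 1)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$labels, rep(c(1L, 0L), c(6, 8)))  # larger clique labeled 0
  expect_equal(cluster_graph(g, seed = 1)$labels, cl$labels)
  expect_error(cluster_graph(igraph::make_empty_graph(0)), "empty graph")
})

test_that("planted Gaussian blobs are recovered through PCA + SNN + Louvain", {
  b <- blob_matrix(4, 100, dim = 20, sep = 10, sigma = 1, seed = 0)
  sc <- embed_pca(b$X, 10)
  cl <- cluster_graph(build_knn_graph(sc, 20), resolution = 1, seed = 0)
  expect_gte(ari(cl$labels, b$labels), 0.95)
})

test_that("UMAP layouts are deterministic and separate blobs", {
  b <- blob_matrix(2, 40, dim = 8, sep = 20, seed = 6)
  sc <- embed_pca(b$X, 5)
  u1 <- embed_umap(sc, 2, seed = 7)
  u2 <- embed_umap(sc, 2, seed = 7)
  expect_equal(u1, u2)
  expect_equal(dim(u1), c(80L, 3L))  # barcode + 2 coords
  xy <- as.matrix(u1[, c("umap_1", "umap_2")])
  c1 <- colMeans(xy[b$labels == 1, ])
  c2 <- colMeans(xy[b$labels == 2, ])
  within <- mean(dist(xy[b$labels == 1, ]))
  expect_gt(sqrt(sum((c1 - c2)^2)), within)
  expect_error(embed_umap(sc[1:5, ], n_neighbors = 10), "fewer cells")
})

test_that("run_multiview produces per-view assignments deterministically", {
  sim <- simulate_counts(sim_config(n_genes = 400, cells_per_subcluster = 20,
                                    base_mean = 2, seed = 1))
  cfg <- multiview_config(M = 2, family = "haar", umap = FALSE, seed = 0,
                          k_neighbors = 10, n_pcs = 15)
  res <- run_multiview(sim$counts, cfg)
  expect_named(res$clusters, c("original", "approx", "detail-1"))
  expect_equal(nrow(tidy(res)), 3 * length(res$barcodes))
  expect_s3_class(glance(res), "tbl_df")
  # rerun: identical labels, and byte-identical CSV export
  res2 <- run_multiview(sim$counts, cfg)
  expect_identical(lapply(res$clusters, `[[`, "labels"),
                   lapply(res2$clusters, `[[`, "labels"))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tidy(res), f1, row.names = FALSE)
  utils::write.csv(tidy(res2), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("stage failures name the failing stage", {
  sim <- simulate_counts(sim_config(n_genes = 400, cells_per_subcluster = 20,
                                    base_mean = 2, seed = 1))
  bad <- multiview_config(M = 2, umap = FALSE,
                          thresholds = qc_thresholds(min_genes_per_cell = 299,
                                                     max_genes_per_cell = 300))
  expect_error(run_multiview(sim$counts, bad), "stage 'qc'")
})
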