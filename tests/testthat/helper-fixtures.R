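# Small fixtures constructed in code.

# 5-gene x 4-cell count matrix with one mitochondrial gene and hand-checkable
# QC metrics.
fixture_counts <- function() {
  m <- matrix(c(
    3, 0, 5, 0,
    2, 0, 1, 0,
    0, 4, 0, 0,
    1, 1, 2, 0,
    0, 2, 0, 0), nrow = 5, byrow = TRUE)
  raw_count_matrix(m,
                   gene_ids = c("G1", "MT-1", "G3", "G4", "G5"),
                   barcodes = c("bc1", "bc2", "bc3", "bc4"))
}

# sparse matrix whose cells have an exact number of detected genes
counts_with_n_genes <- function(n_genes_per_cell, n_genes_total) {
  p <- length(n_genes_per_cell)
  i <- unlist(lapply(n_genes_per_cell, seq_len))
  j <- rep(seq_len(p), n_genes_per_cell)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_genes_total, p))
  raw_count_matrix(m,
                   gene_ids = sprintf("G%05d", seq_len(n_genes_total)),
                   barcodes = sprintf("bc%03d", seq_len(p)))
}

# well-separated Gaussian blobs in `dim` dimensions: returns features x cells
blob_matrix <- function(n_blobs, cells_per_blob, dim = 10, sep = 10,
                        sigma = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_blobs * dim), n_blobs, dim)
  centers <- centers / sqrt(rowSums(centers^2)) * sep * sigma
  X <- do.call(cbind, lapply(seq_len(n_blobs), function(b) {
    matrix(rnorm(dim * cells_per_blob, mean = centers[b, ], sd = sigma),
           dim, cells_per_blob)
  }))
  colnames(X) <- sprintf("c%04d", seq_len(ncol(X)))
  list(X = X, labels = rep(seq_len(n_blobs), each = cells_per_blob))
}
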