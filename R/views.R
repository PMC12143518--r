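## Decomposition of a normalized gene x cell matrix into multi-resolution
## views: the untransformed original, the approximation component, and the
## M-1 detail components. Each view carries both its coefficient matrix
## (k x p, used for embedding and clustering: the block columns of W^T are
## orthonormal, so pairwise cell distances in coefficient space equal those
## in gene-space reconstruction) and its n x p gene-space reconstruction
## (used for marker detection, where gene identity matters).

#' Decompose a normalized matrix into wavelet views
#'
#' Pads the gene axis to a multiple of M, builds the M-band DWT matrix,
#' forward-transforms, and reconstructs every orthogonal component. Returns
#' M + 1 views: `original`, `approx`, `detail-1` .. `detail-(M-1)`.
#' Reconstructions are stripped of pad rows, so they share the input's gene
#' ids and sum to the input matrix. Component orthogonality is exact in the
#' padded space; when pad rows were added (gene count not divisible by M),
#' the stripped reconstructions are orthogonal only up to the pad-row
#' contribution.
#'
#' @param S_norm Normalized gene x cell matrix (e.g. from [log_normalize()]).
#' @param M Band count (2, 3 or 4).
#' @param family Filter family (see [build_filter_bank()]).
#' @return A `wmc_views` object: list with `views` (named list; each view has
#'   `label`, `coef` (features x cells) and `recon` (genes x cells)), `M`,
#'   `family`, `padding`, `gene_ids`.
#' @export
decompose_views <- function(S_norm, M = 2, family = NULL) {
  S_norm <- as.matrix(S_norm)
  if (!all(is.finite(S_norm))) stop("S_norm contains non-finite values")
  fb <- build_filter_bank(M, family)
  padded <- pad_genes(S_norm, fb$M)
  W <- build_dwt_matrix(fb, nrow(padded$S))
  C <- forward_dwt(W, padded$S)
  C$padding <- padded$padding
  n <- nrow(S_norm)
  strip <- function(mat) mat[seq_len(n), , drop = FALSE]
  views <- list(original = list(label = "original",
                                coef = S_norm, recon = S_norm))
  for (lab in names(W$block_index)) {
    coef <- if (lab == "approx") C$a else C$details[[lab]]
    views[[lab]] <- list(label = lab, coef = coef,
                         recon = strip(reconstruct_component(W, C, lab)))
  }
  structure(list(views = views, M = fb$M, family = fb$family,
                 padding = padded$padding,
                 gene_ids = rownames(S_norm),
                 barcodes = colnames(S_norm)),
            class = "wmc_views")
}

#' @export
print.wmc_views <- function(x, ...) {
  cat(sprintf("<wmc_views> M = %d ('%s'): %s; %d genes (+%d pad) x %d cells\n",
              x$M, x$family, paste(names(x$views), collapse = ", "),
              length(x$gene_ids), x$padding,
              ncol(x$views$original$coef)))
  invisible(x)
}
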