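## Marker-gene detection per view: for every cluster, a two-sided Wilcoxon
## rank-sum test of in-cluster cells versus all remaining cells, gene by
## gene, with multiplicity adjustment across genes within each cluster
## comparison. A gene is a marker when its adjusted p-value passes alpha and
## the absolute in/out mean difference passes the effect floor. Detail-view
## reconstructions contain negative values; the rank-sum test is
## location-based and does not require nonnegativity.

## Vectorized two-sided rank-sum test across the rows of X (features) for
## group membership `in_grp` (logical over columns). Normal approximation
## with tie correction and continuity correction, matching
## wilcox.test(exact = FALSE, correct = TRUE).
.ranksum_rows <- function(X, in_grp) {
  n1 <- sum(in_grp)
  n2 <- sum(!in_grp)
  N <- n1 + n2
  R <- matrixStats::rowRanks(X, ties.method = "average")
  W <- rowSums(R[, in_grp, drop = FALSE]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  mu <- n1 * n2 / 2
  ## tie correction: sum over tie groups of (t^3 - t)
  ties <- apply(X, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - ties / (N * (N - 1)))
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * pnorm(-abs(z))
  pmin(p, 1)
}

#' Detect marker genes for one clustered view
#'
#' For each cluster, tests every gene (in-cluster vs rest, two-sided
#' Wilcoxon rank-sum, normal approximation) and adjusts p-values across
#' genes within the cluster comparison (Benjamini-Hochberg by default). A
#' gene is a marker for a cluster if `p_adj <= alpha` and the absolute
#' difference of in/out means is at least `min_abs_effect`. The view's
#' marker set is the union over clusters.
#'
#' @param view_reconstruction Gene x cell matrix of the view (gene-space
#'   reconstruction so gene identity is preserved; pad rows must already be
#'   stripped, as [decompose_views()] does).
#' @param clusters A `wmc_clusters` (or bare label vector) over the same
#'   cells.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_abs_effect Minimum |mean difference| on the expression /
#'   component scale (default 0.25).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`; `"none"` for raw p-values).
#' @return A `wmc_markers` object: list with `genes` (character union),
#'   `table` (tibble: `gene`, `cluster`, `p`, `p_adj`, `mean_diff`,
#'   `is_marker`), and the thresholds used.
#' @export
find_markers <- function(view_reconstruction, clusters, alpha = 0.05,
                         min_abs_effect = 0.25, p_adjust = "BH") {
  X <- as.matrix(view_reconstruction)
  labels <- if (inherits(clusters, "wmc_clusters")) clusters$labels
            else as.integer(clusters)
  if (length(labels) != ncol(X)) {
    stop("label vector length != number of cells")
  }
  ulab <- sort(unique(labels))
  if (length(ulab) < 2) stop("marker detection needs at least 2 clusters")
  genes <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  tabs <- lapply(ulab, function(cl) {
    in_grp <- labels == cl
    if (!any(in_grp) || all(in_grp)) stop("empty cluster ", cl)
    p <- .ranksum_rows(X, in_grp)
    mean_diff <- rowMeans(X[, in_grp, drop = FALSE]) -
      rowMeans(X[, !in_grp, drop = FALSE])
    p_adj <- p.adjust(p, method = p_adjust)
    tibble::tibble(gene = genes, cluster = cl, p = p, p_adj = p_adj,
                   mean_diff = mean_diff,
                   is_marker = p_adj <= alpha & abs(mean_diff) >= min_abs_effect)
  })
  tab <- dplyr::bind_rows(tabs)
  structure(list(genes = sort(unique(tab$gene[tab$is_marker])),
                 table = tab,
                 alpha = alpha, min_abs_effect = min_abs_effect,
                 p_adjust = p_adjust),
            class = "wmc_markers")
}

#' @export
print.wmc_markers <- function(x, ...) {
  cat(sprintf("<wmc_markers> %d marker genes (alpha = %g, min |effect| = %g, %s)\n",
              length(x$genes), x$alpha, x$min_abs_effect, x$p_adjust))
  invisible(x)
}

#' Marker-gene sets for every view of a multi-view result
#'
#' Runs [find_markers()] on each view's gene-space reconstruction with that
#' view's own cluster labels, producing the ordered gene-set collection
#' G_0 (original), G_1 (approximation), G_2.. (details) used by
#' [intersection_analysis()].
#'
#' @param result A `wmc_result`.
#' @param ... Passed to [find_markers()].
#' @return A `wmc_gene_sets` object: list with `sets` (named list of
#'   character vectors in view order), `universe` (all tested genes), and
#'   `detail` (the per-view `wmc_markers`).
#' @export
marker_gene_sets <- function(result, ...) {
  stopifnot(inherits(result, "wmc_result"))
  views <- result$views$views
  per_view <- lapply(names(views), function(lab) {
    find_markers(views[[lab]]$recon, result$clusters[[lab]], ...)
  })
  names(per_view) <- names(views)
  structure(list(sets = lapply(per_view, function(m) m$genes),
                 universe = result$views$gene_ids,
                 detail = per_view),
            class = "wmc_gene_sets")
}
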