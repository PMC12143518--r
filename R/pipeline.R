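## The end-to-end multi-view pipeline:
## QC -> log-normalize -> M-band decomposition -> per-view PCA -> SNN graph
## -> Louvain -> (optional) UMAP. Each stochastic stage reuses the single
## configured seed in every view, so views differ only through the transform.

#' Pipeline configuration
#'
#' @param M Band count (2, 3 or 4).
#' @param family Wavelet family (`NULL` = default for `M`; see
#'   [build_filter_bank()]).
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param normalization `"library-size"` or `"plain-log1p"`.
#' @param scale_factor Library-size target (default 10,000).
#' @param n_pcs Principal components per view (default 30).
#' @param k_neighbors SNN neighborhood size (default 20).
#' @param resolution Louvain resolution (default 1.0).
#' @param umap Compute UMAP layouts? (visualization only).
#' @param umap_dims 2 or 3.
#' @param seed Integer seed used by every stochastic stage.
#' @return A `wmc_config` list.
#' @export
multiview_config <- function(M = 2, family = NULL,
                             thresholds = qc_thresholds(),
                             normalization = c("library-size", "plain-log1p"),
                             scale_factor = 1e4,
                             n_pcs = 30, k_neighbors = 20, resolution = 1.0,
                             umap = TRUE, umap_dims = 2, seed = 0) {
  normalization <- match.arg(normalization)
  stopifnot(n_pcs >= 1, k_neighbors >= 1, resolution > 0,
            umap_dims %in% c(2, 3))
  structure(list(M = M, family = family, thresholds = thresholds,
                 normalization = normalization, scale_factor = scale_factor,
                 n_pcs = n_pcs, k_neighbors = k_neighbors,
                 resolution = resolution, umap = umap,
                 umap_dims = umap_dims, seed = as.integer(seed)),
            class = "wmc_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full multi-view clustering pipeline
#'
#' Executes QC filtering, log normalization, the M-band wavelet
#' decomposition, and per-view PCA + SNN graph + Louvain clustering (plus an
#' optional UMAP layout per view). Every view uses the same seed and
#' parameters, so partitions are comparable across views.
#'
#' @param x A `wmc_counts` (raw counts) or a pre-normalized gene x cell
#'   matrix (in which case QC and normalization are skipped).
#' @param config A [multiview_config()].
#' @return A `wmc_result`: list with `views` (the `wmc_views`), `clusters`
#'   (named list of `wmc_clusters`, one per view), `umap` (named list of
#'   tibbles or `NULL`), `qc` (removal logs), `config`, `barcodes`.
#' @export
run_multiview <- function(x, config = multiview_config()) {
  stopifnot(inherits(config, "wmc_config"))
  qc_log <- NULL
  if (inherits(x, "wmc_counts")) {
    filtered <- .stage("qc", {
      cells <- filter_cells(x, thresholds = config$thresholds)
      genes <- filter_genes(cells, thresholds = config$thresholds)
      attr(genes, "removal_log") <- attr(cells, "removal_log")
      genes
    })
    qc_log <- list(cells = attr(filtered, "removal_log"),
                   genes = attr(filtered, "gene_removal_log"))
    S <- .stage("normalize",
                log_normalize(filtered, config$scale_factor,
                              config$normalization))
  } else {
    S <- as.matrix(x)
    if (is.null(colnames(S))) colnames(S) <- paste0("cell", seq_len(ncol(S)))
  }
  vs <- .stage("decompose", decompose_views(S, config$M, config$family))
  clusters <- list()
  umaps <- if (config$umap) list() else NULL
  for (lab in names(vs$views)) {
    coef <- vs$views[[lab]]$coef
    scores <- .stage(paste0("pca:", lab), embed_pca(coef, config$n_pcs))
    rownames(scores) <- colnames(S)
    g <- .stage(paste0("knn:", lab),
                build_knn_graph(scores, config$k_neighbors))
    clusters[[lab]] <- .stage(paste0("louvain:", lab),
                              cluster_graph(g, config$resolution,
                                            config$seed, view_label = lab))
    clusters[[lab]]$parameters <- c(clusters[[lab]]$parameters,
                                    list(n_pcs = config$n_pcs,
                                         k_neighbors = config$k_neighbors,
                                         M = vs$M, family = vs$family))
    if (config$umap) {
      umaps[[lab]] <- .stage(paste0("umap:", lab),
                             embed_umap(scores, config$umap_dims,
                                        n_neighbors = min(15, ncol(S) - 1),
                                        seed = config$seed))
    }
  }
  structure(list(views = vs, clusters = clusters, umap = umaps,
                 qc = qc_log, config = config, barcodes = colnames(S)),
            class = "wmc_result")
}

#' @export
print.wmc_result <- function(x, ...) {
  cat(sprintf("<wmc_result> M = %d ('%s'), %d cells, views: %s\n",
              x$views$M, x$views$family, length(x$barcodes),
              paste(sprintf("%s[%d]", names(x$clusters),
                            vapply(x$clusters, function(cl) cl$n_clusters, 1L)),
                    collapse = " ")))
  invisible(x)
}

#' Tidy per-cell cluster labels of a multi-view result
#'
#' @param x A `wmc_result`.
#' @param ... Unused.
#' @return Tibble with columns `barcode`, `view`, `cluster` (one row per
#'   cell and view).
#' @exportS3Method generics::tidy
tidy.wmc_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$clusters, tidy))
}

#' One-row-per-view summary of a multi-view result
#'
#' @param x A `wmc_result`.
#' @param ... Unused.
#' @return Tibble with `view`, `n_clusters`, `n_cells`, `M`, `family`,
#'   `resolution`, `seed`.
#' @exportS3Method generics::glance
glance.wmc_result <- function(x, ...) {
  tibble::tibble(
    view = names(x$clusters),
    n_clusters = vapply(x$clusters, function(cl) cl$n_clusters, 1L),
    n_cells = length(x$barcodes),
    M = x$views$M, family = x$views$family,
    resolution = x$config$resolution, seed = x$config$seed)
}

#' UMAP panels of a multi-view result
#'
#' One scatter panel per view, colored by that view's cluster labels.
#' Requires the pipeline to have been run with `umap = TRUE`.
#'
#' @param object A `wmc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wmc_result <- function(object, ...) {
  if (is.null(object$umap)) stop("pipeline was run with umap = FALSE")
  dat <- dplyr::bind_rows(lapply(names(object$umap), function(lab) {
    dplyr::mutate(
      dplyr::inner_join(object$umap[[lab]], tidy(object$clusters[[lab]]),
                        by = "barcode"),
      view = lab)
  }))
  dat$view <- factor(dat$view, levels = names(object$umap))
  ggplot2::ggplot(dat, ggplot2::aes(.data$umap_1, .data$umap_2,
                                    color = factor(.data$cluster))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::facet_wrap(~view) +
    ggplot2::labs(color = "cluster", x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
}
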