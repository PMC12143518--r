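## Graph clustering: Louvain modularity optimization on the SNN graph, with
## deterministic seeding and size-ordered contiguous relabeling.

#' Construct a cluster assignment
#'
#' @param labels Integer vector of per-cell labels (any coding; relabeled to
#'   0-based contiguous integers ordered by decreasing cluster size, ties by
#'   first appearance).
#' @param view_label Which view the labels belong to.
#' @param parameters Named list of provenance (n_pcs, k_neighbors,
#'   resolution, seed, ...).
#' @param barcodes Optional cell identifiers.
#' @return A `wmc_clusters` object.
#' @export
cluster_assignment <- function(labels, view_label = "original",
                               parameters = list(), barcodes = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("every cell must be labeled")
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(remap[as.character(labels)])
  structure(list(labels = labels,
                 n_clusters = length(sizes),
                 view_label = view_label,
                 parameters = parameters,
                 barcodes = barcodes),
            class = "wmc_clusters")
}

#' @export
print.wmc_clusters <- function(x, ...) {
  cat(sprintf("<wmc_clusters> view '%s': %d cells in %d clusters\n",
              x$view_label, length(x$labels), x$n_clusters))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wmc_clusters <- function(x, ...) {
  tibble::tibble(
    barcode = x$barcodes %||% as.character(seq_along(x$labels)),
    view = x$view_label,
    cluster = x$labels)
}

#' Louvain community detection on a cell graph
#'
#' Runs modularity-based Louvain community detection at the given
#' resolution. Deterministic for a fixed seed; labels are relabeled to
#' 0-based contiguous integers ordered by decreasing cluster size.
#'
#' @param graph Weighted undirected [igraph::graph] (e.g. from
#'   [build_knn_graph()]).
#' @param resolution Modularity resolution parameter (larger values give
#'   more, smaller clusters).
#' @param seed Integer seed.
#' @param view_label Provenance label stored in the result.
#' @return A `wmc_clusters` object.
#' @export
cluster_graph <- function(graph, resolution = 1.0, seed = 0,
                          view_label = "original") {
  if (!igraph::is_igraph(graph) || igraph::vcount(graph) == 0) {
    stop("empty graph")
  }
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  cluster_assignment(igraph::membership(comm),
                     view_label = view_label,
                     parameters = list(resolution = resolution, seed = seed),
                     barcodes = igraph::V(graph)$name)
}
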