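## Exclusive intersection analysis of per-view marker-gene sets.
##
## For view sets G_0 .. G_M and every non-empty subset Lambda of {0..M},
## N_Lambda collects the genes present in exactly the views of Lambda:
##   N_Lambda = (intersect over i in Lambda of G_i)
##              minus (union over j not in Lambda of G_j).
## The N_Lambda therefore partition the union of all sets. Because the
## wavelet components live in mutually orthogonal subspaces, the cells with
## |Lambda| >= 2 that exclude the original view are expected to be nearly
## empty; their total is reported as the cross-component leakage diagnostic.

#' Exclusive intersection analysis of view gene sets
#'
#' Enumerates, for every non-empty subset of views, the genes significant in
#' exactly those views (UpSet-style exclusive membership). The resulting
#' cells partition the union of all sets.
#'
#' @param sets A `wmc_gene_sets`, or a named list of character vectors in
#'   view order (original first, then approximation, then details).
#' @return A `wmc_intersections` object: tibble with one row per non-empty
#'   subset — `mask` (membership bitstring over views), `views`
#'   (`"+"`-joined view labels), `n_views`, `size`, `genes` (list-column) —
#'   with attributes `set_names`, `set_totals`, `universe_size` and
#'   `leakage` (total size of cells with `n_views >= 2` excluding the first
#'   set).
#' @export
intersection_analysis <- function(sets) {
  if (inherits(sets, "wmc_gene_sets")) sets <- sets$sets
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets))) {
    names(sets) <- c("original", "approx",
                     paste0("detail-", seq_len(max(0, length(sets) - 2))))[
                       seq_along(sets)]
  }
  nv <- length(sets)
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes), ncol = nv)
  mask <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  ## enumerate every non-empty subset so empty cells are reported too
  combos <- expand.grid(rep(list(c(0L, 1L)), nv))[-1, , drop = FALSE]
  all_masks <- apply(combos, 1, function(r) paste(r, collapse = ""))
  rows <- lapply(all_masks, function(mk) {
    idx <- which(mask == mk)
    sel <- which(strsplit(mk, "")[[1]] == "1")
    tibble::tibble(mask = mk,
                   views = paste(names(sets)[sel], collapse = "+"),
                   n_views = length(sel),
                   size = length(idx),
                   genes = list(if (length(idx)) all_genes[idx] else character()))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$size), .data$mask)
  leakage <- sum(out$size[out$n_views >= 2 &
                            substr(out$mask, 1, 1) == "0"])
  structure(out,
            class = c("wmc_intersections", class(out)),
            set_names = names(sets),
            set_totals = vapply(sets, length, 1L),
            universe_size = length(all_genes),
            leakage = leakage)
}

#' @export
print.wmc_intersections <- function(x, ...) {
  cat(sprintf("<wmc_intersections> %d view sets, union = %d genes, cross-component leakage = %d\n",
              length(attr(x, "set_names")), attr(x, "universe_size"),
              attr(x, "leakage")))
  NextMethod()
}

#' UpSet-style bar chart of exclusive intersections
#'
#' @param x A `wmc_intersections`.
#' @param top Show at most this many non-empty cells (largest first).
#' @return A ggplot object.
#' @export
plot_intersection <- function(x, top = 20) {
  stopifnot(inherits(x, "wmc_intersections"))
  dat <- dplyr::slice_head(
    dplyr::arrange(dplyr::filter(tibble::as_tibble(x), .data$size > 0),
                   dplyr::desc(.data$size)),
    n = top)
  dat$views <- factor(dat$views, levels = rev(dat$views))
  ggplot2::ggplot(dat, ggplot2::aes(.data$size, .data$views)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "genes in exactly this view subset", y = NULL) +
    ggplot2::theme_minimal()
}
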