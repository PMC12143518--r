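## Quality control: per-cell metrics, the standard cell and gene filters,
## and log normalization.
##
## Filter semantics follow the strict-inequality reading of the usual
## criteria: cells are removed when the number of detected genes is strictly
## below min_genes_per_cell or strictly above max_genes_per_cell, or when
## the mitochondrial fraction is strictly above max_mito_fraction; genes are
## removed when detected in strictly fewer than min_cells_per_gene cells.
## Boundary cases (exactly 200 / 3000 genes, exactly 20 cells) are retained.

#' Quality-control thresholds
#'
#' Default thresholds: cells must have between 200 and 3000 detected genes
#' (inclusive) and at most 5% mitochondrial counts; genes must be detected
#' in at least 20 cells.
#'
#' @param min_genes_per_cell,max_genes_per_cell Bounds on detected genes per cell.
#' @param min_cells_per_gene Minimum cells in which a gene must be detected.
#' @param max_mito_fraction Maximum mitochondrial count fraction per cell.
#' @return A `wmc_qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200,
                          max_genes_per_cell = 3000,
                          min_cells_per_gene = 20,
                          max_mito_fraction = 0.05) {
  stopifnot(min_genes_per_cell < max_genes_per_cell,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            min_cells_per_gene >= 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_genes_per_cell = max_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_fraction = max_mito_fraction),
            class = "wmc_qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, for every barcode: the count depth (total counts), the number
#' of detected genes (count > 0), and the mitochondrial count fraction.
#' Cells with zero total counts get `mito_fraction = 0` (they fail the
#' minimum-genes filter regardless).
#'
#' @param x A `wmc_counts`.
#' @return A tibble with columns `barcode`, `count_depth`, `n_genes`,
#'   `mito_fraction`.
#' @export
compute_qc_metrics <- function(x) {
  stopifnot(inherits(x, "wmc_counts"))
  depth <- Matrix::colSums(x$counts)
  n_genes <- Matrix::colSums(x$counts > 0)
  mito <- if (any(x$mito_mask)) {
    Matrix::colSums(x$counts[x$mito_mask, , drop = FALSE])
  } else rep(0, ncol(x$counts))
  mito_fraction <- ifelse(depth > 0, mito / depth, 0)
  tibble::tibble(barcode = x$barcodes,
                 count_depth = as.numeric(depth),
                 n_genes = as.integer(n_genes),
                 mito_fraction = as.numeric(mito_fraction))
}

.cell_filter_reason <- function(metrics, thresholds) {
  dplyr::case_when(
    metrics$n_genes < thresholds$min_genes_per_cell ~ "low_genes",
    metrics$n_genes > thresholds$max_genes_per_cell ~ "high_genes",
    metrics$mito_fraction > thresholds$max_mito_fraction ~ "high_mito",
    TRUE ~ "kept"
  )
}

#' Filter low-quality cells
#'
#' Removes cells whose detected-gene count falls outside
#' `[min_genes_per_cell, max_genes_per_cell]` or whose mitochondrial
#' fraction exceeds `max_mito_fraction`. Cell order is preserved and
#' retained counts are untouched.
#'
#' @param x A `wmc_counts`.
#' @param metrics Optional precomputed [compute_qc_metrics()] tibble.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `wmc_counts`, with attribute `"removal_log"`: a
#'   tibble (`barcode`, `count_depth`, `n_genes`, `mito_fraction`, `kept`,
#'   `reason`) covering every input cell.
#' @export
filter_cells <- function(x, metrics = compute_qc_metrics(x),
                         thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "wmc_counts"), inherits(thresholds, "wmc_qc_thresholds"))
  if (!identical(metrics$barcode, x$barcodes)) {
    stop("metrics do not match the matrix barcodes")
  }
  reason <- .cell_filter_reason(metrics, thresholds)
  keep <- reason == "kept"
  if (!any(keep)) stop("empty result: all ", length(keep), " cells removed by QC")
  log <- dplyr::mutate(metrics, kept = keep, reason = reason)
  out <- raw_count_matrix(x$counts[, keep, drop = FALSE],
                          x$gene_ids, x$barcodes[keep],
                          mito_genes = x$gene_ids[x$mito_mask])
  attr(out, "removal_log") <- log
  out
}

#' Filter rarely detected genes
#'
#' Removes genes detected (count > 0) in fewer than `min_cells_per_gene`
#' cells; genes detected in exactly the threshold number of cells are
#' retained. Gene order is preserved.
#'
#' @inheritParams filter_cells
#' @return The filtered `wmc_counts`, with attribute `"gene_removal_log"`:
#'   a tibble (`gene`, `n_cells_detected`, `kept`).
#' @export
filter_genes <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "wmc_counts"), inherits(thresholds, "wmc_qc_thresholds"))
  detected <- Matrix::rowSums(x$counts > 0)
  keep <- detected >= thresholds$min_cells_per_gene
  if (!any(keep)) stop("empty result: all genes removed by QC")
  out <- raw_count_matrix(x$counts[keep, , drop = FALSE],
                          x$gene_ids[keep], x$barcodes,
                          mito_genes = x$gene_ids[x$mito_mask])
  attr(out, "gene_removal_log") <- tibble::tibble(
    gene = x$gene_ids, n_cells_detected = as.integer(detected), kept = keep)
  out
}

#' Log-normalize a quality-controlled count matrix
#'
#' Library-size method (default): each cell's counts are scaled to a common
#' total (`scale_factor`, default 10,000) and transformed as
#' \eqn{\ln(1 + \mathrm{scale} \cdot x_{gc} / \mathrm{depth}_c)}.
#' Plain method: \eqn{\ln(1 + x_{gc})} without depth scaling. Zeros stay
#' zero under both.
#'
#' @param x A `wmc_counts` (after QC; no zero-depth cells for the
#'   library-size method).
#' @param scale_factor Target per-cell total for the library-size method.
#' @param method `"library-size"` or `"plain-log1p"`.
#' @return A dense base matrix (genes x cells) of normalized expression,
#'   with dimnames carried over.
#' @export
log_normalize <- function(x, scale_factor = 1e4,
                          method = c("library-size", "plain-log1p")) {
  stopifnot(inherits(x, "wmc_counts"))
  method <- match.arg(method)
  m <- x$counts
  if (method == "library-size") {
    depth <- Matrix::colSums(m)
    if (any(depth == 0)) {
      stop("zero-depth cell(s) present (e.g. barcode '",
           x$barcodes[which(depth == 0)[1]],
           "'); run QC filters before log_normalize()")
    }
    m <- m %*% Matrix::Diagonal(ncol(m), scale_factor / depth)
  }
  out <- as.matrix(log1p(m))
  dimnames(out) <- list(x$gene_ids, x$barcodes)
  out
}
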