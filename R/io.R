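## Readers and writers for gene x cell count matrices: 10x Genomics MTX
## triplet directories and dense CSV/TSV. Matrices are kept sparse
## (Matrix::dgCMatrix) wherever possible.

#' Construct a raw count matrix container
#'
#' Bundles a gene x cell count matrix with its gene identifiers, cell
#' barcodes and a mitochondrial-gene mask, and validates the invariants:
#' nonnegative integer entries, unique identifiers matching the matrix
#' dimensions.
#'
#' @param counts Gene x cell matrix of nonnegative integers (dense or sparse).
#' @param gene_ids Character vector of gene identifiers (rows).
#' @param barcodes Character vector of cell barcodes (columns).
#' @param mito_pattern Regular expression identifying mitochondrial gene
#'   symbols (default the conventional `MT-`/`mt-` prefix).
#' @param mito_genes Optional explicit character vector of mitochondrial gene
#'   ids, overriding the pattern.
#' @return A `wmc_counts` object.
#' @export
raw_count_matrix <- function(counts, gene_ids = rownames(counts),
                             barcodes = colnames(counts),
                             mito_pattern = "^(MT|mt)-",
                             mito_genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids) || is.null(barcodes)) {
    stop("gene_ids and barcodes are required")
  }
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts)) {
    stop("parse error: ", length(gene_ids), " gene ids for ",
         nrow(counts), " matrix rows")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("parse error: ", length(barcodes), " barcodes for ",
         ncol(counts), " matrix columns")
  }
  if (anyDuplicated(gene_ids)) stop("gene ids are not unique")
  if (anyDuplicated(barcodes)) stop("cell barcodes are not unique")
  v <- counts@x
  if (length(v)) {
    if (any(v < 0)) {
      k <- which(v < 0)[1]                       # dgCMatrix slot coordinates
      bad_row <- counts@i[k] + 1L
      bad_col <- findInterval(k - 0.5, counts@p)
      stop("parse error: negative count at gene '", gene_ids[bad_row],
           "', barcode '", barcodes[bad_col], "'")
    }
    if (any(v != round(v))) stop("parse error: non-integer count entries")
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  mito_mask <- if (!is.null(mito_genes)) gene_ids %in% mito_genes
               else grepl(mito_pattern, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
                 mito_mask = mito_mask),
            class = "wmc_counts")
}

#' @export
print.wmc_counts <- function(x, ...) {
  cat(sprintf("<wmc_counts> %d genes x %d cells (%d mitochondrial genes, %.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_mask),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.wmc_counts <- function(x) dim(x$counts)

.read_tsv_col <- function(path, col = 1) {
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  dat[[min(col, ncol(dat))]]
}

.find_10x_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("parse error: none of ", paste(stems, collapse = "/"),
       " found in ", dir)
}

#' Read a count matrix from disk
#'
#' Reads a 10x Genomics triplet directory (`matrix.mtx(.gz)`,
#' `features.tsv(.gz)` or `genes.tsv(.gz)`, `barcodes.tsv(.gz)`) or a dense
#' CSV/TSV with genes in rows and cells in columns (first column = gene ids,
#' header = barcodes).
#'
#' @param path Directory (10x) or file (csv/tsv).
#' @param format One of `"10x-mtx"`, `"csv"`, `"tsv"`.
#' @param ... Passed to [raw_count_matrix()] (e.g. `mito_pattern`).
#' @return A `wmc_counts` object.
#' @export
read_counts <- function(path, format = c("10x-mtx", "csv", "tsv"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "10x-mtx") {
    if (!dir.exists(path)) stop("10x-mtx format expects a directory: ", path)
    m <- Matrix::readMM(.find_10x_file(path, "matrix.mtx"))
    genes_file <- .find_10x_file(path, c("features.tsv", "genes.tsv"))
    feats <- .read_tsv_col(genes_file, col = 2)
    ids <- .read_tsv_col(genes_file, col = 1)
    gene_ids <- if (anyDuplicated(feats)) ids else feats
    barcodes <- .read_tsv_col(.find_10x_file(path, "barcodes.tsv"))
    if (length(gene_ids) != nrow(m)) {
      stop("parse error: features file lists ", length(gene_ids),
           " genes but matrix.mtx has ", nrow(m), " rows")
    }
    if (length(barcodes) != ncol(m)) {
      stop("parse error: barcodes file lists ", length(barcodes),
           " cells but matrix.mtx has ", ncol(m), " columns")
    }
    raw_count_matrix(m, gene_ids, barcodes, ...)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dat <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
    raw_count_matrix(as.matrix(dat), rownames(dat), colnames(dat), ...)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: writes a 10x-style MTX triplet directory or a
#' dense CSV/TSV.
#'
#' @param x A `wmc_counts`.
#' @param path Output directory (10x) or file (csv/tsv).
#' @param format One of `"10x-mtx"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("10x-mtx", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "wmc_counts"))
  if (format == "10x-mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = x$gene_ids, symbol = x$gene_ids, type = "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t",
      col.names = FALSE, row.names = FALSE, quote = FALSE)
    writeLines(x$barcodes, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    dense <- as.matrix(x$counts)
    utils::write.table(data.frame(gene = x$gene_ids, dense,
                                  check.names = FALSE),
                       path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export wavelet coefficients or components to disk
#'
#' Writes each block (approximation and details) as dense CSV or sparse MTX
#' plus a sidecar JSON manifest recording M, family, k, padding and block
#' labels.
#'
#' @param C A `wmc_coefs` (from [forward_dwt()]) or a `wmc_views`.
#' @param dir Output directory.
#' @param format `"csv"` or `"mtx"`.
#' @param what For a `wmc_views`: `"coef"` or `"recon"` matrices.
#' @return `dir`, invisibly.
#' @export
export_components <- function(C, dir, format = c("csv", "mtx"),
                              what = c("coef", "recon")) {
  format <- match.arg(format)
  what <- match.arg(what)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(C, "wmc_views")) {
    blocks <- lapply(C$views, `[[`, what)
    meta <- list(M = C$M, family = C$family, padding = C$padding,
                 blocks = names(blocks))
  } else if (inherits(C, "wmc_coefs")) {
    blocks <- c(list(approx = C$a), C$details)
    meta <- list(k = nrow(C$a), source_n = C$source_n,
                 source_p = C$source_p, padding = C$padding,
                 blocks = names(blocks))
  } else stop("expected a wmc_coefs or wmc_views object")
  for (lab in names(blocks)) {
    m <- blocks[[lab]]
    if (format == "csv") {
      utils::write.csv(as.data.frame(m),
                       file.path(dir, paste0(lab, ".csv")), row.names = TRUE)
    } else {
      Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                      file.path(dir, paste0(lab, ".mtx")))
    }
  }
  jsonlite::write_json(meta, file.path(dir, "components.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
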