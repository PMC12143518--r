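## The single-level M-band DWT as an explicit orthogonal n x n matrix W.
##
## Rows are grouped approximation-first: rows 1..k hold M-shifted circulant
## copies of the scaling filter h_0, rows (j k + 1)..((j+1) k) copies of the
## wavelet filter h_j. Periodic (circular) boundary wrap keeps W exactly
## orthogonal for every n divisible by M. For a gene x cell matrix S with
## columns s_i, the transform W s_i stacks the approximation coefficients
## a(i) over the detail coefficients d_1(i) .. d_{M-1}(i), and W^T recovers
## s_i; zeroing all blocks but one before applying W^T gives the orthogonal
## projection of s_i onto the corresponding subspace.

#' Build the M-band DWT matrix for signal length n
#'
#' Assembles the orthogonal \eqn{n \times n} transform matrix whose row blocks
#' are M-shifted, periodically wrapped copies of each tap sequence of the
#' filter bank. Rows are ordered approximation block first, then detail
#' blocks 1..M-1, matching the coefficient layout used throughout.
#'
#' @param fb A `wmc_filter_bank` from [build_filter_bank()].
#' @param n Signal length (number of genes); must be divisible by `fb$M` and
#'   at least the tap length.
#' @return A `wmc_dwt` object: list with `W` (n x n matrix), `M`, `k = n/M`,
#'   `n`, `block_index` (named list of row-index vectors labelled `approx`,
#'   `detail-1`, ...), and the filter bank.
#' @examples
#' W <- build_dwt_matrix(build_filter_bank(2, "haar"), 4)
#' max(abs(W$W %*% t(W$W) - diag(4))) # ~ 0
#' @export
build_dwt_matrix <- function(fb, n) {
  stopifnot(inherits(fb, "wmc_filter_bank"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  M <- fb$M
  if (n %% M != 0) {
    stop("block-size error: n = ", n, " is not divisible by M = ", M,
         "; pad the gene axis first (see pad_genes())")
  }
  if (n < fb$L) {
    stop("n = ", n, " is shorter than the filter length L = ", fb$L)
  }
  k <- n %/% M
  W <- matrix(0, n, n)
  for (b in seq_len(M)) {
    h <- fb$taps[[b]]
    for (r in seq_len(k)) {
      # circulant placement: tap t lands at column (M (r-1) + t) mod n
      cols <- ((M * (r - 1) + seq_len(fb$L) - 1) %% n) + 1
      row <- (b - 1) * k + r
      for (t in seq_along(h)) W[row, cols[t]] <- W[row, cols[t]] + h[t]
    }
  }
  labels <- c("approx", if (M > 1) paste0("detail-", seq_len(M - 1)))
  block_index <- setNames(
    lapply(seq_len(M), function(b) ((b - 1) * k + 1):(b * k)), labels)
  structure(list(W = W, M = M, k = k, n = n,
                 block_index = block_index, filter_bank = fb),
            class = "wmc_dwt")
}

#' @export
print.wmc_dwt <- function(x, ...) {
  cat(sprintf("<wmc_dwt> %d x %d, M = %d (k = %d), family = '%s'\n",
              x$n, x$n, x$M, x$k, x$filter_bank$family))
  invisible(x)
}

#' Pad the gene axis to a multiple of M
#'
#' Appends the minimal number of all-zero rows so the row count is divisible
#' by the band count. Idempotent when already divisible. The returned padding
#' record lets reconstructions be stripped back to the original genes.
#'
#' @param S A gene x cell matrix (base or `Matrix` sparse).
#' @param M Band count.
#' @return List with `S` (padded matrix) and `padding` (number of zero rows
#'   appended at the bottom).
#' @export
pad_genes <- function(S, M) {
  if (is.null(dim(S)) || nrow(S) < 1 || ncol(S) < 1) {
    stop("cannot pad an empty matrix")
  }
  pad <- (M - nrow(S) %% M) %% M
  if (pad > 0) {
    zero <- matrix(0, pad, ncol(S))
    rownames(zero) <- if (!is.null(rownames(S))) paste0("__pad", seq_len(pad))
    S <- rbind(S, zero)
  }
  list(S = S, padding = as.integer(pad))
}

#' Forward M-band DWT of a gene x cell matrix
#'
#' Applies the orthogonal transform column-wise: each cell's expression
#' profile \eqn{s_i \in R^n} becomes \eqn{W s_i}, split into the
#' approximation coefficients and the M-1 detail coefficient blocks. The
#' transform is an isometry, so per-cell energy
#' \eqn{\|a(i)\|^2 + \sum_j \|d_j(i)\|^2 = \|s_i\|^2}.
#'
#' @param W A `wmc_dwt`.
#' @param S A numeric matrix with `nrow(S) == W$n` (genes x cells).
#' @return A `wmc_coefs` object: list with `a` (k x p approximation),
#'   `details` (list of M-1 k x p matrices), `source_n`, `source_p`,
#'   `padding` (0 here; set by [decompose_views()] when it pads).
#' @export
forward_dwt <- function(W, S) {
  stopifnot(inherits(W, "wmc_dwt"))
  S <- as.matrix(S)
  if (nrow(S) != W$n) {
    stop("shape error: S has ", nrow(S), " rows but the transform expects ", W$n)
  }
  St <- W$W %*% S
  blocks <- lapply(W$block_index, function(idx) St[idx, , drop = FALSE])
  structure(list(a = blocks[[1]],
                 details = blocks[-1],
                 source_n = nrow(S), source_p = ncol(S),
                 padding = 0L),
            class = "wmc_coefs")
}

.stack_coefs <- function(C) {
  do.call(rbind, c(list(C$a), unname(C$details)))
}

#' Inverse M-band DWT
#'
#' Applies \eqn{W^T} to the stacked coefficient matrix, recovering the
#' original gene x cell matrix exactly (orthogonality makes the round trip
#' an identity up to floating point).
#'
#' @param W A `wmc_dwt`.
#' @param C A `wmc_coefs` with dimensions consistent with `W`.
#' @return The reconstructed n x p matrix.
#' @export
inverse_dwt <- function(W, C) {
  stopifnot(inherits(W, "wmc_dwt"), inherits(C, "wmc_coefs"))
  St <- .stack_coefs(C)
  if (nrow(St) != W$n) {
    stop("shape error: coefficients have ", nrow(St),
         " rows but the transform expects ", W$n)
  }
  t(W$W) %*% St
}

#' Reconstruct one orthogonal component in gene space
#'
#' Projects the data onto a single wavelet subspace: the approximation
#' component \eqn{A = [w_1 .. w_k] a} or a detail component
#' \eqn{D_j}. Components are mutually orthogonal and sum to the original
#' matrix.
#'
#' @param W A `wmc_dwt`.
#' @param C A `wmc_coefs`.
#' @param which Block label: `"approx"` or `"detail-j"`.
#' @return The n x p component matrix.
#' @export
reconstruct_component <- function(W, C, which = "approx") {
  stopifnot(inherits(W, "wmc_dwt"), inherits(C, "wmc_coefs"))
  if (!which %in% names(W$block_index)) {
    stop("unknown block label '", which, "' (expected one of: ",
         paste(names(W$block_index), collapse = ", "), ")")
  }
  idx <- W$block_index[[which]]
  coef <- if (which == "approx") C$a else C$details[[which]]
  if (is.null(coef)) stop("coefficients are missing block '", which, "'")
  basis <- t(W$W[idx, , drop = FALSE])      # n x k, orthonormal columns
  basis %*% coef
}
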