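## Partition-agreement statistics between two clusterings of the same cells:
## the adjusted Rand index (pair-counting, chance-corrected) and normalized
## mutual information (geometric-mean entropy normalization), both evaluated
## exactly from the contingency table n_ij.

.labels_of <- function(x) {
  if (inherits(x, "wmc_clusters")) x$labels else as.vector(x)
}

.contingency <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors differ in length (", length(a), " vs ", length(b), ")")
  }
  table(a, b)
}

## identical partitions up to relabeling: contingency is a permutation-like
## matrix (one nonzero per row and per column)
.same_partition <- function(n) {
  all(rowSums(n > 0) == 1) && all(colSums(n > 0) == 1)
}

#' Adjusted Rand index
#'
#' Exact pair-counting ARI from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{n_{i+}}{2} + \sum_j\binom{n_{+j}}{2}) - E}}
#' with \eqn{E = \sum_i\binom{n_{i+}}{2}\sum_j\binom{n_{+j}}{2}/\binom{N}{2}}.
#' Values lie in \eqn{[-1, 1]}; 1 means identical partitions. In the
#' degenerate case where the denominator is 0 (e.g. both partitions
#' all-singletons or both one-cluster), identical partitions return 1 and
#' anything else is an error.
#'
#' @param a,b Label vectors or `wmc_clusters` over the same cells, in the
#'   same order.
#' @return A single number in \eqn{[-1, 1]}.
#' @export
ari <- function(a, b) {
  a <- .labels_of(a); b <- .labels_of(b)
  n <- .contingency(a, b)
  N <- sum(n)
  sij <- sum(choose(n, 2))
  si <- sum(choose(rowSums(n), 2))
  sj <- sum(choose(colSums(n), 2))
  expected <- si * sj / choose(N, 2)
  denom <- (si + sj) / 2 - expected
  if (abs(denom) < .Machine$double.eps * max(1, si + sj)) {
    if (.same_partition(n)) return(1)
    stop("ARI undefined: degenerate partitions with zero-variance contingency")
  }
  (sij - expected) / denom
}

#' Normalized mutual information
#'
#' Mutual information of the joint label distribution normalized by the
#' geometric mean of the two marginal label entropies:
#' \deqn{NMI = \frac{\sum_{ij} \frac{n_{ij}}{N}\log\frac{n_{ij} N}{n_{i+} n_{+j}}}{\sqrt{H(A)\,H(B)}}}
#' Values lie in \eqn{[0, 1]}; 1 means identical partitions. If either
#' partition has a single cluster (zero entropy) the normalization is
#' undefined: identical single-cluster partitions return 1, anything else
#' is an error.
#'
#' @inheritParams ari
#' @return A single number in \eqn{[0, 1]}.
#' @export
nmi <- function(a, b) {
  a <- .labels_of(a); b <- .labels_of(b)
  n <- .contingency(a, b)
  N <- sum(n)
  pi <- rowSums(n) / N
  pj <- colSums(n) / N
  ha <- -sum(pi * log(pi))
  hb <- -sum(pj * log(pj))
  if (ha < .Machine$double.eps || hb < .Machine$double.eps) {
    if (.same_partition(n)) return(1)
    stop("NMI undefined: a partition with a single cluster has zero entropy")
  }
  pij <- n / N
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  max(0, min(1, mi / sqrt(ha * hb)))
}

#' Pairwise ARI/NMI concordance across views
#'
#' Computes ARI and NMI for every pair of views' cluster assignments,
#' optionally averaged over replicate results (e.g. reruns with different
#' seeds). Pairs where a metric is undefined are reported as `NA` rather
#' than aborting.
#'
#' @param results A `wmc_result`, or a list of `wmc_result` replicates with
#'   identical views.
#' @param include_original Include pairs involving the untransformed
#'   original view (default `FALSE`, giving the component-only grid:
#'   low vs high for 2-band, six pairs for 4-band).
#' @return A `wmc_concordance` tibble: `bands`, `view_a`, `view_b`,
#'   `components` (e.g. `"low vs h1"`), `ari`, `nmi`, `n_replicates`.
#' @export
pairwise_concordance <- function(results, include_original = FALSE) {
  if (inherits(results, "wmc_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "wmc_result")))
  labs <- names(results[[1]]$clusters)
  if (!include_original) labs <- setdiff(labs, "original")
  if (length(labs) < 2) stop("need at least 2 clustered views to compare")
  M <- results[[1]]$views$M
  short <- function(v) {
    dplyr::case_when(v == "original" ~ "orig",
                     v == "approx" ~ "low",
                     v == "detail-1" & M == 2 ~ "high",  # Table-style 2-band
                     TRUE ~ sub("detail-", "h", v))
  }
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(e) {
    va <- pairs[1, e]; vb <- pairs[2, e]
    vals <- vapply(results, function(res) {
      c(tryCatch(ari(res$clusters[[va]], res$clusters[[vb]]),
                 error = function(e) NA_real_),
        tryCatch(nmi(res$clusters[[va]], res$clusters[[vb]]),
                 error = function(e) NA_real_))
    }, c(ari = 0, nmi = 0))
    tibble::tibble(bands = results[[1]]$views$M,
                   view_a = va, view_b = vb,
                   components = paste(short(va), "vs", short(vb)),
                   ari = mean(vals["ari", ], na.rm = TRUE),
                   nmi = mean(vals["nmi", ], na.rm = TRUE),
                   n_replicates = length(results))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wmc_concordance", class(out))
  out
}
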