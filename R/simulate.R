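## Seed-reproducible negative-binomial (gamma-Poisson) count simulator with
## planted multi-scale structure. It emulates the minimal statistics the
## multi-view pipeline assumes: sparse nonnegative counts, cluster-separated
## marker means, mitochondrial genes, and a fraction of low-quality cells
## that violate the QC thresholds.
##
## Marker layout exploits the gene-order locality of the wavelet transform:
## - major-cluster markers come in adjacent gene PAIRS with BOTH genes
##   elevated, so the pair sum (approximation channel at M = 2) carries the
##   major signal and the pair difference (detail channel) cancels;
## - sub-cluster structure is a cross-cutting cell STATE (think cell-cycle
##   phase or activation state) that splits every major cluster the same
##   way: each state owns adjacent marker pairs, shared across majors, with
##   an alternating +/- pattern (cells in the state elevate the first gene
##   of the pair, all other cells the second). The pair sum is then the
##   same for every cell, so the state is invisible to the approximation
##   channel and largely swamped by major-cluster variance in the original
##   matrix, while the pair difference isolates it in the detail channel.
## - every adjacent gene pair additionally shares a per-cell log-normal
##   "module" fluctuation (correlated local covariation of neighboring,
##   co-regulated genes); pair-differencing cancels it, pair-summing keeps
##   it, mimicking the structured overdispersion of real counts.
## Under a 2-band transform the major structure therefore concentrates in
## the approximation view and the sub-cluster (state) contrast in the
## detail view.

#' Simulation configuration
#'
#' Defaults define the package's reference simulation: 4 major clusters,
#' each split in 2 by a cross-cutting state (sub-clusters), 100 cells per
#' (major, state) group (800 cells), 1200 genes, NB(mean 0.5, dispersion 2)
#' baseline, log2 fold change 2 on markers, pair-correlated module noise
#' (sd 0.4), 2% mitochondrial genes, and 5% planted low-quality cells.
#'
#' @param n_genes Total genes.
#' @param n_major Major clusters (>= 2).
#' @param subclusters_per_major Sub-clusters per major cluster.
#' @param cells_per_subcluster Cells per (major, sub) group.
#' @param base_mean Baseline NB mean per gene per cell.
#' @param dispersion NB dispersion (`size`; variance = mu + mu^2/size).
#' @param lfc Marker log2 fold change.
#' @param major_marker_pairs Adjacent gene pairs per major cluster with both
#'   genes elevated.
#' @param sub_marker_pairs Adjacent gene pairs per sub-cluster state
#'   (shared across majors) with the alternating +/- pattern.
#' @param module_noise_sd Standard deviation of the per-cell log-normal
#'   fluctuation shared by each adjacent gene pair (correlated module
#'   noise; 0 disables).
#' @param mito_gene_fraction Fraction of genes designated mitochondrial
#'   (`MT-` symbols).
#' @param low_quality_cell_fraction Fraction of cells forced to violate QC
#'   (alternating: < 200 detected genes / > 5% mitochondrial counts).
#' @param seed Integer seed; the simulation is fully determined by it.
#' @return A `wmc_sim_config` list.
#' @export
sim_config <- function(n_genes = 1200, n_major = 4, subclusters_per_major = 2,
                       cells_per_subcluster = 100,
                       base_mean = 0.5, dispersion = 2, lfc = 2.0,
                       major_marker_pairs = 12, sub_marker_pairs = 8,
                       module_noise_sd = 0.4,
                       mito_gene_fraction = 0.02,
                       low_quality_cell_fraction = 0.05,
                       seed = 0) {
  stopifnot(n_major >= 2, subclusters_per_major >= 1,
            cells_per_subcluster >= 1, base_mean > 0, dispersion > 0,
            module_noise_sd >= 0,
            mito_gene_fraction >= 0, mito_gene_fraction < 1,
            low_quality_cell_fraction >= 0, low_quality_cell_fraction < 1)
  cfg <- structure(list(n_genes = n_genes, n_major = n_major,
                        subclusters_per_major = subclusters_per_major,
                        cells_per_subcluster = cells_per_subcluster,
                        base_mean = base_mean, dispersion = dispersion,
                        lfc = lfc,
                        major_marker_pairs = major_marker_pairs,
                        sub_marker_pairs = sub_marker_pairs,
                        module_noise_sd = module_noise_sd,
                        mito_gene_fraction = mito_gene_fraction,
                        low_quality_cell_fraction = low_quality_cell_fraction,
                        seed = as.integer(seed)),
                   class = "wmc_sim_config")
  needed <- 2 * n_major * major_marker_pairs +
    2 * subclusters_per_major * sub_marker_pairs +
    ceiling(mito_gene_fraction * n_genes)
  if (needed > n_genes) {
    stop("infeasible config: marker + mitochondrial genes (", needed,
         ") exceed n_genes (", n_genes, ")")
  }
  cfg
}

## deterministically thin a count vector until its total is <= cap
.thin_to <- function(counts, cap) {
  while (sum(counts) > cap) {
    i <- which.max(counts)
    counts[i] <- counts[i] - min(counts[i], sum(counts) - cap)
  }
  counts
}

#' Simulate a count matrix with planted multi-scale clusters
#'
#' Draws a gene x cell nonnegative integer count matrix from a negative
#' binomial model with cluster-specific marker elevation (see the layout
#' described in [sim_config()]), plants QC-violating low-quality cells, and
#' returns the full ground truth. Fully determined by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (a `wmc_counts`) and `truth`: list with
#'   `cells` (tibble: `barcode`, `major`, `sub`, `sub_label`,
#'   `qc_violation`), `genes` (tibble: `gene`, `role`, `major`, `sub`,
#'   `pair`, `member`), and `config`.
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "wmc_sim_config"))
  set.seed(cfg$seed)
  n_sub <- cfg$subclusters_per_major
  n_cells <- cfg$n_major * n_sub * cfg$cells_per_subcluster
  major <- rep(seq_len(cfg$n_major), each = n_sub * cfg$cells_per_subcluster)
  sub <- rep(rep(seq_len(n_sub), each = cfg$cells_per_subcluster),
             times = cfg$n_major)
  barcodes <- sprintf("cell%05d", seq_len(n_cells))

  ## --- gene layout ------------------------------------------------------
  n_mito <- ceiling(cfg$mito_gene_fraction * cfg$n_genes)
  genes <- tibble::tibble(gene = sprintf("G%05d", seq_len(cfg$n_genes)),
                          role = "baseline",
                          major = NA_integer_, sub = NA_integer_,
                          pair = NA_integer_, member = NA_integer_)
  pos <- 1L
  pair_id <- 0L
  take_pair <- function() {
    p <- c(pos, pos + 1L); pos <<- pos + 2L; pair_id <<- pair_id + 1L
    list(idx = p, id = pair_id)
  }
  major_pairs <- vector("list", cfg$n_major)
  for (m in seq_len(cfg$n_major)) {
    prs <- lapply(seq_len(cfg$major_marker_pairs), function(i) take_pair())
    major_pairs[[m]] <- prs
    for (pr in prs) {
      genes$role[pr$idx] <- "major_marker"
      genes$major[pr$idx] <- m
      genes$pair[pr$idx] <- pr$id
      genes$member[pr$idx] <- 1:2
    }
  }
  sub_pairs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    prs <- lapply(seq_len(cfg$sub_marker_pairs), function(i) take_pair())
    sub_pairs[[s]] <- prs
    for (pr in prs) {
      genes$role[pr$idx] <- "sub_marker"
      genes$sub[pr$idx] <- s
      genes$pair[pr$idx] <- pr$id
      genes$member[pr$idx] <- 1:2
    }
  }
  if (n_mito > 0) {
    mito_idx <- pos:(pos + n_mito - 1L)
    genes$role[mito_idx] <- "mito"
    genes$gene[mito_idx] <- sprintf("MT-%03d", seq_len(n_mito))
    pos <- pos + n_mito
  } else mito_idx <- integer()

  ## --- mean model -------------------------------------------------------
  up <- 2^cfg$lfc
  mu <- matrix(cfg$base_mean, cfg$n_genes, n_cells)
  for (m in seq_len(cfg$n_major)) {
    cells_m <- which(major == m)
    for (pr in major_pairs[[m]]) mu[pr$idx, cells_m] <- cfg$base_mean * up
  }
  ## cross-cutting state: cells in state s elevate the first gene of every
  ## state-s pair, all other cells the second gene, so pair sums are flat
  for (s in seq_len(n_sub)) {
    in_state <- which(sub == s)
    other <- which(sub != s)
    for (pr in sub_pairs[[s]]) {
      mu[pr$idx[1], in_state] <- cfg$base_mean * up
      if (length(other)) mu[pr$idx[2], other] <- cfg$base_mean * up
    }
  }
  ## per-cell module fluctuation shared by each adjacent gene pair
  if (cfg$module_noise_sd > 0) {
    n_blocks <- ceiling(cfg$n_genes / 2)
    eta <- matrix(stats::rnorm(n_blocks * n_cells, 0, cfg$module_noise_sd),
                  n_blocks, n_cells)
    mu <- mu * exp(eta[rep(seq_len(n_blocks), each = 2)[seq_len(cfg$n_genes)], ,
                       drop = FALSE])
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                   cfg$n_genes, n_cells)

  ## --- planted QC violations -------------------------------------------
  n_lq <- round(cfg$low_quality_cell_fraction * n_cells)
  lq_cells <- if (n_lq > 0) sort(sample.int(n_cells, n_lq)) else integer()
  violation <- rep("none", n_cells)
  for (i in seq_along(lq_cells)) {
    j <- lq_cells[i]
    if (i %% 2 == 1 || length(mito_idx) == 0) {
      ## low-gene cell: expression restricted to 150 random genes
      keep <- sample.int(cfg$n_genes, 150)
      counts[-keep, j] <- 0L
      violation[j] <- "low_genes"
    } else {
      ## high-mito cell: mitochondrial load forced to 20% of the library
      rest <- sum(counts[-mito_idx, j])
      target <- max(ceiling(rest * 0.25), 1)
      counts[mito_idx, j] <- as.integer(
        rmultinom(1, target, rep(1, length(mito_idx))))
      violation[j] <- "high_mito"
    }
  }
  ## cap mitochondrial load of normal cells safely below the 5% threshold
  if (length(mito_idx) > 0) {
    for (j in setdiff(seq_len(n_cells), lq_cells)) {
      rest <- sum(counts[-mito_idx, j])
      cap <- floor(rest * 0.04 / 0.96)
      if (sum(counts[mito_idx, j]) > cap) {
        counts[mito_idx, j] <- .thin_to(counts[mito_idx, j], cap)
      }
    }
  }

  x <- raw_count_matrix(counts, genes$gene, barcodes)
  truth <- list(cells = tibble::tibble(
                  barcode = barcodes, major = major, sub = sub,
                  sub_label = sprintf("s%d", sub),
                  qc_violation = violation),
                genes = genes, config = cfg)
  list(counts = x, truth = truth)
}

#' Recovery of planted labels by a multi-view result
#'
#' Compares every view's cluster assignment against the planted major and
#' sub-cluster labels (restricted to the cells retained by QC) with ARI and
#' NMI.
#'
#' @param truth The `truth` element of [simulate_counts()].
#' @param result A `wmc_result` run on the simulated counts.
#' @return Tibble with columns `view`, `ari_major`, `nmi_major`, `ari_sub`,
#'   `nmi_sub`.
#' @export
evaluate_recovery <- function(truth, result) {
  stopifnot(inherits(result, "wmc_result"))
  idx <- match(result$barcodes, truth$cells$barcode)
  if (anyNA(idx)) {
    stop("misaligned barcodes: result contains cells absent from the truth")
  }
  major <- truth$cells$major[idx]
  sub <- truth$cells$sub_label[idx]
  safe <- function(f, a, b) tryCatch(f(a, b), error = function(e) NA_real_)
  dplyr::bind_rows(lapply(names(result$clusters), function(lab) {
    cl <- result$clusters[[lab]]$labels
    tibble::tibble(view = lab,
                   ari_major = safe(ari, cl, major),
                   nmi_major = safe(nmi, cl, major),
                   ari_sub = safe(ari, cl, sub),
                   nmi_sub = safe(nmi, cl, sub))
  }))
}
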