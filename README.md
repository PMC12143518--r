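# wmclust — M-band wavelet multi-view clustering of single cells

Standard scRNA-seq pipelines cluster one matrix once, at one resolution, and
routinely blend away sub-populations — rare subtypes, cell-cycle phases,
activation states — whose signal is weak relative to the dominant cell-type
structure. `wmclust` gives the same cells several orthogonal looks. It
decomposes a quality-controlled, log-normalized gene × cell matrix
`S ∈ ℝ^{n×p}` with an orthogonal M-band discrete wavelet transform along the
gene axis,

```
W S = [a, d_1, …, d_{M−1}]ᵀ,   S = A + D_1 + … + D_{M−1},
```

into one approximation component `A` (a smoothed, weighted-average-like view
of the matrix) and M−1 detail components `D_j` (band-pass fluctuation views),
all mutually orthogonal and summing exactly back to `S`. Each component —
plus the untransformed original — is embedded with PCA, turned into a
shared-nearest-neighbor graph, and clustered with Louvain community
detection, independently but with identical parameters and seed. The
resulting multi-view partitions are then assessed with:

* **pairwise ARI / NMI concordance** between views (exact contingency-table
  evaluation), and
* **marker-set intersection analysis**: per-view marker genes (Wilcoxon
  rank-sum + Benjamini–Hochberg) decomposed into exclusive UpSet-style cells
  `N_Λ` — the genes significant in exactly the views of each subset Λ.

The package is aimed at computational biologists who want to probe a dataset
for structure that whole-matrix clustering misses, with every stochastic
stage seed-reproducible. It includes a 10x MTX / CSV reader, the standard QC
filters (200–3000 detected genes per cell, ≤ 5% mitochondrial counts, genes
in ≥ 20 cells), a negative-binomial simulator with planted multi-scale
ground truth, and a small command-line front end.

## Worked example

Simulate the reference dataset — 4 major cell types, each split in two by a
cross-cutting state (e.g. a cell-cycle-like program) that is deliberately
hard to see in the whole matrix — then run the 2-band pipeline:

```r
library(wmclust)

sim <- simulate_counts(sim_config(seed = 0))
sim$counts
#> <wmc_counts> 1200 genes x 800 cells (24 mitochondrial genes, 37.1% nonzero)

res <- run_multiview(sim$counts,
                     multiview_config(M = 2, family = "haar", seed = 0))
glance(res)
#> # A tibble: 3 × 7
#>   view     n_clusters n_cells     M family resolution  seed
#> 1 original          5     760     2 db1             1     0
#> 2 approx            4     760     2 db1             1     0
#> 3 detail-1          3     760     2 db1             1     0

evaluate_recovery(sim$truth, res)
#> # A tibble: 3 × 5
#>   view     ari_major nmi_major  ari_sub  nmi_sub
#> 1 original   0.864     0.866    0.0518  0.124
#> 2 approx     0.962     0.939   -0.00174 0.000248
#> 3 detail-1  -0.00176   0.00320  0.956   0.910
```

Reading the recovery table: 40 of the 800 cells were planted QC violators
and removed (760 remain). The **approximation** view recovers the 4 major
cell types nearly perfectly (ARI 0.96) and is blind to the state (ARI ≈ 0);
the **detail** view is blind to the major types but resolves the hidden
state (ARI 0.96) that the **original** matrix clustering largely misses
(ARI 0.05) — the detail component surfaces a real partition that the
conventional single-view analysis does not. Concordance between views
(`pairwise_concordance(res, include_original = TRUE)`) quantifies the same
picture: orig-vs-low agree (ARI 0.85), while low-vs-high ARI ≈ 0 because
the two components carry orthogonal structure.

`tidy(res)` returns per-cell labels (barcode, view, cluster),
`marker_gene_sets(res)` + `intersection_analysis()` give the exclusive
marker decomposition, and `autoplot(res)` draws per-view UMAP panels (when
the pipeline is run with `umap = TRUE`, the default).

The same pipeline runs from a shell:

```sh
Rscript inst/cli/wmc.R simulate --seed 0 --outdir sim/
Rscript inst/cli/wmc.R run --input sim/counts --format 10x-mtx \
    --bands 2 --family haar --seed 0 --outdir out/
```

Every run writes a JSON manifest (inputs with checksums, all resolved
parameters, stage status); rerunning with the same flags reproduces the
label CSVs byte for byte.

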