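test_that("a perfectly separating gene is always called a marker", {
  X <- matrix(0, 20, 40)
  rownames(X) <- sprintf("g%d", 1:20)
  labels <- rep(c(1L, 2L), each = 20)
  X[7, labels == 1] <- 5
  mk <- find_markers(X, labels, alpha = 0.05, min_abs_effect = 0.25)
  expect_equal(mk$genes, "g7")
  # permutation of cells leaves the marker set unchanged
  perm <- sample(40)
  mk2 <- find_markers(X[, perm], labels[perm])
  expect_equal(mk2$genes, mk$genes)
})

test_that("the vectorized rank-sum test matches wilcox.test", {
  set.seed(13)
  X <- matrix(round(rnorm(30 * 40), 1), 30, 40)  # rounding induces ties
  grp <- rep(c(TRUE, FALSE), c(18, 22))
  p_fast <- wmclust:::.ranksum_rows(X, grp)
  p_ref <- apply(X, 1, function(r) {
    stats::wilcox.test(r[grp], r[!grp], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(p_fast, p_ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("under the null the raw-p marker rate matches the alpha level", {
  n_seeds <- 20
  n_genes <- 500
  hits <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    X <- matrix(rnorm(n_genes * 100), n_genes, 100)
    labels <- rep(c(1L, 2L), each = 50)
    mk <- find_markers(X, labels, alpha = 0.05, min_abs_effect = 0,
                       p_adjust = "none")
    hits <- hits + length(mk$genes)
  }
  trials <- n_seeds * n_genes
  expected <- 0.05 * trials
  band <- 2.576 * sqrt(trials * 0.05 * 0.95)
  expect_gt(hits, expected - band)
  expect_lt(hits, expected + band)
})

test_that("marker detection rejects degenerate clusterings", {
  X <- matrix(rnorm(100), 10, 10)
  expect_error(find_markers(X, rep(1L, 10)), "at least 2 clusters")
  expect_error(find_markers(X, rep(1L, 5)), "label vector length")
})

test_that("the worked 3-set intersection example evaluates exactly", {
  g <- list(original = c("a", "b", "c"),
            approx = c("b", "c", "d"),
            `detail-1` = c("c", "e"))
  rep <- intersection_analysis(g)
  tab <- tibble::as_tibble(rep)
  get <- function(mask) tab$genes[tab$mask == mask][[1]]
  expect_equal(get("010"), "d")          # approximation only
  expect_equal(get("111"), "c")          # all three views
  expect_equal(get("011"), character())  # approx + detail, not original
  expect_equal(get("100"), "a")
  expect_equal(sum(tab$size), 5L)
  expect_equal(attr(rep, "universe_size"), 5L)
  expect_equal(attr(rep, "leakage"), 0L)  # 011 and 001-with-|L|>=2 empty
})

test_that("exclusive cells partition the union on random collections", {
  set.seed(21)
  for (i in 1:200) {
    nv <- sample(2:5, 1)
    universe <- sprintf("g%02d", 1:30)
    sets <- lapply(seq_len(nv), function(j) {
      sample(universe, sample(0:20, 1))
    })
    rep <- intersection_analysis(sets)
    tab <- tibble::as_tibble(rep)
    expect_equal(sum(tab$size), length(unique(unlist(sets))))
    all_members <- unlist(tab$genes)
    expect_equal(anyDuplicated(all_members), 0L)
    # agreement with the per-gene scan oracle
    oracle <- oracle_exclusive_cells(sets)
    for (mask in names(oracle)) {
      expect_setequal(tab$genes[tab$mask == mask][[1]], oracle[[mask]])
    }
  }
})

test_that("identical sets occupy only the full-intersection cell", {
  s <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  tab <- tibble::as_tibble(intersection_analysis(s))
  expect_equal(tab$size[tab$mask == "111"], 2L)
  expect_equal(sum(tab$size), 2L)
})

test_that("ARI and NMI reproduce hand-derived values and invariances", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(ari(a, a), 1)
  expect_equal(nmi(a, a), 1)
  # label permutation invariance
  expect_equal(ari(a, c(7, 7, 5, 5, 1, 1)), 1)
  b <- c(1, 2, 2, 3, 3, 3)
  expect_equal(ari(a, b), ari(c(9, 9, 4, 4, 2, 2), b))
  expect_equal(nmi(a, b), nmi(b, a))
  expect_error(ari(c(1, 2), c(1, 2, 3)), "differ in length")
})

test_that("degenerate partitions follow the documented conventions", {
  expect_equal(ari(1:5, 1:5), 1)              # both all-singletons, identical
  expect_equal(ari(rep(1, 5), rep(2, 5)), 1)  # both single-cluster
  expect_equal(nmi(rep(1, 5), rep(1, 5)), 1)
  expect_error(nmi(rep(1, 5), c(1, 1, 1, 2, 2)), "zero entropy")
  # one single-cluster partition against a finer one: denominator nonzero,
  # agreement exactly at chance level
  expect_equal(ari(rep(1, 5), c(1, 1, 1, 2, 2)), 0)
})

test_that("ARI and NMI agree with brute-force oracles on random labelings", {
  set.seed(17)
  for (i in 1:50) {
    n <- 40
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise concordance reports the component grid", {
  mk <- function(labels, view) cluster_assignment(labels, view)
  labs <- list(
    original = mk(rep(1:4, 10), "original"),
    approx = mk(rep(1:4, 10), "approx"),
    `detail-1` = mk(rep(1:2, 20), "detail-1"),
    `detail-2` = mk(rep(1:2, each = 20), "detail-2"),
    `detail-3` = mk(sample(1:3, 40, replace = TRUE), "detail-3"))
  res4 <- structure(list(clusters = labs, views = list(M = 4L)),
                    class = "wmc_result")
  grid <- pairwise_concordance(res4)
  expect_equal(nrow(grid), 6L)  # choose(4, 2) among low/h1/h2/h3
  expect_setequal(grid$components,
                  c("low vs h1", "low vs h2", "low vs h3",
                    "h1 vs h2", "h1 vs h3", "h2 vs h3"))
  res2 <- structure(list(clusters = labs[c("original", "approx", "detail-1")],
                         views = list(M = 2L)),
                    class = "wmc_result")
  expect_equal(nrow(pairwise_concordance(res2)), 1L)
  expect_equal(nrow(pairwise_concordance(res2, include_original = TRUE)), 3L)
  # identical labels across views give perfect agreement
  same <- structure(list(clusters = list(approx = mk(rep(1:2, 10), "approx"),
                                         `detail-1` = mk(rep(1:2, 10), "detail-1")),
                         views = list(M = 2L)),
                    class = "wmc_result")
  g <- pairwise_concordance(same)
  expect_equal(g$ari, 1)
  expect_equal(g$nmi, 1)
})

test_that("marker sets from a pipeline run feed the intersection analysis", {
  sim <- simulate_counts(sim_config(n_genes = 400, cells_per_subcluster = 20,
                                    base_mean = 2, seed = 2))
  res <- run_multiview(sim$counts,
                       multiview_config(M = 2, family = "haar", umap = FALSE,
                                        k_neighbors = 10, n_pcs = 15, seed = 0))
  sets <- marker_gene_sets(res)
  expect_named(sets$sets, c("original", "approx", "detail-1"))
  rep <- intersection_analysis(sets)
  expect_equal(sum(tibble::as_tibble(rep)$size),
               length(unique(unlist(sets$sets))))
})
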