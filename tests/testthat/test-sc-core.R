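toy_qc_matrix <- function() {
  ## 6 genes x 5 cells; detected genes per cell: 1, 2, 4, 5, 3
  ## cell 5 has 60% mitochondrial counts
  counts <- rbind(
    `mt-Nd1` = c(5, 0, 1, 1, 6),
    geneA    = c(0, 3, 1, 1, 2),
    geneB    = c(0, 2, 1, 1, 2),
    geneC    = c(0, 0, 1, 1, 0),
    geneD    = c(0, 0, 0, 1, 0),
    geneE    = c(0, 0, 0, 0, 0)
  )
  colnames(counts) <- paste0("c", 1:5)
  count_matrix(counts)
}

test_that("qc_filter applies the hand-derived retention rules", {
  m <- toy_qc_matrix()
  expect_equal(m$cell_meta$n_genes_detected, c(1, 2, 4, 5, 3))
  expect_equal(m$cell_meta$pct_mito[5], 60)

  kept <- qc_filter(m, min_genes = 2, max_genes = 4, max_pct_mito = 50)
  expect_identical(colnames(kept$counts), c("c2", "c3"))

  ## permissive thresholds are the identity
  ident <- qc_filter(m, min_genes = 0, max_genes = Inf, max_pct_mito = 100)
  expect_identical(ident$counts, m$counts)

  ## idempotence
  twice <- qc_filter(qc_filter(m, 2, 4, 50), 2, 4, 50)
  expect_identical(twice$counts, kept$counts)

  ## boundaries are inclusive
  edge <- qc_filter(m, min_genes = 3, max_genes = 4, max_pct_mito = 60)
  expect_identical(colnames(edge$counts), c("c3", "c5"))

  expect_warning(empty <- qc_filter(m, 100, 200, 1), "no cell")
  expect_identical(ncol(empty$counts), 0L)
  expect_true(attr(empty, "empty_result"))
})

test_that("published QC presets are encoded", {
  p <- qc_preset("ontogeny")
  expect_equal(p[c("min_genes", "max_genes", "max_pct_mito", "dims", "resolution")],
               list(min_genes = 1000, max_genes = 4600, max_pct_mito = 4.5,
                    dims = 12, resolution = 1.1))
  expect_equal(qc_preset("gfspf")$max_pct_mito, 7)
  expect_equal(qc_preset("irf3")$dims, 30)
})

test_that("normalize_log matches the closed form and handles zero cells", {
  counts <- cbind(a = c(1, 1), b = c(0, 0), d = c(3, 1))
  rownames(counts) <- c("g1", "g2")
  expect_warning(x <- normalize_log(counts, scale = 2), "zero total")
  expect_equal(x[, "a"], c(g1 = log1p(1), g2 = log1p(1)))
  expect_equal(unname(x[, "b"]), c(0, 0))
  ## de-logged column sums return the scale factor for nonzero cells
  expect_equal(unname(colSums(expm1(x))[c("a", "d")]), c(2, 2))
})

test_that("select_hvg never picks constant genes and keeps planted markers", {
  set.seed(1)
  x <- matrix(rnorm(200 * 50, 0, 1), 200, 50,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  x[1:10, ] <- 5  # constant genes
  hv <- select_hvg(x, 50)
  expect_length(intersect(hv, sprintf("g%03d", 1:10)), 0)
  ## n = n_features returns everything
  expect_setequal(select_hvg(x, 200), rownames(x))

  sim <- make_sc_dataset(n_cells = 300, n_genes = 600, branch_sep = 2, seed = 4)
  hv2 <- select_hvg(normalize_log(sim$matrix), 300)
  markers <- unlist(sim$truth$signature_genes)
  expect_gt(mean(markers %in% hv2), 0.8)
})

test_that("cell-cycle scores are zero-centred under the null and seeded", {
  set.seed(2)
  counts <- matrix(rpois(300 * 80, 5), 300, 80,
                   dimnames = list(sprintf("g%03d", 1:300), NULL))
  m <- count_matrix(counts)
  s_genes <- sprintf("g%03d", 1:15)
  g2m_genes <- sprintf("g%03d", 16:30)
  sc <- score_cell_cycle(m, s_genes, g2m_genes, seed = 7)
  ## no planted program: population mean score ~ 0
  expect_lt(abs(mean(sc$s_score)), 0.05)
  expect_lt(abs(mean(sc$g2m_score)), 0.05)
  sc2 <- score_cell_cycle(m, s_genes, g2m_genes, seed = 7)
  expect_identical(sc, sc2)
  expect_error(score_cell_cycle(m, c("nope1", "nope2"), g2m_genes),
               "no phase gene")
})

test_that("covariate regression removes exactly the linear part", {
  set.seed(3)
  n <- 60
  cov1 <- rnorm(n)
  x <- rbind(lin = 2 * cov1 + 5,
             orth = rnorm(n),
             mix = cov1 + rnorm(n))
  res <- regress_covariates(x, data.frame(cov1 = cov1))
  expect_lt(max(abs(res["lin", ])), 1e-10)
  ## residuals of non-degenerate genes are uncorrelated with the covariate
  expect_lt(max(abs(cor(t(res[c("orth", "mix"), ]), cov1))), 1e-8)
  expect_warning(
    regress_covariates(x, data.frame(cov1 = cov1, dup = 2 * cov1)),
    "collinear")
  expect_error(regress_covariates(x, data.frame(bad = c(NA, rnorm(n - 1)))),
               "finite")
})

test_that("clustering separates Gaussian blobs and degenerates gracefully", {
  set.seed(4)
  blob <- function(center, n) {
    matrix(rnorm(n * 10, rep(center, each = n), 0.3), n, 10)
  }
  x <- t(rbind(blob(c(rep(0, 10)), 60), blob(c(rep(4, 10)), 60)))
  rownames(x) <- sprintf("g%02d", 1:10)
  colnames(x) <- sprintf("c%03d", 1:120)
  truth <- rep(0:1, each = 60)
  cl <- cluster_cells(x, dims = 3, resolution = 0.3, k_nn = 15, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1)
  expect_setequal(unique(cl$labels), c(0L, 1L))

  ## resolution -> 0 merges a connected cloud into one community
  one <- t(blob(rep(0, 10), 100))
  rownames(one) <- rownames(x); colnames(one) <- sprintf("c%03d", 1:100)
  cl0 <- cluster_cells(one, dims = 3, resolution = 1e-4, k_nn = 30, seed = 1)
  expect_identical(unique(cl0$labels), 0L)

  cl_a <- cluster_cells(x, dims = 3, resolution = 0.3, k_nn = 15, seed = 9)
  cl_b <- cluster_cells(x, dims = 3, resolution = 0.3, k_nn = 15, seed = 9)
  expect_identical(cl_a$labels, cl_b$labels)
})

test_that("Louvain clusters recover planted subsets (ARI >= 0.9)", {
  sim <- make_sc_dataset(n_cells = 2000, n_genes = 1000, branch_sep = 2,
                         seed = 7)
  x <- normalize_log(sim$matrix)
  xs <- t(scale(t(x[select_hvg(x, 500), ])))
  xs[!is.finite(xs)] <- 0
  cl <- cluster_cells(xs, dims = 12, resolution = 0.2, seed = 1)
  ari <- mclust::adjustedRandIndex(cl$labels, sim$matrix$cell_meta$subset)
  expect_gte(ari, 0.9)
})

test_that("endothelial gating drops clusters at or above the expression gate", {
  set.seed(5)
  counts <- matrix(rpois(50 * 40, 3), 50, 40,
                   dimnames = list(c("Pecam1", sprintf("g%02d", 2:50)),
                                   sprintf("c%02d", 1:40)))
  counts["Pecam1", 1:20] <- 0          # cluster 0: no expression
  counts["Pecam1", 21:40] <- 50        # cluster 1: high expression
  m <- count_matrix(counts)
  labels <- rep(0:1, each = 20)
  kept <- gate_non_endothelial(m, labels, "Pecam1", max_expr = 1)
  expect_identical(attr(kept, "kept_clusters"), 0L)
  expect_identical(ncol(kept$counts), 20L)

  ## boundary: a cluster whose mean equals the gate exactly is dropped
  gate_mean <- mean(normalize_log(m)["Pecam1", 1:20])
  kept2 <- suppressWarnings(
    gate_non_endothelial(m, labels, "Pecam1", max_expr = gate_mean))
  expect_false(0L %in% attr(kept2, "kept_clusters"))

  expect_error(gate_non_endothelial(m, labels, "NotAGene"), "not present")
})

test_that("per-cluster DEGs match exact rank-sum enumeration on a 3 vs 3 toy", {
  x <- rbind(g1 = c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0),
             g2 = c(4.0, 6.0, 5.0, 1.2, 2.3, 3.1))
  colnames(x) <- paste0("c", 1:6)
  labels <- rep(c(0, 1), each = 3)
  degs <- cluster_degs(x, labels, min_log2fc = 0, max_padj = 1)

  ## brute-force two-sided rank-sum p over all C(6,3) = 20 group assignments
  brute_p <- function(vals, grp) {
    w_obs <- sum(rank(vals)[grp == 0])
    combos <- combn(6, 3)
    ws <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu))
  }
  for (g in c("g1", "g2")) {
    got <- degs$p[degs$gene == g & degs$cluster == 0]
    expect_equal(got, brute_p(x[g, ], labels), tolerance = 1e-12)
  }

  ## identical distributions produce (almost) no DEGs
  set.seed(6)
  xn <- matrix(rnorm(200 * 60), 200, 60,
               dimnames = list(sprintf("g%03d", 1:200), NULL))
  null_degs <- cluster_degs(xn, rep(0:1, each = 30),
                            min_log2fc = 0, max_padj = 0.05)
  expect_lt(nrow(null_degs) / (2 * 200), 0.01)

  ## a planted 8-fold marker is detected
  counts <- matrix(rpois(100 * 60, 4), 100, 60,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  counts[1, 31:60] <- rpois(30, 32)
  m <- count_matrix(counts)
  found <- cluster_degs(m, rep(0:1, each = 30))
  expect_true("g001" %in% found$gene[found$cluster == 1 & found$direction == "up"])

  ## BH monotonicity within each contrast
  ord <- order(found$cluster, found$p)
  by_cl <- split(found[ord, ], found$cluster[ord])
  for (d in by_cl) expect_true(all(diff(d$padj) >= -1e-12))
})

test_that("composition matrix uses the two-step normalization", {
  ## one subset, two equal groups
  expect_equal(unname(composition_heatmap(rep("s", 40), rep(c("g1", "g2"), 20))),
               matrix(c(50, 50), 1))
  ## a subset present only in one group
  labels <- c(rep("a", 10), rep("b", 10))
  groups <- c(rep("g1", 10), rep("g2", 10))
  cm <- composition_heatmap(labels, groups)
  expect_equal(cm["a", "g1"], 100)
  expect_equal(cm["a", "g2"], 0)
  ## hand toy: 10 of 100 vs 40 of 200 -> fractions 0.1 vs 0.2 -> (33.3, 66.7)
  labels2 <- c(rep("s", 10), rep("o", 90), rep("s", 40), rep("o", 160))
  groups2 <- c(rep("g1", 100), rep("g2", 200))
  cm2 <- composition_heatmap(labels2, groups2)
  expect_equal(unname(cm2["s", ]), c(100 / 3, 200 / 3))
  ## rows always sum to 100
  expect_true(all(abs(rowSums(cm2) - 100) < 1e-6))
})
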