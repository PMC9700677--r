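## Single-cell core: QC filtering, library-size log normalization, variable
## gene selection, cell-cycle scoring, covariate regression, SNN-Louvain
## clustering, endothelial gating, per-cluster Wilcoxon DEGs and
## subset-composition summaries.

#' Named QC / clustering presets
#'
#' Parameter bundles for the three profiled datasets: postnatal ontogeny
#' (1000-4600 detected genes, <= 4.5% mitochondrial reads, 12 PCs,
#' resolution 1.1), germ-free vs SPF (750-4000, 7%, 17 PCs, 0.4) and the
#' Irf3-knockout comparison (750-4500, 6%, 30 PCs, 0.4).
#'
#' @param name one of `"ontogeny"`, `"gfspf"`, `"irf3"`.
#' @return list with `min_genes`, `max_genes`, `max_pct_mito`, `dims`,
#'   `resolution`.
#' @export
qc_preset <- function(name = c("ontogeny", "gfspf", "irf3")) {
  name <- match.arg(name)
  switch(name,
    ontogeny = list(min_genes = 1000, max_genes = 4600, max_pct_mito = 4.5,
                    dims = 12, resolution = 1.1),
    gfspf = list(min_genes = 750, max_genes = 4000, max_pct_mito = 7,
                 dims = 17, resolution = 0.4),
    irf3 = list(min_genes = 750, max_genes = 4500, max_pct_mito = 6,
                dims = 30, resolution = 0.4)
  )
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains cells with `min_genes <= n_genes_detected <= max_genes`
#' (inclusive on both boundaries) and `pct_mito <= max_pct_mito`. A gene is
#' "detected" when its raw count exceeds zero. Features are untouched. An
#' empty result is returned as a zero-cell matrix with attribute
#' `empty_result = TRUE` rather than an error.
#'
#' @param m a [count_matrix].
#' @param min_genes,max_genes detected-gene bounds.
#' @param max_pct_mito maximum percent mitochondrial counts.
#' @return filtered [count_matrix].
#' @export
qc_filter <- function(m, min_genes = 1000, max_genes = 4600,
                      max_pct_mito = 4.5) {
  stopifnot(inherits(m, "count_matrix"), min_genes < max_genes)
  ng <- colSums(m$counts > 0)
  pm <- m$cell_meta$pct_mito
  keep <- ng >= min_genes & ng <= max_genes & pm <= max_pct_mito
  out <- subset_counts(m, cells = keep)
  if (sum(keep) == 0) {
    warning("no cell passes QC; returning empty matrix")
    attr(out, "empty_result") <- TRUE
  }
  out
}

#' Library-size normalization with log transform
#'
#' Per cell: counts divided by the cell total, multiplied by `scale`, then
#' `log1p`. Cells with zero total become all-zero columns with a warning.
#'
#' @param m a [count_matrix] or raw count matrix.
#' @param scale scale factor (default 10,000).
#' @return numeric matrix genes x cells of log-normalized expression.
#' @export
normalize_log <- function(m, scale = 1e4) {
  stopifnot(scale > 0)
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  tot <- colSums(counts)
  if (any(tot == 0)) warning("cells with zero total counts set to all-zero")
  denom <- ifelse(tot == 0, 1, tot)
  log1p(sweep(counts, 2, denom, "/") * scale)
}

#' Select highly variable genes
#'
#' Ranks genes by the residual of a loess fit of log-normalized expression
#' variance on mean (variance detrending), highest first; ties break
#' deterministically by gene name. Constant genes are never selected unless
#' `n` equals the number of features.
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param n number of genes to return (default 2000).
#' @return character vector of gene names, length `min(n, n_features)`.
#' @export
select_hvg <- function(m, n = 2000) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  stopifnot(n <= nrow(x))
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  if (n == nrow(x)) {
    return(rownames(x)[order(-v, rownames(x))])
  }
  score <- rep(-Inf, nrow(x))
  ok <- v > 0
  if (sum(ok) > 10) {
    fit <- suppressWarnings(loess(v[ok] ~ mu[ok], span = 0.75, degree = 2))
    score[ok] <- v[ok] - predict(fit, mu[ok])
  } else {
    score[ok] <- v[ok]
  }
  ord <- order(-score, rownames(x))
  cand <- ord[seq_len(min(n, sum(ok)))]
  rownames(x)[cand]
}

#' Per-cell S-phase and G2M-phase program scores
#'
#' Score = mean log-normalized expression of the phase gene set minus the
#' mean over control genes drawn (seeded) from expression-matched bins, so
#' that under no program activity the expectation is zero.
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param s_genes,g2m_genes phase gene sets.
#' @param n_bins number of expression bins for control matching (default 25).
#' @param n_ctrl control genes sampled per set gene (default 50).
#' @param seed integer seed for control sampling.
#' @return data.frame per cell: `s_score`, `g2m_score`.
#' @export
score_cell_cycle <- function(m, s_genes, g2m_genes, n_bins = 25,
                             n_ctrl = 50, seed = 1) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  score_one <- function(set, rng_seed) {
    present <- intersect(set, rownames(x))
    if (length(present) == 0) {
      stop("no phase gene found in the matrix; missing: ",
           paste(head(set, 5), collapse = ", "))
    }
    set <- present
    mu <- rowMeans(x)
    bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
    set.seed(rng_seed)
    ctrl <- unique(unlist(lapply(set, function(g) {
      pool <- rownames(x)[bins == bins[match(g, rownames(x))]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
    colMeans(x[set, , drop = FALSE]) - colMeans(x[ctrl, , drop = FALSE])
  }
  data.frame(s_score = score_one(s_genes, seed),
             g2m_score = score_one(g2m_genes, seed + 1),
             row.names = colnames(x))
}

#' Regress per-cell covariates out of an expression matrix
#'
#' Per gene, returns the residuals of an ordinary-least-squares fit of
#' expression on the covariates (plus intercept). Collinear covariate
#' columns are dropped with a warning.
#'
#' @param x genes x cells numeric matrix.
#' @param covs data.frame of per-cell covariates (rows = cells).
#' @return genes x cells residual matrix.
#' @export
regress_covariates <- function(x, covs) {
  covs <- as.data.frame(covs)
  stopifnot(ncol(x) == nrow(covs))
  if (!all(vapply(covs, function(c) all(is.finite(c)), TRUE))) {
    stop("covariates must be finite")
  }
  D <- cbind(intercept = 1, as.matrix(covs))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    warning("dropping collinear covariate(s): ", paste(drop, collapse = ", "))
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
  }
  ## residual maker applied to all genes at once
  coef <- solve(crossprod(D), crossprod(D, t(x)))
  res <- t(x) - D %*% coef
  t(res)
}

#' SNN-graph Louvain clustering
#'
#' PCA to `dims` components, shared-nearest-neighbor graph over the
#' `k_nn`-neighbor sets with Jaccard edge weights, Louvain community
#' detection at the given resolution. The 2-D embedding (first two PCs) is
#' attached for plotting only.
#'
#' @param x genes x cells numeric matrix (already normalized / regressed).
#' @param dims number of principal components (default 12).
#' @param resolution Louvain resolution (default 1.1).
#' @param k_nn neighbors per cell (default 20; reduced with a warning when
#'   there are fewer cells).
#' @param seed integer seed (tie-breaking in community detection).
#' @return list of class `cluster_result`: `labels` (integer per cell,
#'   contiguous from 0), `embedding` (cells x 2), `pc_scores`
#'   (cells x dims), `resolution`, `dims_used`.
#' @export
cluster_cells <- function(x, dims = 12, resolution = 1.1, k_nn = 20, seed = 1) {
  n <- ncol(x)
  stopifnot(dims <= min(dim(x)))
  if (n <= k_nn) {
    warning("fewer cells than k_nn; reducing k_nn")
    k_nn <- max(n - 1, 1)
  }
  pc <- prcomp(t(x), rank. = dims, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(dims), drop = FALSE]

  d <- as.matrix(dist(scores))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_nn + 1)]))
  ## SNN: Jaccard similarity of neighbor sets (including self)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_nn + 1),
    j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- as.matrix(shared) / (2 * (k_nn + 1) - as.matrix(shared))
  diag(jac) <- 0
  jac[jac < 1 / 15] <- 0   # prune weak ties, standard SNN practice
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  ## contiguous ids from 0, ordered by cluster size (largest first)
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(labels)])
  structure(list(labels = setNames(labels, colnames(x)),
                 embedding = pc$x[, 1:2, drop = FALSE],
                 pc_scores = scores,
                 resolution = resolution, dims_used = dims),
            class = "cluster_result")
}

#' Drop endothelial clusters by a gate gene
#'
#' Removes every cluster whose mean normalized expression of the gate gene
#' is at or above `max_expr` (strictly-below-threshold clusters are kept).
#'
#' @param m a [count_matrix].
#' @param clusters a `cluster_result` (or integer labels per cell).
#' @param gate_gene marker gene (default `"Pecam1"`).
#' @param max_expr exclusive upper bound on mean normalized expression
#'   (default 1).
#' @return filtered [count_matrix]; attribute `kept_clusters` lists the
#'   retained cluster ids. Empty result carries `empty_result = TRUE`.
#' @export
gate_non_endothelial <- function(m, clusters, gate_gene = "Pecam1",
                                 max_expr = 1) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  if (!gate_gene %in% rownames(m$counts)) {
    stop("gate gene not present: ", gate_gene)
  }
  x <- normalize_log(m)[gate_gene, ]
  mean_by_cl <- tapply(x, labels, mean)
  keep_cl <- as.integer(names(mean_by_cl)[mean_by_cl < max_expr])
  keep <- labels %in% keep_cl
  out <- subset_counts(m, cells = keep)
  attr(out, "kept_clusters") <- keep_cl
  if (!any(keep)) {
    warning("all clusters at or above the gate; returning empty matrix")
    attr(out, "empty_result") <- TRUE
  }
  out
}

wilcox_vs_rest <- function(x_in, x_out) {
  ## two-sided rank-sum; exact for small untied samples via stats::wilcox.test
  suppressWarnings(wilcox.test(x_in, x_out, alternative = "two.sided")$p.value)
}

#' Per-cluster differential expression (one vs rest)
#'
#' For each cluster, each gene is tested with a two-sided Wilcoxon rank-sum
#' of its normalized expression in the cluster against all other cells, with
#' BH correction per cluster. log2FC is computed on de-logged means:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. Only genes with
#' `|log2FC| >= min_log2fc` and `padj <= max_padj` are reported. Singleton
#' clusters are skipped with a warning.
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param labels cluster id per cell.
#' @param min_log2fc,max_padj reporting thresholds (defaults 0.2, 0.05).
#' @return data.frame: `gene`, `cluster`, `log2FC`, `p`, `padj`,
#'   `direction`.
#' @export
cluster_degs <- function(m, labels, min_log2fc = 0.2, max_padj = 0.05) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  labels <- as.vector(labels)
  stopifnot(length(labels) == ncol(x))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least 2 clusters")
  out <- list()
  for (cl in cls) {
    inside <- labels == cl
    if (sum(inside) < 2) {
      warning("skipping singleton cluster ", cl)
      next
    }
    expm_in <- rowMeans(expm1(x[, inside, drop = FALSE]))
    expm_out <- rowMeans(expm1(x[, !inside, drop = FALSE]))
    l2fc <- log2((expm_in + 1) / (expm_out + 1))
    p <- vapply(seq_len(nrow(x)), function(i) {
      wilcox_vs_rest(x[i, inside], x[i, !inside])
    }, numeric(1))
    p[is.na(p)] <- 1
    padj <- p.adjust(p, method = "BH")
    keep <- abs(l2fc) >= min_log2fc & padj <= max_padj
    if (any(keep)) {
      out[[as.character(cl)]] <- data.frame(
        gene = rownames(x)[keep], cluster = cl, log2FC = l2fc[keep],
        p = p[keep], padj = padj[keep],
        direction = ifelse(l2fc[keep] > 0, "up", "down"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), cluster = integer(0),
                      log2FC = numeric(0), p = numeric(0), padj = numeric(0),
                      direction = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset-composition matrix with two-step normalization
#'
#' Step 1 corrects unequal group sizes: within each group, the fraction of
#' its cells in each subset. Step 2 renormalizes each subset's fractions
#' across groups to sum to 100. Rows are subsets, columns groups; empty
#' groups give NaN columns with a warning.
#'
#' @param labels subset / cluster id per cell.
#' @param groups group (timepoint, condition, branch) per cell.
#' @return numeric matrix subsets x groups of percentages (rows sum to 100).
#' @export
composition_heatmap <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  tab <- table(factor(labels), factor(groups))
  gsize <- colSums(tab)
  if (any(gsize == 0)) warning("empty group yields NaN column")
  frac <- sweep(unclass(tab), 2, gsize, "/")
  pct <- 100 * frac / rowSums(frac)
  pct
}
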