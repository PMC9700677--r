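## Branching pseudotime on a principal tree: PCA, centroid minimum spanning
## tree, projection of cells onto tree edges, geodesic pseudotime from a
## root, segment-wise branch labels, marker-based branch splitting and
## branch-point differential expression.

#' Filter genes by mean normalized expression
#'
#' Keeps genes whose mean normalized expression is strictly greater than
#' `min_mean` (default 0.1).
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param min_mean exclusive lower bound on the mean.
#' @return character vector of gene names.
#' @export
expression_gene_filter <- function(m, min_mean = 0.1) {
  stopifnot(min_mean >= 0)
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  rownames(x)[rowMeans(x) > min_mean]
}

#' Fit a principal tree and order cells in pseudotime
#'
#' Cells are reduced to `dims` principal components; `centers` k-means
#' centroids (or the centroids of supplied cluster labels) are joined by a
#' Euclidean minimum spanning tree; each cell is projected onto its nearest
#' tree edge; pseudotime is the geodesic distance from the root node to the
#' projection, normalized to `[0, 1]`. Tree segments between
#' branch nodes (degree >= 3) become branch labels; cells on a branching
#' edge follow their projection offset.
#'
#' @param x genes x cells numeric matrix (normalized expression on filtered
#'   genes).
#' @param dims principal components to use (default 5).
#' @param seed integer seed (k-means initialization).
#' @param centers number of k-means centroids (default 10) or an integer
#'   vector of per-cell cluster labels whose centroids are used instead.
#' @param root root node id; `NULL` defers to [choose_root] (node 1 is used
#'   until then).
#' @param knn_smooth number of nearest neighbours over which each cell's PC
#'   scores are averaged before centroids are fitted (0 disables; the default
#'   `NULL` uses `n/50`, capped at 50). This denoising stabilizes the
#'   centroid tree, standing in for the latent-space smoothing a
#'   principal-graph optimizer performs; projections and pseudotime use the
#'   smoothed scores.
#' @return object of class `principal_tree`: `graph` (igraph tree with edge
#'   lengths), `node_coords`, `cell_edge` (edge index per cell),
#'   `cell_offset` (distance from the edge's first node), `cell_node`
#'   (nearer node per cell), `pseudotime` (normalized), `branch_label`,
#'   `root_node`, `pc_scores`.
#' @export
fit_principal_tree <- function(x, dims = 5, seed = 1, centers = 10,
                               root = NULL, knn_smooth = NULL) {
  n <- ncol(x)
  if (is.null(knn_smooth)) knn_smooth <- min(50, floor(n / 50))
  dims <- min(dims, n - 1, nrow(x))
  pc <- prcomp(t(x), rank. = dims, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(dims), drop = FALSE]
  if (sum(apply(scores, 2, var)) < 1e-12) {
    stop("degenerate input: all cells identical")
  }
  if (knn_smooth > 0 && n > knn_smooth + 1) {
    d <- as.matrix(dist(scores))
    nn <- t(apply(d, 1, function(row) order(row)[seq_len(knn_smooth + 1)]))
    scores <- t(vapply(seq_len(n), function(i) {
      colMeans(scores[nn[i, ], , drop = FALSE])
    }, numeric(dims)))
    rownames(scores) <- colnames(x)
  }

  if (length(centers) == n) {
    labels <- as.integer(factor(centers))
    cent <- do.call(rbind, lapply(sort(unique(labels)), function(k) {
      colMeans(scores[labels == k, , drop = FALSE])
    }))
  } else {
    set.seed(seed)
    k <- min(centers, n)
    cent <- kmeans(scores, centers = k, nstart = 10, iter.max = 100)$centers
  }
  k <- nrow(cent)
  stopifnot(k >= 2)

  ## Euclidean MST over centroids
  dmat <- as.matrix(dist(cent))
  gfull <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                               weighted = TRUE)
  tree <- igraph::mst(gfull)
  el <- igraph::as_edgelist(tree, names = FALSE)
  elen <- igraph::E(tree)$weight

  ## project every cell onto its nearest edge; projections may overhang past
  ## leaf nodes so that cells beyond the terminal centroid keep their order
  deg <- igraph::degree(tree)
  n_edges <- nrow(el)
  best_d <- rep(Inf, n); best_e <- integer(n); best_off <- numeric(n)
  for (e in seq_len(n_edges)) {
    a <- cent[el[e, 1], ]; b <- cent[el[e, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(scores, 2, a)
    tpar_raw <- as.vector(rel %*% ab) / len2
    tpar <- pmin(pmax(tpar_raw, 0), 1)
    ## distance to the (clamped) segment decides the nearest edge
    proj <- outer(tpar, ab) + matrix(a, n, length(a), byrow = TRUE)
    dd <- sqrt(rowSums((scores - proj)^2))
    ## overhang allowed only past a leaf end
    tpar_eff <- tpar
    if (deg[el[e, 1]] == 1) tpar_eff[tpar_raw < 0] <- tpar_raw[tpar_raw < 0]
    if (deg[el[e, 2]] == 1) tpar_eff[tpar_raw > 1] <- tpar_raw[tpar_raw > 1]
    upd <- dd < best_d
    best_d[upd] <- dd[upd]
    best_e[upd] <- e
    best_off[upd] <- tpar_eff[upd] * sqrt(len2)
  }

  ## extend leaf nodes outward to the farthest overhanging projection, so the
  ## tree spans the data and end cells keep their ordering
  for (e in seq_len(n_edges)) {
    on_e <- best_e == e
    if (!any(on_e)) next
    a_id <- el[e, 1]; b_id <- el[e, 2]
    ab <- cent[b_id, ] - cent[a_id, ]
    len <- sqrt(sum(ab^2))
    u <- ab / len
    if (deg[a_id] == 1) {
      m <- min(best_off[on_e])
      if (m < 0) {
        cent[a_id, ] <- cent[a_id, ] + m * u
        best_off[on_e] <- best_off[on_e] - m
        elen[e] <- elen[e] - m
      }
    }
    if (deg[b_id] == 1) {
      M <- max(best_off[on_e])
      if (M > elen[e]) {
        elen[e] <- M
        cent[b_id, ] <- cent[a_id, ] + u * M
      }
    }
  }
  igraph::E(tree)$weight <- elen

  obj <- structure(list(graph = tree, node_coords = cent,
                        edge_list = el, edge_length = elen,
                        cell_edge = best_e, cell_offset = best_off,
                        pc_scores = scores, cell_names = colnames(x)),
                   class = "principal_tree")
  set_root(obj, if (is.null(root)) 1L else root)
}

#' @export
print.principal_tree <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  cat(sprintf("principal_tree: %d nodes (%d leaves, %d branch nodes), %d cells, root %d\n",
              length(deg), sum(deg == 1), sum(deg >= 3),
              length(x$cell_edge), x$root_node))
  invisible(x)
}

#' Re-root a principal tree and recompute pseudotime and branch labels
#'
#' Pseudotime is geodesic distance from the root to each cell's projection
#' point, scaled to `[0, 1]` by the maximum. Branch labels are the maximal
#' unbranched tree segments: walking away from the root, each child edge of
#' a node with out-degree >= 2 starts a new segment; the segment containing
#' the root is `"root"`, others are `"branch<i>"` in discovery order.
#'
#' @param t a `principal_tree`.
#' @param root node id.
#' @return the re-rooted `principal_tree`.
#' @export
set_root <- function(t, root) {
  g <- t$graph
  nd <- igraph::distances(g, v = root)
  el <- t$edge_list

  ## pseudotime: distance from root to nearer endpoint + offset along edge;
  ## offsets outside [0, edge length] are leaf overhangs
  a <- el[t$cell_edge, 1]; b <- el[t$cell_edge, 2]
  len <- t$edge_length[t$cell_edge]
  off <- t$cell_offset
  da <- nd[a]; db <- nd[b]
  from_a <- da <= db
  pt_raw <- ifelse(off < 0, da - off,
                   ifelse(off > len, db + (off - len),
                          ifelse(from_a, da + off, db + (len - off))))
  maxpt <- max(pt_raw)
  pt <- if (maxpt > 0) pt_raw / maxpt else pt_raw

  ## segment decomposition from the root
  nv <- igraph::vcount(g)
  seg_of_edge <- integer(nrow(el))
  adj <- igraph::as_adj_list(g)
  eid <- function(u, v) {
    w <- which((el[, 1] == u & el[, 2] == v) | (el[, 1] == v & el[, 2] == u))
    w[1]
  }
  seg_names <- "root"
  ## BFS carrying the current segment id
  queue <- list(list(node = root, seg = 1L, parent = 0L))
  while (length(queue) > 0) {
    item <- queue[[1]]; queue <- queue[-1]
    nbrs <- setdiff(as.integer(adj[[item$node]]), item$parent)
    branching <- length(nbrs) >= 2 ||
      (item$node == root && length(nbrs) >= 2)
    for (nb in nbrs) {
      seg <- item$seg
      if (branching) {
        seg_names <- c(seg_names, sprintf("branch%d", length(seg_names)))
        seg <- length(seg_names)
      }
      seg_of_edge[eid(item$node, nb)] <- seg
      queue <- c(queue, list(list(node = nb, seg = seg, parent = item$node)))
    }
  }
  branch <- seg_names[seg_of_edge[t$cell_edge]]

  ## nearer node per cell (for root selection): by offset along own edge
  nearer <- as.integer(ifelse(off <= len / 2, a, b))

  t$root_node <- as.integer(root)
  t$pseudotime <- setNames(pt, t$cell_names)
  t$pseudotime_raw <- setNames(pt_raw, t$cell_names)
  t$branch_label <- setNames(branch, t$cell_names)
  t$cell_node <- setNames(nearer, t$cell_names)
  t$node_dist <- as.vector(nd)
  t$segment_of_edge <- seg_of_edge
  t$segment_names <- seg_names
  t
}

#' Choose the tree root from timepoint metadata
#'
#' The root is the node whose projected cells contain the highest fraction
#' of the earliest timepoint; ties break by the highest mean proliferation
#' score (when supplied), then by smallest node id.
#'
#' @param t a `principal_tree`.
#' @param cell_groups ordered factor or character of timepoint per cell
#'   (earliest level first; character vectors are sorted).
#' @param proliferation optional numeric per-cell proliferation score.
#' @return node id (integer).
#' @export
choose_root <- function(t, cell_groups, proliferation = NULL) {
  if (missing(cell_groups) || is.null(cell_groups)) {
    stop("no timepoint metadata; supply an explicit root to set_root()")
  }
  lev <- if (is.factor(cell_groups)) levels(cell_groups) else
    sort(unique(as.character(cell_groups)))
  earliest <- lev[1]
  nodes <- sort(unique(t$cell_node))
  frac <- vapply(nodes, function(nd) {
    cells <- t$cell_node == nd
    mean(as.character(cell_groups)[cells] == earliest)
  }, numeric(1))
  best <- nodes[frac == max(frac)]
  if (length(best) > 1 && !is.null(proliferation)) {
    ms <- vapply(best, function(nd) mean(proliferation[t$cell_node == nd]),
                 numeric(1))
    best <- best[ms == max(ms)]
  }
  as.integer(min(best))
}

#' Split terminal branches between two marker genes
#'
#' Each terminal branch (segment containing a leaf node) is assigned to the
#' marker with the higher mean normalized expression among its cells; all
#' its cells inherit the assignment. Branches with exactly tied means, and
#' cells on non-terminal segments, go to the unassigned set.
#'
#' @param t a `principal_tree`.
#' @param m [count_matrix] or log-normalized matrix containing both markers.
#' @param marker_a,marker_b marker gene names (e.g. Cd34 / Vcam1).
#' @return list with character vectors `set_a`, `set_b`, `unassigned`
#'   (cell names) and the per-branch decision table `branches`.
#' @export
split_by_markers <- function(t, m, marker_a, marker_b) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  for (mk in c(marker_a, marker_b)) {
    if (!mk %in% rownames(x)) stop("marker absent: ", mk)
  }
  g <- t$graph
  deg <- igraph::degree(g)
  leaves <- which(deg == 1 & seq_along(deg) != t$root_node)
  term_segs <- unique(vapply(leaves, function(lf) {
    e <- which(t$edge_list[, 1] == lf | t$edge_list[, 2] == lf)[1]
    t$segment_names[t$segment_of_edge[e]]
  }, character(1)))

  decide <- vapply(term_segs, function(sg) {
    cells <- names(t$branch_label)[t$branch_label == sg]
    if (length(cells) == 0) return("unassigned")
    ma <- mean(x[marker_a, cells]); mb <- mean(x[marker_b, cells])
    if (ma > mb) "a" else if (mb > ma) "b" else "unassigned"
  }, character(1))

  assign_of_cell <- rep("unassigned", length(t$branch_label))
  names(assign_of_cell) <- names(t$branch_label)
  for (sg in term_segs) {
    cells <- t$branch_label == sg
    assign_of_cell[cells] <- decide[[sg]]
  }
  list(set_a = names(assign_of_cell)[assign_of_cell == "a"],
       set_b = names(assign_of_cell)[assign_of_cell == "b"],
       unassigned = names(assign_of_cell)[assign_of_cell == "unassigned"],
       branches = data.frame(segment = term_segs, assigned = unname(decide),
                             stringsAsFactors = FALSE))
}

#' Differential expression between two post-branch-point branches
#'
#' Two-sided Wilcoxon rank-sum per gene between the cells of the two
#' branches, BH correction, same thresholds as [cluster_degs]. Requires at
#' least 10 cells per branch (smaller branches are skipped with a warning
#' and an empty table).
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param cells_a,cells_b cell name vectors of the two branches.
#' @param min_log2fc,max_padj reporting thresholds (defaults 0.2, 0.05).
#' @return DEG data.frame as in [cluster_degs] (`cluster` column holds
#'   "a_vs_b").
#' @export
branch_degs <- function(m, cells_a, cells_b, min_log2fc = 0.2,
                        max_padj = 0.05) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  empty <- data.frame(gene = character(0), cluster = character(0),
                      log2FC = numeric(0), p = numeric(0),
                      padj = numeric(0), direction = character(0))
  if (length(cells_a) < 10 || length(cells_b) < 10) {
    warning("branch with fewer than 10 cells; skipping")
    return(empty)
  }
  xa <- x[, cells_a, drop = FALSE]; xb <- x[, cells_b, drop = FALSE]
  l2fc <- log2((rowMeans(expm1(xa)) + 1) / (rowMeans(expm1(xb)) + 1))
  p <- vapply(seq_len(nrow(x)), function(i) {
    wilcox_vs_rest(xa[i, ], xb[i, ])
  }, numeric(1))
  p[is.na(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  keep <- abs(l2fc) >= min_log2fc & padj <= max_padj
  if (!any(keep)) return(empty)
  data.frame(gene = rownames(x)[keep], cluster = "a_vs_b",
             log2FC = l2fc[keep], p = p[keep], padj = padj[keep],
             direction = ifelse(l2fc[keep] > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Composition of cluster labels across tree branches
#'
#' Same two-step normalization as [composition_heatmap], with branches as
#' groups.
#'
#' @param t a `principal_tree`.
#' @param labels cluster / subset label per cell (in `t` cell order).
#' @return percentage matrix subsets x branches.
#' @export
branch_composition <- function(t, labels) {
  composition_heatmap(labels, t$branch_label)
}

#' Full trajectory workflow from raw counts
#'
#' Normalizes, keeps the `n_hvg` most variable genes, standardizes them,
#' fits the principal tree and roots it at the node dominated by the
#' earliest timepoint (from `cell_meta$timepoint` unless `groups` is given).
#'
#' @param m a [count_matrix] with a `timepoint` column in `cell_meta` (or
#'   supply `groups`).
#' @param n_hvg variable genes to use (default 500).
#' @param dims,centers,seed,knn_smooth passed to [fit_principal_tree].
#' @param groups optional per-cell timepoint overriding `cell_meta`.
#' @return a rooted `principal_tree`.
#' @export
run_trajectory <- function(m, n_hvg = 500, dims = 5, centers = 12, seed = 1,
                           knn_smooth = NULL, groups = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(groups)) groups <- m$cell_meta$timepoint
  x <- normalize_log(m)
  hvg <- select_hvg(x, min(n_hvg, nrow(x)))
  xs <- t(scale(t(x[hvg, , drop = FALSE])))
  xs[!is.finite(xs)] <- 0
  tr <- fit_principal_tree(xs, dims = dims, seed = seed, centers = centers,
                           knn_smooth = knn_smooth)
  set_root(tr, choose_root(tr, groups))
}

#' Export the tree skeleton as JSON (nodes, edges, lengths)
#'
#' @param t a `principal_tree`.
#' @param path output file.
#' @export
write_tree_json <- function(t, path) {
  jsonlite::write_json(list(
    nodes = seq_len(nrow(t$node_coords)),
    root = t$root_node,
    edges = data.frame(from = t$edge_list[, 1], to = t$edge_list[, 2],
                       length = t$edge_length)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
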