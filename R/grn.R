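## Dynamical gene-regulatory-network inference: pseudotemporal binning of
## branch expression into a pseudo-timeseries, random-forest regression of
## each gene's rate of change (plus first-order decay) on candidate TF
## levels, global Top-K link selection, and node-centrality summaries.

#' Order branch expression into an equal-occupancy pseudo-timeseries
#'
#' Cells of the branch are sorted by their time key and split into `n_bins`
#' equal-occupancy bins; the bin means form one pseudotemporal sample per
#' bin. Branches with fewer cells than bins reduce the bin count with a
#' warning.
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param branch_cells cell names of the branch.
#' @param time per-cell numeric time (pseudotime or physiological age),
#'   named by cell.
#' @param n_bins number of bins (default 20).
#' @return genes x bins matrix; attribute `bin_time` holds mean time per
#'   bin.
#' @export
order_expression <- function(m, branch_cells, time, n_bins = 20) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  cells <- intersect(branch_cells, colnames(x))
  stopifnot(length(cells) >= 2)
  tt <- time[cells]
  if (length(cells) < n_bins) {
    warning("branch has fewer cells than bins; reducing bins to ", length(cells))
    n_bins <- length(cells)
  }
  ord <- cells[order(tt)]
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  out <- vapply(seq_len(n_bins), function(b) {
    rowMeans(x[, ord[bin == b], drop = FALSE])
  }, numeric(nrow(x)))
  rownames(out) <- rownames(x)
  colnames(out) <- sprintf("bin%02d", seq_len(n_bins))
  attr(out, "bin_time") <- vapply(seq_len(n_bins), function(b) {
    mean(tt[ord[bin == b]])
  }, numeric(1))
  out
}

#' Infer a dynamical gene regulatory network from a pseudo-timeseries
#'
#' For each target gene g the response at step t is
#' `y_t = (x_g(t+1) - x_g(t)) / dt + alpha * x_g(t)`; a random-forest
#' regression of y on the candidate TF expressions at t yields per-TF
#' importances (total impurity reduction), used as link weights. The
#' strongest `top_k` links across all targets form the network. A TF never
#' predicts itself. Constant targets are skipped.
#'
#' @param ts genes x time matrix (e.g. from [order_expression]).
#' @param candidate_tfs character vector of regulator genes (subset of
#'   rownames).
#' @param alpha decay rate per unit time (default 0.02).
#' @param n_trees random-forest size (default 100).
#' @param seed integer seed.
#' @param top_k links retained globally, ranked by weight (default 500).
#' @param dt time step between consecutive columns (default 1).
#' @return object of class `grn`: `links` (data.frame regulator, target,
#'   weight, sorted by weight descending), `alpha`, `top_k`,
#'   `all_links` (pre-truncation).
#' @export
infer_network <- function(ts, candidate_tfs, alpha = 0.02, n_trees = 100,
                          seed = 1, top_k = 500, dt = 1) {
  stopifnot(all(candidate_tfs %in% rownames(ts)), ncol(ts) >= 3)
  nt <- ncol(ts)
  set.seed(seed)
  links <- list()
  for (g in rownames(ts)) {
    xg <- ts[g, ]
    y <- (xg[-1] - xg[-nt]) / dt + alpha * xg[-nt]
    preds <- setdiff(candidate_tfs, g)
    if (length(preds) == 0) next
    X <- t(ts[preds, -nt, drop = FALSE])
    if (var(y) < 1e-12) next
    mtry <- max(1, floor(sqrt(length(preds))))
    rf <- randomForest::randomForest(
      x = as.data.frame(X), y = y, ntree = n_trees, mtry = mtry,
      importance = FALSE)
    imp <- randomForest::importance(rf, type = 2)[, 1]
    links[[g]] <- data.frame(regulator = preds, target = g,
                             weight = unname(imp[preds]),
                             stringsAsFactors = FALSE)
  }
  all_links <- do.call(rbind, links)
  rownames(all_links) <- NULL
  all_links <- all_links[order(-all_links$weight, all_links$regulator,
                               all_links$target), ]
  kept <- head(all_links, top_k)
  rownames(kept) <- rownames(all_links) <- NULL
  structure(list(links = kept, alpha = alpha, top_k = top_k,
                 all_links = all_links, candidate_tfs = candidate_tfs),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("grn: %d links (top_k = %d), %d regulators\n",
              nrow(x$links), x$top_k, length(unique(x$links$regulator))))
  invisible(x)
}

#' Degree and betweenness per network node
#'
#' Degree counts in- plus out-links; betweenness is standard shortest-path
#' betweenness on the directed, unweighted link graph.
#'
#' @param net a `grn` (or a data.frame of links).
#' @return data.frame: `node`, `degree`, `betweenness`.
#' @export
node_stats <- function(net) {
  links <- if (inherits(net, "grn")) net$links else net
  stopifnot(nrow(links) > 0)
  g <- igraph::graph_from_data_frame(links[, c("regulator", "target")],
                                     directed = TRUE)
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(igraph::degree(g, mode = "all")),
             betweenness = igraph::betweenness(g, directed = TRUE,
                                               weights = NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regulator overlap between two networks
#'
#' @param net_a,net_b `grn` objects.
#' @return list: `regulators_a`, `regulators_b`, `shared`,
#'   `fraction_shared` (|intersection| / |union|).
#' @export
shared_regulators <- function(net_a, net_b) {
  ra <- sort(unique(net_a$links$regulator))
  rb <- sort(unique(net_b$links$regulator))
  stopifnot(length(ra) > 0, length(rb) > 0)
  shared <- intersect(ra, rb)
  list(regulators_a = ra, regulators_b = rb, shared = shared,
       fraction_shared = length(shared) / length(union(ra, rb)))
}

#' Write a network edge list as TSV
#'
#' @param net a `grn`.
#' @param path output file.
#' @export
write_grn_tsv <- function(net, path) {
  write.table(net$links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
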