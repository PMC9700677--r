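## Independent oracles used across the suite. Each re-derives a quantity by
## brute force or closed form, never through the code path under test.

## rank-based AUROC (Mann-Whitney)
rank_auc <- function(score, is_pos) {
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## one-sided (enrichment) Fisher p as an explicit hypergeometric tail sum
hyper_tail_p <- function(a, b, c, d) {
  m <- a + c          # in-set genes
  k <- a + b          # foreground draws
  n_tot <- a + b + c + d
  xs <- max(0, k - (n_tot - m)):min(k, m)
  sum(stats::dhyper(xs[xs >= a], m, n_tot - m, k))
}

## per-base occupancy union of 0-based half-open intervals on a small range
brute_union <- function(df, limit = 20000) {
  occ <- logical(limit)
  for (i in seq_len(nrow(df))) {
    occ[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

## exhaustive directed betweenness by shortest-path enumeration (<= 8 nodes)
brute_betweenness <- function(links) {
  nodes <- sort(unique(c(links$regulator, links$target)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[cbind(links$regulator, links$target)] <- TRUE
  ## all shortest paths between ordered pairs via BFS with path tracking
  bt <- setNames(numeric(n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    ## BFS levels
    paths <- list(c(s))
    found <- list()
    while (length(paths) > 0 && length(found) == 0) {
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (v in nodes[adj[last, ]]) {
          if (v %in% p) next
          q <- c(p, v)
          if (v == t) found[[length(found) + 1]] <- q else nxt[[length(nxt) + 1]] <- q
        }
      }
      paths <- nxt
    }
    if (length(found) > 0) {
      for (p in found) {
        inner <- p[-c(1, length(p))]
        for (v in inner) bt[v] <- bt[v] + 1 / length(found)
      }
    }
  }
  bt
}

## GRanges overlap helpers for planted-truth recovery
interval_recall <- function(called, truth) {
  if (nrow(truth) == 0) return(NA_real_)
  if (nrow(called) == 0) return(0)
  gc <- GenomicRanges::GRanges(called$chrom,
                               IRanges::IRanges(called$start + 1, called$end))
  gt <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  mean(GenomicRanges::countOverlaps(gt, gc) > 0)
}

interval_precision <- function(called, truth) {
  if (nrow(called) == 0) return(NA_real_)
  if (nrow(truth) == 0) return(0)
  gc <- GenomicRanges::GRanges(called$chrom,
                               IRanges::IRanges(called$start + 1, called$end))
  gt <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  mean(GenomicRanges::countOverlaps(gc, gt) > 0)
}

## branch-assignment accuracy of a marker split against planted truth
split_accuracy <- function(split, truth_branch) {
  pred <- rep("unassigned", length(truth_branch))
  names(pred) <- names(truth_branch)
  pred[intersect(split$set_a, names(pred))] <- "branchA"
  pred[intersect(split$set_b, names(pred))] <- "branchB"
  sel <- truth_branch %in% c("branchA", "branchB")
  mean(pred[sel] == truth_branch[sel])
}
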