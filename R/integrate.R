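## Joint interpretation of expression and accessibility: the tri-class gene
## scheme (correlated / inducible / active-TF-regulated), Fisher set
## enrichment, per-class motif enrichment and TF nomination at trajectory
## branch points.

#' Classify genes by concordance of expression and accessibility changes
#'
#' Using the upstream binary calls (a gene is expression-differential when it
#' appears in `degs`; accessibility-differential when it has at least one
#' associated DAR, optionally promoter-restricted):
#' * `correlated` - differential in both, same sign;
#' * `inducible` - accessibility changes without expression change;
#' * `active_tf_regulated` - expression changes with no associated DAR;
#' * `discordant` - differential in both with opposite signs;
#' * `unregulated` - neither signal.
#' The `side` column records which condition is up (expression sign when
#' available, else accessibility sign).
#'
#' @param degs DEG table (`gene`, `log2FC`) as from [cluster_degs] or
#'   [bulk_de] (already thresholded).
#' @param dars DAR table from [diff_accessibility].
#' @param gene_map region-to-gene map from [annotate_regions].
#' @param promoter_only when `TRUE` (default) only promoter-annotated DARs
#'   count as accessibility signal.
#' @param sides length-2 character naming the (down, up) conditions for the
#'   `side` label, in the order matching negative / positive log2FC.
#' @return data.frame: `gene`, `class`, `log2FC_expr`, `cum_log2FC_access`,
#'   `side`.
#' @export
classify_genes <- function(degs, dars, gene_map, promoter_only = TRUE,
                           sides = c("A_up", "B_up")) {
  cum <- cumulative_fc(dars, gene_map,
                       features = if (promoter_only) "promoter" else NULL)
  expr_fc <- setNames(degs$log2FC, degs$gene)
  universe <- sort(unique(c(degs$gene, names(cum),
                            gene_map$gene[!is.na(gene_map$gene)])))
  e <- expr_fc[universe]
  a <- cum[universe]
  has_e <- !is.na(e); has_a <- !is.na(a)
  cls <- rep("unregulated", length(universe))
  cls[has_a & !has_e] <- "inducible"
  cls[has_e & !has_a] <- "active_tf_regulated"
  both <- has_e & has_a
  cls[both & sign(e) == sign(a)] <- "correlated"
  cls[both & sign(e) != sign(a)] <- "discordant"
  side_fc <- ifelse(has_e, e, a)
  side <- ifelse(is.na(side_fc), NA_character_,
                 ifelse(side_fc > 0, sides[2], sides[1]))
  data.frame(gene = universe, class = cls,
             log2FC_expr = unname(e), cum_log2FC_access = unname(a),
             side = side, stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sided Fisher enrichment of annotation sets in a gene foreground
#'
#' For each annotation set, the 2x2 table (foreground x in-set) over the
#' background universe is tested with a one-sided Fisher exact test
#' (enrichment direction), BH-corrected across sets. Sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param foreground gene set of interest (must be contained in
#'   `background`).
#' @param background gene universe.
#' @param annotations named list of gene sets.
#' @return data.frame: `set`, `a`, `b`, `c`, `d` (contingency counts:
#'   fg-in-set, fg-out, bg-only-in-set, bg-only-out), `odds_ratio`
#'   (sample odds ratio), `p`, `padj`.
#' @export
fisher_set_enrichment <- function(foreground, background, annotations) {
  foreground <- unique(foreground); background <- unique(background)
  if (length(foreground) == 0) stop("empty foreground")
  stopifnot(all(foreground %in% background))
  rows <- lapply(names(annotations), function(nm) {
    set <- intersect(annotations[[nm]], background)
    if (length(set) == 0) {
      warning("annotation set disjoint from universe, skipped: ", nm)
      return(NULL)
    }
    a <- sum(foreground %in% set)
    b <- length(foreground) - a
    c <- length(set) - a
    d <- length(background) - a - b - c
    p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    ## sample odds ratio; degenerate margins carry no association
    orat <- if (min(a + b, c + d, a + c, b + d) == 0) 1 else (a * d) / (b * c)
    data.frame(set = nm, a = a, b = b, c = c, d = d,
               odds_ratio = orat, p = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(set = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), padj = numeric(0)))
  }
  rows$padj <- p.adjust(rows$p, method = "BH")
  rownames(rows) <- NULL
  rows
}

#' Motif enrichment within the class-by-side gene-loci sets
#'
#' Builds the six foreground sets (3 classes x 2 sides: correlated,
#' inducible, active_tf_regulated, each split by which condition is up) and
#' tests every motif for over-representation against the full accessible
#' universe (all genes in the motif table). A motif is flagged `recurrent`
#' when it is enriched (`padj < 0.05`) in at least `recurrent_min` of the
#' six sets.
#'
#' @param classes table from [classify_genes].
#' @param motif_hits 0/1 motif x gene matrix.
#' @param recurrent_min sets required for the recurrent flag (default 5).
#' @return list with `table` (long data.frame motif x set: counts, p, padj),
#'   `p_matrix` (motifs x sets of p-values, the heatmap shape) and
#'   `recurrent` (character vector of recurrent motifs).
#' @export
motif_enrichment_by_class <- function(classes, motif_hits, recurrent_min = 5) {
  universe <- intersect(classes$gene, colnames(motif_hits))
  stopifnot(length(universe) > 0)
  keep_classes <- c("correlated", "inducible", "active_tf_regulated")
  sets <- list()
  for (cl in keep_classes) {
    for (sd in sort(unique(classes$side[!is.na(classes$side)]))) {
      nm <- paste(cl, sd, sep = ".")
      sets[[nm]] <- intersect(
        classes$gene[classes$class == cl & !is.na(classes$side) &
                       classes$side == sd], universe)
    }
  }
  sets <- sets[lengths(sets) > 0]
  annotations <- apply(motif_hits[, universe, drop = FALSE] > 0, 1, function(r) {
    universe[r]
  }, simplify = FALSE)
  out <- lapply(names(sets), function(nm) {
    res <- fisher_set_enrichment(sets[[nm]], universe, annotations)
    res$gene_set <- nm
    res
  })
  tab <- do.call(rbind, out)
  names(tab)[names(tab) == "set"] <- "motif"
  pm <- matrix(NA_real_, nrow(motif_hits), length(sets),
               dimnames = list(rownames(motif_hits), names(sets)))
  pm[cbind(tab$motif, tab$gene_set)] <- tab$p
  enr <- tapply(tab$padj < 0.05, tab$motif, sum)
  recurrent <- names(enr)[enr >= recurrent_min]
  list(table = tab, p_matrix = pm, recurrent = sort(recurrent))
}

#' Nominate transcription factors at trajectory branch points
#'
#' Combines accessibility-derived TFs (via a motif-to-TF map over enriched
#' motifs) with branch differential expression: reports, per trajectory, the
#' fraction of accessibility-derived TFs that are differentially expressed,
#' the Venn decomposition (unique to each branch point, shared), and
#' optionally the union with DMR-proximal TFs.
#'
#' @param motif_to_tf data.frame `motif`, `tf` (many-to-many; optional
#'   `family` flag).
#' @param enriched_motifs character vector of enriched motif names.
#' @param branch_deg_list named list (one per trajectory) of DEG tables with
#'   a `gene` column.
#' @param dmr_tfs optional character vector of DMR-proximal TFs.
#' @return list: `accessibility_tfs`, `de_fraction` (per trajectory),
#'   `venn` (`only_a`, `only_b`, `shared` TF vectors using the first two
#'   trajectories), `combined` (union with `dmr_tfs`).
#' @export
nominate_tfs <- function(motif_to_tf, enriched_motifs, branch_deg_list,
                         dmr_tfs = NULL) {
  if (nrow(motif_to_tf) == 0) stop("empty motif-to-TF map")
  acc_tfs <- sort(unique(motif_to_tf$tf[motif_to_tf$motif %in% enriched_motifs]))
  de_sets <- lapply(branch_deg_list, function(d) {
    intersect(acc_tfs, unique(d$gene))
  })
  de_fraction <- vapply(de_sets, function(s) {
    if (length(acc_tfs) == 0) 0 else length(s) / length(acc_tfs)
  }, numeric(1))
  venn <- NULL
  if (length(de_sets) >= 2) {
    a <- de_sets[[1]]; b <- de_sets[[2]]
    venn <- list(only_a = sort(setdiff(a, b)), only_b = sort(setdiff(b, a)),
                 shared = sort(intersect(a, b)))
  }
  list(accessibility_tfs = acc_tfs, de_fraction = de_fraction,
       de_tfs = de_sets, venn = venn,
       combined = sort(union(acc_tfs, dmr_tfs)))
}
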