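## Subset signatures and cumulative Z-scores: bulk differential expression
## with the expressed-gene filter and TPM, Top-N signature construction,
## cZscore matching of overexpression profiles and of single cells, and the
## interferon-stimulated-gene overlap score.

#' Transcripts-per-million from raw counts and exon lengths
#'
#' @param counts genes x samples matrix.
#' @param lengths exon length in bp per gene.
#' @return TPM matrix (columns sum to 1e6 for non-empty samples).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(nrow(counts) == length(lengths))
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Bulk differential expression between two arms
#'
#' Applies the expressed-gene filter (at least `min_reads` reads in at least
#' `min_reps` replicates across all samples), computes TPM when lengths are
#' available, and tests with the negative-binomial Wald machinery of
#' [diff_accessibility]. A gene is `de` when expressed, `padj < max_padj`
#' and `|FC| > min_fc` (strict, natural scale).
#'
#' @param m a [count_matrix] whose `cell_meta` has an `arm` column, or a raw
#'   matrix plus `arms`.
#' @param arms character of arm per sample (2 arms; log2FC is second arm,
#'   alphabetically, over first).
#' @param gene_lengths optional exon lengths (bp) named by gene; taken from
#'   `feature_meta$length` when present.
#' @param min_reads,min_reps expressed filter (defaults 5 reads, 2 reps).
#' @param max_padj,min_fc DE thresholds (defaults 0.05, 2; FC strict).
#' @return data.frame: `gene`, `baseMean`, `log2FC`, `p`, `padj`,
#'   `expressed`, `de`, plus `tpm_<sample>` columns when lengths are known.
#' @export
bulk_de <- function(m, arms = NULL, gene_lengths = NULL,
                    min_reads = 5, min_reps = 2,
                    max_padj = 0.05, min_fc = 2) {
  if (inherits(m, "count_matrix")) {
    if (is.null(arms)) arms <- m$cell_meta$arm
    if (is.null(gene_lengths) && "length" %in% colnames(m$feature_meta)) {
      gene_lengths <- setNames(m$feature_meta$length, rownames(m$counts))
    }
    counts <- m$counts
  } else {
    counts <- as.matrix(m)
  }
  stopifnot(length(arms) == ncol(counts))
  lev <- sort(unique(arms))
  stopifnot(length(lev) == 2)
  if (min(table(arms)) < 2) stop("need >= 2 replicates per arm")

  expressed <- rowSums(counts >= min_reads) >= min_reps
  res <- diff_accessibility(counts, arms, max_padj = max_padj, min_fc = min_fc)
  out <- data.frame(gene = rownames(counts), baseMean = res$baseMean,
                    log2FC = res$log2FC, p = res$p, padj = res$padj,
                    expressed = expressed, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$de <- expressed & out$padj < max_padj & abs(out$log2FC) > log2(min_fc)
  if (!is.null(gene_lengths)) {
    tp <- tpm(counts, gene_lengths[rownames(counts)])
    colnames(tp) <- paste0("tpm_", colnames(counts))
    out <- cbind(out, tp)
    attr(out, "tpm") <- tp
  }
  attr(out, "arms") <- arms
  attr(out, "arm_levels") <- lev
  out
}

#' Build Top-N upregulated signatures per subset
#'
#' Per subset, the top `n` upregulated DEGs ranked by adjusted p-value then
#' by descending |log2FC|, ties broken by gene name. Subsets with fewer
#' DEGs yield shorter signatures with a warning. Shared genes across
#' signatures are allowed.
#'
#' @param degs DEG table from [cluster_degs] (uses rows with
#'   `direction == "up"`).
#' @param n signature size (default 100).
#' @return named list of gene vectors (class `signature_set`).
#' @export
build_signatures <- function(degs, n = 100) {
  up <- degs[degs$direction == "up", , drop = FALSE]
  out <- lapply(split(up, up$cluster), function(d) {
    d <- d[order(d$padj, -abs(d$log2FC), d$gene), ]
    if (nrow(d) < n) {
      warning("subset ", d$cluster[1], " has only ", nrow(d), " DEGs")
    }
    unique(head(d$gene, n))
  })
  structure(out, class = "signature_set")
}

#' Cumulative Z-score of an overexpression profile against a signature
#'
#' For every signature gene that is differentially expressed in the
#' overexpression arm, the gene's z-score is the change of mean log(TPM+1)
#' (overexpression minus control) standardized by the control-arm standard
#' deviation; the cZscore is the sum of those z over the signature, and the
#' overlap is the percentage of signature genes that are DE. Genes whose
#' control sd is zero are skipped and counted in the report.
#'
#' @param de result of [bulk_de] (with TPM columns).
#' @param signature character vector of signature genes.
#' @return list: `czscore`, `pct_overlap`, `n_de`, `n_skipped`,
#'   `per_gene` (data.frame of contributing genes and z).
#' @export
czscore_bulk <- function(de, signature) {
  tp <- attr(de, "tpm")
  if (is.null(tp)) stop("bulk_de result lacks TPM; supply gene lengths")
  arms <- attr(de, "arms"); lev <- attr(de, "arm_levels")
  lt <- log1p(tp)
  ctrl <- lt[, arms == lev[1], drop = FALSE]
  oe <- lt[, arms == lev[2], drop = FALSE]
  sig <- intersect(signature, de$gene)
  de_sig <- sig[sig %in% de$gene[de$de]]
  z <- numeric(0); skipped <- 0L
  for (g in de_sig) {
    i <- match(g, de$gene)
    s <- sd(ctrl[i, ])
    if (!is.finite(s) || s == 0) { skipped <- skipped + 1L; next }
    z[g] <- (mean(oe[i, ]) - mean(ctrl[i, ])) / s
  }
  list(czscore = sum(z), pct_overlap = 100 * length(de_sig) / length(signature),
       n_de = length(de_sig), n_skipped = skipped,
       per_gene = data.frame(gene = names(z), z = unname(z),
                             stringsAsFactors = FALSE))
}

#' Per-cell cumulative Z-score over a gene set
#'
#' Each gene's log-normalized expression is z-scored across cells; a cell's
#' score is the sum of z over the set genes. Genes with zero variance
#' contribute 0.
#'
#' @param m [count_matrix] or log-normalized matrix.
#' @param gene_set character vector (at least one present gene required).
#' @return named numeric per cell.
#' @export
czscore_per_cell <- function(m, gene_set) {
  x <- if (inherits(m, "count_matrix")) normalize_log(m) else as.matrix(m)
  set <- intersect(gene_set, rownames(x))
  if (length(set) == 0) stop("no gene of the set present in the matrix")
  xs <- x[set, , drop = FALSE]
  mu <- rowMeans(xs)
  s <- apply(xs, 1, sd)
  z <- (xs - mu) / ifelse(s > 0, s, Inf)
  colSums(z)
}

#' Filter an interferon-stimulated-gene table and score the remaining set
#'
#' Rows are kept when `time <= tmax`, `fc > fc_min` and `p < 0.05`; the
#' surviving gene set is scored with [czscore_per_cell] (on a cell matrix)
#' or [czscore_bulk] (on a [bulk_de] result).
#'
#' @param x a [count_matrix] / log-normalized matrix, or a [bulk_de] result.
#' @param isg_table data.frame with columns `gene`, `fc`, `p`, `time`
#'   (hours).
#' @param fc_min fold-change threshold (default 2, strict >).
#' @param tmax latest stimulation time in hours (default 6, inclusive).
#' @return list with `genes` (the filtered set) and `score` (per-cell vector
#'   or [czscore_bulk] list).
#' @export
isg_overlap <- function(x, isg_table, fc_min = 2, tmax = 6) {
  stopifnot(all(c("gene", "fc", "p", "time") %in% colnames(isg_table)))
  keep <- isg_table$time <= tmax & isg_table$fc > fc_min & isg_table$p < 0.05
  genes <- unique(isg_table$gene[keep])
  if (length(genes) == 0) stop("ISG filter left an empty set")
  score <- if (is.data.frame(x) && "de" %in% colnames(x)) {
    czscore_bulk(x, genes)
  } else {
    czscore_per_cell(x, genes)
  }
  list(genes = genes, score = score)
}
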