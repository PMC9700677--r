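## ATAC-seq differential accessibility: replicate peak consolidation with
## blacklist removal, median-of-ratios normalization, a negative-binomial
## Wald test with trend-shrunk method-of-moments dispersions, TSS annotation
## and per-gene cumulative fold change.

#' Merge replicate peak sets and remove blacklisted intervals
#'
#' Peaks from all replicates that share at least one base pair are combined
#' into one interval (pure union; intervals that merely touch at a boundary
#' stay separate under half-open coordinates). Any merged interval
#' overlapping the blacklist by at least one base pair is dropped.
#'
#' @param replicate_sets list of interval data.frames (`chrom`, `start`,
#'   `end`).
#' @param blacklist optional interval data.frame.
#' @return interval data.frame of merged peaks named `mpeak<i>`.
#' @export
merge_peaks <- function(replicate_sets, blacklist = NULL) {
  stopifnot(length(replicate_sets) >= 1)
  all_df <- do.call(rbind, lapply(replicate_sets, function(d) {
    d <- d[, c("chrom", "start", "end")]
    if (is.unsorted(order(d$chrom, d$start))) {
      warning("unsorted replicate peak set; sorting")
      d <- d[order(d$chrom, d$start), ]
    }
    d
  }))
  gr <- intervals_to_granges(all_df)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    bl <- intervals_to_granges(blacklist)
    bad <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(merged, bl)))
    if (length(bad) > 0) merged <- merged[-bad]
  }
  out <- granges_to_intervals(merged)
  out$name <- sprintf("mpeak%05d", seq_len(nrow(out)))
  out
}

#' Median-of-ratios size factors and normalized counts
#'
#' The reference profile is the per-region geometric mean across samples,
#' restricted to regions positive in every sample; each sample's size factor
#' is the median of its count-to-reference ratios. When no region is
#' positive in all samples the function falls back to library-size factors
#' (total counts scaled to geometric mean 1) with a warning.
#'
#' @param counts numeric matrix regions x samples (or a [count_matrix]).
#' @return list with `size_factors` (named) and `normalized` (counts divided
#'   by their sample's factor).
#' @export
count_normalize <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no region positive in all samples; using library-size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  } else {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(x) {
      median(exp(log(x) - logref))
    })
  }
  names(sf) <- colnames(counts)
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Negative-binomial Wald test for differential accessibility
#'
#' Counts are normalized by median-of-ratios size factors; per-region
#' dispersions are method-of-moments estimates shrunk halfway toward a
#' mean-dispersion trend; the Wald statistic tests the log2 ratio of group
#' means (pseudocount 0.5) against zero, with BH correction across regions.
#' A region is flagged `dar` when `padj < max_padj` (strict) and
#' `|log2FC| >= log2(min_fc)` (inclusive).
#'
#' @param counts regions x samples matrix or [count_matrix].
#' @param groups character vector of condition per sample (2 conditions,
#'   >= 2 replicates each). log2FC is second condition (alphabetically) over
#'   first.
#' @param max_padj adjusted-p threshold (default 0.05).
#' @param min_fc fold-change threshold on the natural scale (default 2).
#' @return data.frame: `region`, `baseMean`, `log2FC`, `se`, `p`, `padj`,
#'   `dar`, `direction`.
#' @export
diff_accessibility <- function(counts, groups, max_padj = 0.05, min_fc = 2) {
  if (inherits(counts, "count_matrix")) {
    if (missing(groups)) groups <- counts$cell_meta$condition
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2)
  na <- sum(groups == lev[1]); nb <- sum(groups == lev[2])
  if (na < 2 || nb < 2) stop("each condition needs >= 2 replicates to estimate dispersion")

  norm <- count_normalize(counts)$normalized
  a <- norm[, groups == lev[1], drop = FALSE]
  b <- norm[, groups == lev[2], drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  base_mean <- rowMeans(norm)

  ## method-of-moments dispersion per region, pooled within conditions
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  pooled_mu <- (na * ma + nb * mb) / (na + nb)
  disp_mom <- pmax((pooled_var - pooled_mu) / pooled_mu^2, 1e-8)
  disp_mom[!is.finite(disp_mom)] <- 1e-8

  ## mean-dispersion trend: loess of log dispersion on log mean
  ok <- pooled_mu > 0 & is.finite(disp_mom)
  trend <- rep(median(disp_mom[ok]), length(disp_mom))
  if (sum(ok) > 50) {
    fit <- suppressWarnings(loess(log(disp_mom[ok]) ~ log(pooled_mu[ok]),
                                  span = 0.5, degree = 1))
    tr <- exp(predict(fit, log(pmax(pooled_mu, min(pooled_mu[ok])))))
    trend[is.finite(tr)] <- tr[is.finite(tr)]
  }
  disp <- 0.5 * disp_mom + 0.5 * trend

  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  ## delta-method SE of log2 of a mean of NB counts
  v_log_a <- (1 / pmax(ma, 0.5) + disp) / na
  v_log_b <- (1 / pmax(mb, 0.5) + disp) / nb
  se <- sqrt(v_log_a + v_log_b) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")
  dar <- padj < max_padj & abs(log2fc) >= log2(min_fc)
  data.frame(
    region = if (!is.null(rownames(counts))) rownames(counts) else
      sprintf("region%05d", seq_len(nrow(counts))),
    baseMean = base_mean, log2FC = log2fc, se = se, p = p, padj = padj,
    dar = dar,
    direction = ifelse(log2fc > 0, paste0(lev[2], "_up"), paste0(lev[1], "_up")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify regions by genomic feature and assign the nearest gene
#'
#' A region is a `promoter` when it lies within `promoter_window` bp of a
#' TSS (any overlap of the region with the window), a `gene_body` when it
#' overlaps a gene span without touching a promoter window, else
#' `intergenic`. Every region also gets its nearest gene by TSS distance
#' from the region midpoint.
#'
#' @param regions interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param genes annotation data.frame with `gene`, `chrom`, `tss`, `strand`
#'   and optionally `start`/`end` gene spans (defaults to TSS +- 10 kb
#'   downstream when absent).
#' @param promoter_window promoter half-width in bp (default 2000).
#' @return data.frame: `region`, `feature`, `gene`, `tss_distance`.
#' @export
annotate_regions <- function(regions, genes, promoter_window = 2000) {
  stopifnot(all(c("gene", "chrom", "tss") %in% colnames(genes)))
  if (!all(c("start", "end") %in% colnames(genes))) {
    minus <- !is.null(genes$strand) & genes$strand == "-"
    genes$start <- ifelse(minus, pmax(genes$tss - 10000, 0), genes$tss)
    genes$end <- ifelse(minus, genes$tss + 2, genes$tss + 10000)
  }
  nm <- if ("name" %in% colnames(regions)) regions$name else
    sprintf("region%05d", seq_len(nrow(regions)))
  mid <- floor((regions$start + regions$end) / 2)
  feature <- character(nrow(regions))
  gene <- character(nrow(regions))
  tssd <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    same <- which(genes$chrom == regions$chrom[i])
    if (length(same) == 0) {
      feature[i] <- "intergenic"; gene[i] <- NA_character_; tssd[i] <- NA_real_
      next
    }
    d <- abs(genes$tss[same] - mid[i])
    j <- same[which.min(d)]
    gene[i] <- genes$gene[j]
    tssd[i] <- min(d)
    ## promoter: region overlaps [tss - w, tss + w)
    prom <- any(regions$start[i] < genes$tss[same] + promoter_window &
                  regions$end[i] > genes$tss[same] - promoter_window)
    body <- any(regions$start[i] < genes$end[same] &
                  regions$end[i] > genes$start[same])
    feature[i] <- if (prom) "promoter" else if (body) "gene_body" else "intergenic"
  }
  data.frame(region = nm, feature = feature, gene = gene,
             tss_distance = tssd, stringsAsFactors = FALSE)
}

#' Per-gene cumulative fold change over associated DARs
#'
#' For each gene, the arithmetic mean of the signed log2 fold changes of all
#' differential regions assigned to it. Genes without any DAR are absent
#' from the output.
#'
#' @param dars [diff_accessibility] table (only rows with `dar == TRUE`
#'   contribute).
#' @param gene_map [annotate_regions] table linking regions to genes.
#' @param features optional subset of feature classes to use (e.g.
#'   `"promoter"`); `NULL` uses all.
#' @return named numeric vector gene -> mean log2FC.
#' @export
cumulative_fc <- function(dars, gene_map, features = NULL) {
  d <- dars[dars$dar, , drop = FALSE]
  gm <- gene_map
  if (!is.null(features)) gm <- gm[gm$feature %in% features, , drop = FALSE]
  d <- merge(d, gm[, c("region", "gene")], by = "region")
  d <- d[!is.na(d$gene), , drop = FALSE]
  if (nrow(d) == 0) return(setNames(numeric(0), character(0)))
  out <- tapply(d$log2FC, d$gene, mean)
  setNames(as.numeric(out), names(out))
}
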