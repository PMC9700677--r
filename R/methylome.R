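## Whole-genome bisulfite analysis: coverage filtering, kernel smoothing of
## CpG methylation, group t-statistics with a pooled-sd floor, and DMR
## construction under four criteria (>= 3 CpGs, <= 300 bp apart, mean
## difference >= 0.25, all member t beyond empirical quantile cutoffs).

#' Per-CpG methylation table
#'
#' Holds methylated-read and coverage counts per CpG and sample on 0-based
#' coordinates, with a sample-to-condition map. Positions must be strictly
#' increasing within each chromosome and `0 <= M <= C` everywhere.
#'
#' @param chrom chromosome per CpG.
#' @param pos 0-based CpG coordinate (each CpG occupies `[pos, pos + 2)`).
#' @param M integer matrix CpG x sample of methylated read counts.
#' @param Cov integer matrix CpG x sample of total coverage.
#' @param group named character vector sample -> condition.
#' @return object of class `methylome_table`.
#' @export
methylome_table <- function(chrom, pos, M, Cov, group) {
  M <- as.matrix(M); Cov <- as.matrix(Cov)
  stopifnot(length(chrom) == length(pos), nrow(M) == length(pos),
            all(dim(M) == dim(Cov)), all(M >= 0), all(Cov >= M))
  if (is.null(colnames(M))) colnames(M) <- names(group)
  if (is.null(colnames(Cov))) colnames(Cov) <- colnames(M)
  stopifnot(!is.null(names(group)), all(colnames(M) %in% names(group)))
  group <- group[colnames(M)]
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chrom")
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 M = M, Cov = Cov, group = group),
            class = "methylome_table")
}

#' @export
print.methylome_table <- function(x, ...) {
  cat(sprintf("methylome_table: %d CpGs, %d samples (%s)\n",
              length(x$pos), ncol(x$M),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a methylome table as TSV
#'
#' Plain-text layout: `chrom`, `pos`, then `M_<sample>` and `C_<sample>`
#' columns; the condition map is encoded in the sample names written to a
#' header comment-free companion convention `<sample>` = `<group>.<rep>`.
#'
#' @param t a `methylome_table`.
#' @param path file path.
#' @export
write_methylome_tsv <- function(t, path) {
  df <- data.frame(chrom = t$chrom, pos = t$pos)
  for (s in colnames(t$M)) df[[paste0("M_", s)]] <- t$M[, s]
  for (s in colnames(t$Cov)) df[[paste0("C_", s)]] <- t$Cov[, s]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylome_tsv
#' @param group named sample -> condition vector for the samples in the file.
#' @export
read_methylome_tsv <- function(path, group) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  msamp <- sub("^M_", "", grep("^M_", colnames(df), value = TRUE))
  M <- as.matrix(df[, paste0("M_", msamp), drop = FALSE])
  Cov <- as.matrix(df[, paste0("C_", msamp), drop = FALSE])
  colnames(M) <- colnames(Cov) <- msamp
  methylome_table(df$chrom, df$pos, M, Cov, group)
}

#' Coverage filter for CpGs
#'
#' Keeps CpGs covered by at least `min_cov` reads in at least `min_reps`
#' replicates of at least one condition.
#'
#' @param t a `methylome_table`.
#' @param min_cov minimum read coverage (default 5).
#' @param min_reps minimum qualifying replicates (default 2).
#' @return filtered `methylome_table`.
#' @export
coverage_filter <- function(t, min_cov = 5, min_reps = 2) {
  stopifnot(inherits(t, "methylome_table"), min_cov >= 0)
  if (min_cov < 1) return(t)
  ok <- rep(FALSE, length(t$pos))
  for (g in unique(t$group)) {
    cols <- names(t$group)[t$group == g]
    ok <- ok | rowSums(t$Cov[, cols, drop = FALSE] >= min_cov) >= min_reps
  }
  t$chrom <- t$chrom[ok]; t$pos <- t$pos[ok]
  t$M <- t$M[ok, , drop = FALSE]; t$Cov <- t$Cov[ok, , drop = FALSE]
  t
}

#' Smooth per-sample methylation levels along the genome
#'
#' Coverage-weighted local-linear fit (tricube kernel) of the raw ratio
#' `M / C` over a window that is the wider of `bandwidth` bp and the span of
#' the `min_cpg_window` nearest CpGs, evaluated at each CpG and clipped to
#' `[0, 1]`. Chromosomes holding fewer CpGs than `min_cpg_window` fall back
#' to a coverage-weighted mean with a warning.
#'
#' @param t a `methylome_table`.
#' @param bandwidth window width in bp (default 300, suited to the ~200 bp
#'   CpG spacing of the synthetic genome; widen for sparser genomes).
#' @param min_cpg_window minimum CpGs per window (default 5).
#' @return matrix CpG x sample of smoothed levels.
#' @export
smooth_methylation <- function(t, bandwidth = 300, min_cpg_window = 5) {
  stopifnot(inherits(t, "methylome_table"), bandwidth > 0)
  n <- length(t$pos)
  out <- matrix(NA_real_, n, ncol(t$M), dimnames = list(NULL, colnames(t$M)))
  for (ch in unique(t$chrom)) {
    idx <- which(t$chrom == ch)
    few <- length(idx) < min_cpg_window
    if (few) {
      warning(sprintf("chromosome %s has fewer than %d CpGs; using weighted mean",
                      ch, min_cpg_window))
    }
    for (s in colnames(t$M)) {
      cov <- t$Cov[idx, s]
      ratio <- ifelse(cov > 0, t$M[idx, s] / cov, NA_real_)
      if (few) {
        w <- cov
        mu <- if (sum(w) > 0) sum(w * ratio, na.rm = TRUE) / sum(w[!is.na(ratio)]) else NA_real_
        out[idx, s] <- ifelse(is.na(ratio) & is.na(mu), NA_real_,
                              pmin(pmax(rep(mu, length(idx)), 0), 1))
      } else {
        out[idx, s] <- smooth_llin(as.numeric(t$pos[idx]), ratio, cov,
                                   bandwidth, as.integer(min_cpg_window))
      }
    }
  }
  out
}

#' Two-group t-statistic per CpG on smoothed levels
#'
#' `t = (mean_A - mean_B) / (sd_pooled * sqrt(1/n_A + 1/n_B))` with the
#' pooled standard deviation floored at its genome-wide 75th percentile, a
#' shrinkage step that keeps near-constant sites from dominating the tails.
#'
#' @param smoothed CpG x sample matrix from [smooth_methylation].
#' @param groups named sample -> condition vector (exactly 2 conditions; the
#'   first level, alphabetically, is "A" in the difference).
#' @return data.frame with per-CpG `mean_a`, `mean_b`, `diff`, `sd_pooled`,
#'   `tstat`.
#' @export
group_tstat <- function(smoothed, groups) {
  groups <- groups[colnames(smoothed)]
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2)
  a <- smoothed[, names(groups)[groups == lev[1]], drop = FALSE]
  b <- smoothed[, names(groups)[groups == lev[2]], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) {
    stop("each condition needs >= 2 samples for a pooled variance; ",
         "use a variance-floor-only analysis for single replicates")
  }
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  floor_sd <- quantile(sp, 0.75, na.rm = TRUE, names = FALSE)
  spf <- pmax(sp, floor_sd)
  tt <- (ma - mb) / (spf * sqrt(1 / na + 1 / nb))
  data.frame(mean_a = ma, mean_b = mb, diff = ma - mb,
             sd_pooled = sp, tstat = tt)
}

#' Construct differentially methylated regions from per-CpG t-statistics
#'
#' Candidate CpGs are those whose t-statistic lies beyond the empirical
#' `q_low` / `q_high` quantiles of all t-statistics. Maximal runs of
#' same-sign candidates with inter-CpG gaps of at most `max_gap` bp become
#' regions; a region is kept when it holds at least `min_cpg` CpGs and the
#' absolute mean smoothed group difference over its members is at least
#' `min_diff`. Regions are half-open `[first pos, last pos + 2)`.
#'
#' @param tstats numeric vector of per-CpG t (from [group_tstat]).
#' @param chrom,positions CpG coordinates (0-based), sorted within chrom.
#' @param diffs per-CpG smoothed group difference (mean_A - mean_B).
#' @param q_low,q_high empirical quantile cutoffs (defaults 0.01 / 0.99).
#' @param cutoffs optional explicit `c(low, high)` t cutoffs, bypassing the
#'   quantile estimation (which refuses genomes under 100 CpGs).
#' @param max_gap maximum distance between consecutive member CpGs (300 bp).
#' @param min_cpg minimum CpGs per region (3).
#' @param min_diff minimum absolute mean methylation difference (0.25).
#' @return data.frame of DMRs: `chrom`, `start`, `end`, `n_cpg`,
#'   `mean_diff`, `direction` ("hyper" = higher in condition A),
#'   `area_stat` (sum of member t).
#' @export
find_dmrs <- function(tstats, chrom, positions, diffs,
                      q_low = 0.01, q_high = 0.99,
                      max_gap = 300, min_cpg = 3, min_diff = 0.25,
                      cutoffs = NULL) {
  n <- length(tstats)
  stopifnot(length(positions) == n, length(diffs) == n, length(chrom) == n)
  if (is.null(cutoffs)) {
    if (n < 100) stop("fewer than 100 CpGs genome-wide; refusing quantile estimation")
    cuts <- quantile(tstats, c(q_low, q_high), na.rm = TRUE, names = FALSE)
  } else {
    cuts <- cutoffs
  }
  cand <- !is.na(tstats) & (tstats < cuts[1] | tstats > cuts[2])

  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0),
                      mean_diff = numeric(0), direction = character(0),
                      area_stat = numeric(0), stringsAsFactors = FALSE)
  if (!any(cand)) return(empty)

  idx <- which(cand)
  ch <- chrom[idx]; po <- positions[idx]; tt <- tstats[idx]; dd <- diffs[idx]
  sgn <- sign(tt)
  ## break runs at chromosome change, gap > max_gap, or sign change
  brk <- c(TRUE, ch[-1] != ch[-length(ch)] |
             diff(po) > max_gap |
             sgn[-1] != sgn[-length(sgn)])
  run <- cumsum(brk)
  out <- lapply(split(seq_along(idx), run), function(ii) {
    if (length(ii) < min_cpg) return(NULL)
    md <- mean(dd[ii])
    if (abs(md) < min_diff) return(NULL)
    data.frame(chrom = ch[ii[1]], start = po[ii[1]],
               end = po[ii[length(ii)]] + 2L, n_cpg = length(ii),
               mean_diff = md,
               direction = if (md > 0) "hyper" else "hypo",
               area_stat = sum(tt[ii]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Run the full DMR pipeline for one two-condition contrast
#'
#' Convenience wrapper: coverage filter, smoothing, t-statistics, region
#' construction.
#'
#' @param t a `methylome_table` (two conditions).
#' @param min_cov,min_reps coverage-filter parameters.
#' @param bandwidth,min_cpg_window smoothing parameters.
#' @param ... passed to [find_dmrs].
#' @return data.frame of DMRs.
#' @export
call_dmrs <- function(t, min_cov = 5, min_reps = 2,
                      bandwidth = 300, min_cpg_window = 5, ...) {
  tf <- coverage_filter(t, min_cov, min_reps)
  sm <- smooth_methylation(tf, bandwidth, min_cpg_window)
  st <- group_tstat(sm, tf$group)
  find_dmrs(st$tstat, tf$chrom, tf$pos, st$diff, ...)
}

#' Merge per-contrast DMR sets into a non-overlapping union
#'
#' Runs [find_dmrs] results from several pairwise contrasts through an
#' interval union; each union interval records which contrasts contributed.
#'
#' @param dmr_list named list of DMR data.frames (one per contrast).
#' @return data.frame of non-overlapping intervals with a `contrasts` column
#'   (comma-separated contributing contrast names) and `n_contrasts`.
#' @export
pairwise_dmr_sets <- function(dmr_list) {
  stopifnot(length(dmr_list) >= 2, !is.null(names(dmr_list)))
  nonempty <- dmr_list[vapply(dmr_list, nrow, 0L) > 0]
  if (length(nonempty) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), contrasts = character(0),
                      n_contrasts = integer(0)))
  }
  all_df <- do.call(rbind, lapply(names(nonempty), function(nm) {
    d <- nonempty[[nm]][, c("chrom", "start", "end")]
    d$contrast <- nm
    d
  }))
  gr <- intervals_to_granges(all_df)
  un <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(un, gr)
  tags <- vapply(seq_along(un), function(i) {
    paste(sort(unique(all_df$contrast[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]])), collapse = ",")
  }, character(1))
  out <- granges_to_intervals(un)
  out$contrasts <- tags
  out$n_contrasts <- lengths(strsplit(tags, ","))
  out
}

#' Assign DMRs to genes by proximity to transcription start sites
#'
#' A DMR is assigned to a gene when its midpoint lies within `window` bp of
#' that gene's TSS (symmetric up- and downstream); the nearest TSS wins ties.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`, ...).
#' @param genes annotation data.frame with `gene`, `chrom`, `tss`
#'   (0-based), `strand`.
#' @param window assignment window in bp (default 2000).
#' @return `dmrs` with added `annotated_gene` (NA outside every window) and
#'   `tss_distance`.
#' @export
annotate_promoter <- function(dmrs, genes, window = 2000) {
  stopifnot(all(c("gene", "chrom", "tss") %in% colnames(genes)))
  out <- dmrs
  out$annotated_gene <- NA_character_
  out$tss_distance <- NA_real_
  if (nrow(dmrs) == 0) return(out)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  for (i in seq_len(nrow(dmrs))) {
    same <- genes$chrom == dmrs$chrom[i]
    if (!any(same)) next
    d <- abs(genes$tss[same] - mid[i])
    j <- which.min(d)
    if (d[j] <= window) {
      out$annotated_gene[i] <- genes$gene[same][j]
      out$tss_distance[i] <- d[j]
    }
  }
  out
}
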