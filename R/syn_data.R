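## Seeded generators producing every input the pipeline consumes, each paired
## with a SimTruth record of what was planted. All generators are pure
## functions of their arguments including the seed.

#' @name syn_data
#' @title Synthetic multi-omics generators with planted ground truth
#' @description
#' Each `make_*` generator emulates one input type of the stromal-cell
#' pipeline on a single synthetic chromosome (`chrS`, 10 Mb by default) and
#' returns, alongside the dataset, a `sim_truth` list recording the planted
#' signal (DMR intervals with their methylation shift, differentially
#' accessible peaks with their true fold change, per-cell branch membership
#' and latent developmental time, subset marker sets, regulator-target
#' links). Downstream modules are benchmarked against these records.
NULL

sim_truth <- function(...) {
  structure(list(...), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth with fields:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a sim_truth record as JSON
#' @param truth a `sim_truth`.
#' @param path output file.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Simulate a clustered scRNA-seq dataset with a planted bifurcating trajectory
#'
#' Cells belong to a proliferating progenitor pool plus two post-bifurcation
#' branches. Genes are partitioned into housekeeping genes, subset markers,
#' a cell-cycle program (active in the progenitor pool) and
#' trajectory-dynamic genes whose log-mean increases monotonically with the
#' latent time `t` in [0, 1] (globally or per branch). Counts are negative
#' binomial with per-cell log-normal library-size factors. Marker and
#' branch effects scale as `2^branch_sep`, so `branch_sep = 0` removes all
#' subset structure.
#'
#' @param n_cells number of cells (>= 100).
#' @param n_genes number of genes (>= 200).
#' @param subset_props proportions for (progenitor, branchA, branchB);
#'   must sum to 1 within 1e-8. A single proportion of 1 collapses the
#'   dataset to one subset with no differential structure.
#' @param branch_sep effect size: subset markers and branch-dynamic genes are
#'   shifted by `2^branch_sep`-fold.
#' @param seed integer seed.
#' @param t_split latent time of the bifurcation (progenitor cells live in
#'   `[0, t_split)`, branch cells in `[t_split, 1]`).
#' @param dispersion negative-binomial dispersion (scRNA default 0.5).
#' @param mito_prefix prefix used to name mitochondrial genes.
#' @return list with elements `matrix` (a [count_matrix]) and `truth`
#'   (a `sim_truth` with `branch_of_cell`, `true_time`, `signature_genes`,
#'   `marker_a`/`marker_b` split markers and the cell-cycle gene sets).
#' @export
make_sc_dataset <- function(n_cells = 2000, n_genes = 1000,
                            subset_props = c(progenitor = 0.2,
                                             branchA = 0.4, branchB = 0.4),
                            branch_sep = 2, seed = 1,
                            t_split = 0.25, dispersion = 0.5,
                            mito_prefix = "mt-") {
  stopifnot(n_cells >= 100, n_genes >= 200)
  if (abs(sum(subset_props) - 1) > 1e-8) {
    stop("subset_props must sum to 1 within 1e-8")
  }
  set.seed(seed)

  one_subset <- length(subset_props) == 1
  if (!one_subset && length(subset_props) < 3) {
    stop("need at least 3 subsets (a proliferating progenitor plus branches)")
  }
  subset_names <- names(subset_props)
  if (is.null(subset_names)) {
    subset_names <- if (one_subset) "progenitor" else
      c("progenitor", "branchA", "branchB")[seq_along(subset_props)]
  }

  subset <- sample(subset_names, n_cells, replace = TRUE, prob = subset_props)
  tt <- numeric(n_cells)
  prog <- subset == subset_names[1]
  tt[prog] <- runif(sum(prog), 0, t_split)
  tt[!prog] <- runif(sum(!prog), t_split, 1)

  ## gene partition (proportional to the panel size; remainder housekeeping)
  n_mito <- 10
  n_ribo <- 20
  n_cc <- 40
  n_marker_per <- max(10, round(0.03 * n_genes))
  n_dyn_shared <- max(20, round(0.10 * n_genes))
  n_dyn_branch <- max(30, round(0.15 * n_genes))
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  gene_names[seq_len(n_mito)] <- paste0(mito_prefix, c(
    "Nd1", "Nd2", "Co1", "Co2", "Atp6", "Cytb", "Nd4", "Nd5", "Co3", "Atp8"))
  gene_names[n_mito + seq_len(n_ribo)] <-
    c(sprintf("Rps%d", 1:10), sprintf("Rpl%d", 1:10))
  idx_cc <- n_mito + n_ribo + seq_len(n_cc)
  gene_names[idx_cc] <- sprintf("Ccgene%02d", seq_len(n_cc))
  s_genes <- gene_names[idx_cc[1:20]]
  g2m_genes <- gene_names[idx_cc[21:40]]

  nxt <- n_mito + n_ribo + n_cc
  markers <- list()
  if (!one_subset) {
    for (s in subset_names) {
      markers[[s]] <- gene_names[nxt + seq_len(n_marker_per)]
      nxt <- nxt + n_marker_per
    }
  }
  idx_dyn_shared <- nxt + seq_len(n_dyn_shared); nxt <- nxt + n_dyn_shared
  idx_dyn_a <- nxt + seq_len(n_dyn_branch); nxt <- nxt + n_dyn_branch
  idx_dyn_b <- nxt + seq_len(n_dyn_branch); nxt <- nxt + n_dyn_branch
  stopifnot(nxt <= n_genes)

  base <- exp(rnorm(n_genes, log(2.0), 0.8))   # baseline mean per gene
  base[seq_len(n_mito)] <- exp(rnorm(n_mito, log(2), 0.3))
  base[n_mito + seq_len(n_ribo)] <- exp(rnorm(n_ribo, log(5), 0.3))
  ## developmental-program genes are well expressed at baseline
  base[c(idx_dyn_shared, idx_dyn_a, idx_dyn_b)] <-
    exp(rnorm(n_dyn_shared + 2 * n_dyn_branch, log(4), 0.5))
  if (!one_subset) {
    ## the designated split markers share a common baseline so that the
    ## higher-mean rule compares like with like (Vcam1/Cd34-style exclusivity)
    base[match(c(markers[["branchA"]][1], markers[["branchB"]][1]),
               gene_names)] <- 1
  }

  ## log2 fold shifts, cells x structure
  log2mu <- matrix(log2(base), n_genes, n_cells)
  fold <- branch_sep
  if (!one_subset) {
    for (s in subset_names) {
      rows <- match(markers[[s]], gene_names)
      log2mu[rows, subset == s] <- log2mu[rows, subset == s] + fold
    }
  }
  ## cell-cycle program: on in the proliferating progenitor pool
  cc_gain <- if (one_subset) 0 else 2
  log2mu[idx_cc, prog] <- log2mu[idx_cc, prog] + cc_gain
  ## dynamic genes: monotone in latent time, with gene-specific amplitudes
  ## (developmental programs swing 2-8-fold at the reference effect size 2)
  amp_shared <- (fold / 2) * runif(n_dyn_shared, 2, 4)
  amp_a <- (fold / 2) * runif(n_dyn_branch, 2, 4)
  amp_b <- (fold / 2) * runif(n_dyn_branch, 2, 4)
  log2mu[idx_dyn_shared, ] <- log2mu[idx_dyn_shared, ] + outer(amp_shared, tt)
  if (!one_subset) {
    on_a <- subset == "branchA"
    on_b <- subset == "branchB"
    ramp <- function(t) 0.3 + 0.7 * (t - t_split) / (1 - t_split)
    if (any(on_a)) {
      log2mu[idx_dyn_a, on_a] <- log2mu[idx_dyn_a, on_a] +
        outer(amp_a, ramp(tt[on_a]))
    }
    if (any(on_b)) {
      log2mu[idx_dyn_b, on_b] <- log2mu[idx_dyn_b, on_b] +
        outer(amp_b, ramp(tt[on_b]))
    }
  }

  libsize <- exp(rnorm(n_cells, 0, 0.3))
  mu <- 2^log2mu * rep(libsize, each = n_genes)
  counts <- matrix(
    rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
    n_genes, n_cells,
    dimnames = list(gene_names, sprintf("cell%04d", seq_len(n_cells)))
  )

  ## marker genes used by split_by_markers: the first marker of each branch
  marker_a <- if (one_subset) NA_character_ else markers[["branchA"]][1]
  marker_b <- if (one_subset) NA_character_ else markers[["branchB"]][1]

  timepoint <- cut(tt, breaks = c(-Inf, t_split, 0.5, 0.75, Inf),
                   labels = c("D0", "D10", "D24", "D56"))
  cm <- count_matrix(counts,
                     cell_meta = data.frame(
                       subset = subset,
                       timepoint = as.character(timepoint),
                       stringsAsFactors = FALSE))
  truth <- sim_truth(
    branch_of_cell = setNames(ifelse(prog, "root", subset), colnames(counts)),
    true_time = setNames(tt, colnames(counts)),
    signature_genes = markers,
    s_genes = s_genes, g2m_genes = g2m_genes,
    dynamic_genes = gene_names[c(idx_dyn_shared, idx_dyn_a, idx_dyn_b)],
    marker_a = marker_a, marker_b = marker_b,
    t_split = t_split
  )
  list(matrix = cm, truth = truth)
}

#' Simulate a two-condition methylome with planted DMRs
#'
#' Background CpGs share a beta-distributed methylation level between the
#' two conditions; inside each planted region the level of condition B is
#' shifted by `delta`, directed away from the nearer boundary of `[0, 1]`
#' (hypermethylated baselines lose methylation and vice versa) and clamped
#' (with a warning) if it would leave `(0, 1)`. Methylated counts are
#' binomial at Poisson-distributed coverage. Planted regions contain 4-8
#' CpGs spaced 40-140 bp apart.
#'
#' @param n_cpg total CpGs on the synthetic chromosome.
#' @param n_dmr number of planted DMRs (0 when `delta == 0`).
#' @param delta methylation difference (>= 0).
#' @param coverage_mean mean read coverage per CpG and sample.
#' @param reps_per_group replicates per condition.
#' @param seed integer seed.
#' @param chrom_len chromosome length in bp.
#' @return list with `table` (a `methylome_table`, see [methylome_table]) and
#'   `truth` (`sim_truth` with `dmr_intervals`: chrom/start/end/delta).
#' @export
make_methylome <- function(n_cpg = 50000, n_dmr = 50, delta = 0.4,
                           coverage_mean = 30, reps_per_group = 3, seed = 1,
                           chrom_len = 1e7) {
  stopifnot(delta >= 0, n_cpg >= 10, reps_per_group >= 1)
  set.seed(seed)
  if (delta == 0) n_dmr <- 0

  ## planted regions: CpG-island-like blocks of closely spaced CpGs
  n_in_dmr <- if (n_dmr > 0) sample(8:15, n_dmr, replace = TRUE) else integer(0)
  n_bg <- n_cpg - sum(n_in_dmr)
  stopifnot(n_bg > 0)
  pos_bg <- sort(sample.int(chrom_len - 1000L, n_bg))
  dmr_rows <- vector("list", n_dmr)
  pos_dmr <- integer(0)
  dmr_idx <- rep(0L, 0)
  if (n_dmr > 0) {
    anchors <- sort(sample(seq(5000L, chrom_len - 5000L, by = 10000L), n_dmr))
    for (i in seq_len(n_dmr)) {
      p <- anchors[i] + cumsum(c(0L, sample(30:80, n_in_dmr[i] - 1, replace = TRUE)))
      pos_dmr <- c(pos_dmr, p)
      dmr_idx <- c(dmr_idx, rep(i, n_in_dmr[i]))
    }
  }
  pos <- c(pos_bg, pos_dmr)
  in_dmr <- c(rep(0L, n_bg), dmr_idx)
  o <- order(pos)
  pos <- pos[o]; in_dmr <- in_dmr[o]
  keep <- !duplicated(pos)
  pos <- pos[keep]; in_dmr <- in_dmr[keep]
  n <- length(pos)

  ## baseline levels: bimodal genome background, mid-range inside DMRs
  p0 <- ifelse(runif(n) < 0.7, rbeta(n, 8, 2), rbeta(n, 1.5, 6))
  region_base <- rbeta(max(n_dmr, 1), 3, 3)
  sel <- in_dmr > 0
  if (any(sel)) {
    p0[sel] <- pmin(pmax(
      region_base[in_dmr[sel]] + rnorm(sum(sel), 0, 0.03), 0.05), 0.95)
  }
  ## direction: away from the nearer boundary
  dir_region <- ifelse(region_base > 0.5, -1, 1)
  pB <- p0
  if (any(sel)) {
    shifted <- p0[sel] + delta * dir_region[in_dmr[sel]]
    if (any(shifted < 0 | shifted > 1)) {
      warning("delta pushes methylation outside (0,1); clamping")
    }
    pB[sel] <- pmin(pmax(shifted, 0.01), 0.99)
  }

  k <- reps_per_group
  samples <- c(sprintf("A%d", seq_len(k)), sprintf("B%d", seq_len(k)))
  group <- setNames(rep(c("A", "B"), each = k), samples)
  Cov <- matrix(rpois(n * 2 * k, coverage_mean), n, 2 * k,
                dimnames = list(NULL, samples))
  P <- cbind(matrix(p0, n, k), matrix(pB, n, k))
  M <- matrix(rbinom(n * 2 * k, as.vector(Cov), as.vector(P)), n, 2 * k,
              dimnames = list(NULL, samples))

  dmr_tab <- if (n_dmr > 0) {
    do.call(rbind, lapply(seq_len(n_dmr), function(i) {
      p <- pos[in_dmr == i]
      data.frame(chrom = "chrS", start = min(p), end = max(p) + 2L,
                 delta = mean(pB[in_dmr == i] - p0[in_dmr == i]))
    }))
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               delta = numeric(0))
  }

  tab <- methylome_table(chrom = rep("chrS", n), pos = pos,
                         M = M, Cov = Cov, group = group)
  list(table = tab, truth = sim_truth(dmr_intervals = dmr_tab))
}

#' Simulate ATAC-seq peaks and counts with planted differential accessibility
#'
#' A master set of non-overlapping peaks on the synthetic chromosome receives
#' negative-binomial counts with sample-specific size factors; a random
#' subset is scaled by `fc` in one condition (half up in B, half up in A, so
#' both signs occur). Per-replicate peak lists are the master set with random
#' dropout and up-to-50-bp boundary jitter, for merge testing.
#'
#' @param n_peaks master peak count.
#' @param n_dar planted differential peaks (0 when `fc == 1`).
#' @param fc true fold change (>= 1).
#' @param reps replicates per condition.
#' @param seed integer seed.
#' @param mean_count mean accessibility count at baseline.
#' @param dispersion negative-binomial dispersion (bulk default 0.2).
#' @return list with `peaks` (master interval data.frame), `replicate_peaks`
#'   (list of jittered per-replicate data.frames), `counts` (a
#'   [count_matrix] over peaks with `condition` in `cell_meta`) and `truth`
#'   (`sim_truth` with `dar_ids` and `dar_fc`).
#' @export
make_atac <- function(n_peaks = 5000, n_dar = 250, fc = 4, reps = 3, seed = 1,
                      mean_count = 100, dispersion = 0.2) {
  stopifnot(fc >= 1, reps >= 1)
  set.seed(seed)
  if (fc == 1) n_dar <- 0

  gap <- floor(1e7 / n_peaks)
  start <- seq(0L, by = gap, length.out = n_peaks) +
    sample.int(max(gap - 900L, 1L), n_peaks, replace = TRUE)
  width <- sample(300:800, n_peaks, replace = TRUE)
  peaks <- data.frame(chrom = "chrS", start = start, end = start + width,
                      name = sprintf("peak%05d", seq_len(n_peaks)),
                      stringsAsFactors = FALSE)

  base_mu <- exp(rnorm(n_peaks, log(mean_count) - 0.5^2 / 2, 0.5))
  dar <- sample.int(n_peaks, n_dar)
  dir_up_b <- rep(c(TRUE, FALSE), length.out = max(n_dar, 1))
  samples <- c(sprintf("A%d", seq_len(reps)), sprintf("B%d", seq_len(reps)))
  cond <- rep(c("A", "B"), each = reps)
  sf <- exp(rnorm(2 * reps, 0, 0.2))
  mu <- matrix(base_mu, n_peaks, 2 * reps)
  if (n_dar > 0) {
    up_b <- dar[dir_up_b[seq_len(n_dar)]]
    up_a <- setdiff(dar, up_b)
    mu[up_b, cond == "B"] <- mu[up_b, cond == "B"] * fc
    mu[up_a, cond == "A"] <- mu[up_a, cond == "A"] * fc
  }
  mu <- mu * rep(sf, each = n_peaks)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_peaks, 2 * reps,
                   dimnames = list(peaks$name, samples))

  replicate_peaks <- lapply(seq_len(2 * reps), function(j) {
    keep <- runif(n_peaks) > 0.1
    jit_s <- sample(-50:50, sum(keep), replace = TRUE)
    jit_e <- sample(-50:50, sum(keep), replace = TRUE)
    df <- peaks[keep, , drop = FALSE]
    df$start <- pmax(df$start + jit_s, 0L)
    df$end <- pmax(df$end + jit_e, df$start + 50L)
    rownames(df) <- NULL
    df
  })
  names(replicate_peaks) <- samples

  truth <- sim_truth(
    dar_ids = peaks$name[sort(dar)],
    dar_fc = setNames(rep(fc, n_dar), peaks$name[sort(dar)])
  )
  cm <- count_matrix(counts,
                     cell_meta = data.frame(condition = cond,
                                            stringsAsFactors = FALSE))
  list(peaks = peaks, replicate_peaks = replicate_peaks,
       counts = cm, truth = truth)
}

#' Simulate a binary motif-hit table with planted enrichment
#'
#' Hits are Bernoulli with motif-specific baseline probabilities; within each
#' `(motif, gene set)` pair in `enriched_pairs` the odds of a hit are
#' multiplied by `odds`.
#'
#' @param n_motifs,n_genes table dimensions.
#' @param enriched_pairs list of `list(motif = "m", genes = c(...))` entries;
#'   motif may be given as index or name (`motif001` style).
#' @param odds enrichment odds ratio (>= 1).
#' @param seed integer seed.
#' @return list with `hits` (0/1 matrix motifs x genes) and `truth`
#'   (`sim_truth` with the enriched pairs).
#' @export
make_motif_hits <- function(n_motifs = 50, n_genes = 2000,
                            enriched_pairs = list(), odds = 1, seed = 1) {
  stopifnot(odds >= 1)
  set.seed(seed)
  motifs <- sprintf("motif%03d", seq_len(n_motifs))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  p0 <- runif(n_motifs, 0.05, 0.3)
  P <- matrix(p0, n_motifs, n_genes)
  rownames(P) <- motifs; colnames(P) <- genes
  for (pair in enriched_pairs) {
    m <- pair$motif
    if (is.numeric(m)) m <- motifs[m]
    g <- intersect(pair$genes, genes)
    p <- P[m, g]
    P[m, g] <- odds * p / (1 - p + odds * p)
  }
  hits <- matrix(as.integer(runif(length(P)) < P), n_motifs, n_genes,
                 dimnames = dimnames(P))
  list(hits = hits,
       truth = sim_truth(enriched_pairs = enriched_pairs, odds = odds))
}

#' Simulate bulk overexpression profiles contaminated with a subset signature
#'
#' Two arms (control vs overexpression) of negative-binomial counts; the
#' signature genes are up-shifted `2^strength`-fold in the overexpression
#' arm.
#'
#' @param signature character vector of signature genes (must be a subset of
#'   the generated gene universe, `gene0001...`).
#' @param strength log2 effect size (0 = no effect).
#' @param reps replicates per arm (>= 2).
#' @param seed integer seed.
#' @param n_genes gene-universe size.
#' @param dispersion negative-binomial dispersion.
#' @return list with `counts` (a [count_matrix]; `cell_meta$arm` is
#'   control/overexpr; `feature_meta$length` holds exon lengths for TPM) and
#'   `truth` (`sim_truth` with `signature_genes`).
#' @export
make_overexpression_bulk <- function(signature, strength = 3, reps = 3,
                                     seed = 1, n_genes = 2000,
                                     dispersion = 0.2) {
  stopifnot(reps >= 2)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  signature <- intersect(signature, genes)
  base <- exp(rnorm(n_genes, log(100) - 0.5^2 / 2, 0.5))
  samples <- c(sprintf("ctrl%d", seq_len(reps)), sprintf("oe%d", seq_len(reps)))
  arm <- rep(c("control", "overexpr"), each = reps)
  mu <- matrix(base, n_genes, 2 * reps)
  mu[match(signature, genes), arm == "overexpr"] <-
    mu[match(signature, genes), arm == "overexpr"] * 2^strength
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2 * reps, dimnames = list(genes, samples))
  cm <- count_matrix(counts,
                     feature_meta = data.frame(
                       row.names = genes,
                       length = sample(500:5000, n_genes, replace = TRUE),
                       biotype = "protein_coding"),
                     cell_meta = data.frame(arm = arm,
                                            stringsAsFactors = FALSE))
  list(counts = cm, truth = sim_truth(signature_genes = signature,
                                      strength = strength))
}

#' Simulate a pseudotemporal expression series driven by planted regulators
#'
#' Transcription-factor expressions follow smooth random curves (sums of
#' sinusoids); each target integrates a linear response to its single driving
#' TF with first-order decay, `x(t+1) = x(t) + w * x_tf(t) - alpha * x(t)`,
#' in per-bin time units (one step per pseudotime bin), plus Gaussian
#' observation noise. This is the planted ground truth for dynamical network
#' inference.
#'
#' @param n_tf,n_target numbers of regulators and targets.
#' @param alpha decay rate per bin.
#' @param noise_sd observation noise.
#' @param n_time number of time points (bins).
#' @param seed integer seed.
#' @return list with `ts` (gene x time matrix; TFs first), `tfs` (names) and
#'   `truth` (`sim_truth` with `regulator_links` data.frame).
#' @export
make_grn_timeseries <- function(n_tf = 5, n_target = 15, alpha = 0.3,
                                noise_sd = 0.05, n_time = 50, seed = 1) {
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  targets <- sprintf("G%02d", seq_len(n_target))
  tgrid <- seq(0, 1, length.out = n_time)
  tf_x <- t(sapply(seq_len(n_tf), function(i) {
    a <- rnorm(3); ph <- runif(3, 0, 2 * pi); fr <- sample(1:3, 3)
    y <- rowSums(sapply(1:3, function(k) a[k] * sin(2 * pi * fr[k] * tgrid + ph[k])))
    (y - min(y)) / (max(y) - min(y) + 1e-9) + 0.2
  }))
  rownames(tf_x) <- tfs
  driver <- sample(seq_len(n_tf), n_target, replace = TRUE)
  w <- runif(n_target, 0.3, 0.6) * sample(c(-1, 1), n_target, replace = TRUE)
  tgt_x <- matrix(0, n_target, n_time)
  tgt_x[, 1] <- runif(n_target, 0.2, 1)
  for (j in seq_len(n_time - 1)) {
    tgt_x[, j + 1] <- tgt_x[, j] + w * tf_x[driver, j] - alpha * tgt_x[, j]
  }
  rownames(tgt_x) <- targets
  ts <- rbind(tf_x, tgt_x) +
    matrix(rnorm((n_tf + n_target) * n_time, 0, noise_sd),
           n_tf + n_target, n_time)
  colnames(ts) <- sprintf("t%03d", seq_len(n_time))
  links <- data.frame(regulator = tfs[driver], target = targets,
                      weight = abs(w), stringsAsFactors = FALSE)
  list(ts = ts, tfs = tfs,
       truth = sim_truth(regulator_links = links, alpha = alpha))
}
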