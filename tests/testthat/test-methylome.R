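make_toy_meth <- function(pos, M, Cov, group = c(A1 = "A", A2 = "A",
                                                 B1 = "B", B2 = "B")) {
  methylome_table(rep("chrS", length(pos)), pos, M, Cov, group)
}

test_that("methylome container enforces its invariants", {
  expect_error(make_toy_meth(c(10, 5), matrix(0, 2, 4), matrix(1, 2, 4)),
               "strictly increasing")
  expect_error(make_toy_meth(c(5, 10), matrix(2, 2, 4), matrix(1, 2, 4)))
})

test_that("coverage filter keeps CpGs qualifying in at least one condition", {
  Cov <- rbind(c(5, 5, 0, 0),   # condition A qualifies
               c(4, 4, 4, 4),   # nobody reaches 5
               c(0, 5, 5, 5),   # condition B qualifies
               c(5, 0, 5, 0))   # one replicate each, no condition qualifies
  M <- matrix(0, 4, 4)
  t <- make_toy_meth(c(10, 20, 30, 40), M, Cov)
  kept <- coverage_filter(t, min_cov = 5, min_reps = 2)
  expect_identical(kept$pos, c(10L, 30L))
  ## min_cov = 0 is the identity
  expect_identical(coverage_filter(t, 0, 2)$pos, t$pos)
})

test_that("smoothing reproduces constants, isolated CpGs, and a WLS oracle", {
  ## constant methylation level is invariant under smoothing
  n <- 50
  pos <- sort(sample.int(10000, n))
  Cov <- matrix(10L, n, 4, dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  M <- matrix(7L, n, 4, dimnames = dimnames(Cov))
  t <- make_toy_meth(pos, M, Cov)
  sm <- smooth_methylation(t)
  expect_equal(unname(sm), matrix(0.7, n, 4), tolerance = 1e-12)

  ## a chromosome with a single CpG falls back to its raw ratio
  t1 <- methylome_table(c(rep("chrS", n), "chrT"), c(pos, 5),
                        rbind(M, 3L), rbind(Cov, 10L),
                        c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_warning(sm1 <- smooth_methylation(t1), "fewer than")
  expect_equal(unname(sm1[n + 1, ]), rep(0.3, 4))

  ## random data: smoothed value matches a direct weighted-least-squares fit
  set.seed(13)
  n <- 400
  pos <- sort(sample.int(120000, n))
  Cov <- matrix(rpois(n * 4, 20), n, 4, dimnames = list(NULL, colnames(M)))
  Mr <- matrix(rbinom(n * 4, as.vector(Cov), 0.5), n, 4,
               dimnames = dimnames(Cov))
  t2 <- make_toy_meth(pos, Mr, Cov)
  bw <- 300; ncw <- 5
  sm2 <- smooth_methylation(t2, bandwidth = bw, min_cpg_window = ncw)
  wls_oracle <- function(i, s) {
    ratio <- Mr[, s] / Cov[, s]
    half <- bw / 2
    lo <- i; hi <- i
    while (hi - lo + 1 < ncw && (lo > 1 || hi < n)) {
      dlo <- if (lo > 1) pos[i] - pos[lo - 1] else Inf
      dhi <- if (hi < n) pos[hi + 1] - pos[i] else Inf
      if (dlo <= dhi) lo <- lo - 1 else hi <- hi + 1
    }
    half <- max(half, pos[i] - pos[lo], pos[hi] - pos[i])
    lo <- min(which(pos >= pos[i] - half))
    hi <- max(which(pos <= pos[i] + half))
    idx <- lo:hi
    d <- abs(pos[idx] - pos[i]) / (half + 1e-9)
    w <- pmax(1 - d^3, 0)^3 * Cov[idx, s]
    X <- cbind(1, pos[idx] - pos[i])
    fit <- lm.wfit(X, ratio[idx], w)
    min(max(fit$coefficients[1], 0), 1)
  }
  for (i in sample.int(n, 20)) {
    expect_equal(unname(sm2[i, "A1"]), unname(wls_oracle(i, "A1")),
                 tolerance = 1e-8)
    expect_equal(unname(sm2[i, "B2"]), unname(wls_oracle(i, "B2")),
                 tolerance = 1e-8)
  }
})

test_that("group t-statistic matches the closed form and is antisymmetric", {
  h <- 0.1 / sqrt(2)
  sm <- cbind(A1 = c(0.8 + h, 0.5), A2 = c(0.8 - h, 0.5),
              B1 = c(0.3 + h, 0.5), B2 = c(0.3 - h, 0.5))
  groups <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  st <- group_tstat(sm, groups)
  ## pooled sd is 0.1 at CpG 1; the floor (75th pct) does not exceed it
  expect_equal(unname(st$tstat[1]), 5, tolerance = 1e-12)
  ## equal group means give t = 0
  expect_equal(unname(st$tstat[2]), 0)
  ## swapping the groups negates every t
  swapped <- group_tstat(sm, setNames(c("B", "B", "A", "A"), names(groups)))
  expect_equal(swapped$tstat, -st$tstat)
  ## single-replicate groups are refused
  expect_error(group_tstat(sm[, 1:3], groups[1:3]), "variance-floor")
})

test_that("DMR construction enumerates maximal qualifying runs", {
  pos <- c(0L, 100L, 250L, 600L, 650L, 700L)
  tt <- c(5, 5, 5, 0, 0, 0)
  dd <- c(0.3, 0.3, 0.3, 0, 0, 0)
  d <- find_dmrs(tt, rep("chrS", 6), pos, dd, cutoffs = c(-3, 3))
  expect_identical(nrow(d), 1L)
  expect_identical(d$start, 0L)
  expect_identical(d$end, 252L)
  expect_identical(d$n_cpg, 3L)
  expect_equal(d$mean_diff, 0.3)
  expect_identical(d$direction, "hyper")
  expect_equal(d$area_stat, 15)

  ## two qualifying CpGs are not enough
  d2 <- find_dmrs(c(5, 5, 0, 0, 0, 0), rep("chrS", 6), pos,
                  c(0.3, 0.3, 0, 0, 0, 0), cutoffs = c(-3, 3))
  expect_identical(nrow(d2), 0L)

  ## a sign change breaks a run
  d3 <- find_dmrs(c(5, -5, 5, 5, 5, 5), rep("chrS", 6), pos,
                  c(0.3, -0.3, 0.3, 0.3, 0.3, 0.3), cutoffs = c(-3, 3))
  expect_true(all(d3$n_cpg < 4))

  ## a gap beyond max_gap breaks a run: 250 -> 600 is 350 bp apart
  d4 <- find_dmrs(rep(5, 6), rep("chrS", 6), pos, rep(0.3, 6),
                  cutoffs = c(-3, 3))
  expect_identical(nrow(d4), 2L)
  expect_identical(d4$end, c(252L, 702L))

  ## sub-threshold mean difference is rejected
  d5 <- find_dmrs(tt, rep("chrS", 6), pos, dd * 0.5, cutoffs = c(-3, 3))
  expect_identical(nrow(d5), 0L)

  ## tiny genomes refuse quantile estimation without explicit cutoffs
  expect_error(find_dmrs(tt, rep("chrS", 6), pos, dd), "100 CpGs")
})

test_that("called DMRs satisfy all four criteria and flip with group labels", {
  sim <- make_methylome(n_cpg = 8000, n_dmr = 10, delta = 0.4, seed = 17)
  tab <- coverage_filter(sim$table)
  sm <- smooth_methylation(tab)
  st <- group_tstat(sm, tab$group)
  cuts <- quantile(st$tstat, c(0.01, 0.99), names = FALSE)
  dmrs <- find_dmrs(st$tstat, tab$chrom, tab$pos, st$diff)
  expect_gt(nrow(dmrs), 0)

  ## per-region: >= 3 CpGs, gaps <= 300, |mean diff| >= 0.25, all t beyond cutoffs
  for (i in seq_len(nrow(dmrs))) {
    idx <- which(tab$pos >= dmrs$start[i] & tab$pos <= dmrs$end[i] - 2L)
    member <- idx[st$tstat[idx] < cuts[1] | st$tstat[idx] > cuts[2]]
    expect_gte(length(member), 3)
    expect_true(all(diff(tab$pos[member]) <= 300))
    expect_gte(abs(dmrs$mean_diff[i]), 0.25)
  }
  ## non-overlapping within the contrast
  if (nrow(dmrs) > 1) {
    o <- order(dmrs$start)
    expect_true(all(dmrs$start[o][-1] >= dmrs$end[o][-nrow(dmrs)]))
  }

  ## swapping condition labels mirrors every region with flipped direction
  grp2 <- setNames(ifelse(tab$group == "A", "B", "A"), names(tab$group))
  ## keep level order stable by renaming to comparable labels
  st2 <- group_tstat(sm, grp2)
  expect_equal(st2$tstat, -st$tstat)
  dmrs2 <- find_dmrs(st2$tstat, tab$chrom, tab$pos, st2$diff)
  expect_equal(dmrs2$start, dmrs$start)
  expect_equal(dmrs2$end, dmrs$end)
  expect_true(all(dmrs2$direction != dmrs$direction))
})

test_that("per-contrast DMR sets merge into a tagged non-overlapping union", {
  d1 <- data.frame(chrom = "chrS", start = c(0L, 1000L), end = c(100L, 1100L))
  d2 <- data.frame(chrom = "chrS", start = 5000L, end = 5100L)
  un <- pairwise_dmr_sets(list(c1 = d1, c2 = d2))
  expect_identical(nrow(un), 3L)
  expect_setequal(un$contrasts, c("c1", "c2"))

  ## an identical region in two contrasts is counted once with both tags
  un2 <- pairwise_dmr_sets(list(c1 = d1, c2 = d1[1, ]))
  expect_identical(nrow(un2), 2L)
  expect_identical(un2$contrasts[un2$start == 0], "c1,c2")
  expect_identical(un2$n_contrasts[un2$start == 0], 2L)

  ## random overlaps match the per-base sweep oracle
  set.seed(19)
  mk <- function() {
    s <- sort(sample.int(9000, 8))
    data.frame(chrom = "chrS", start = s, end = s + sample(50:400, 8, TRUE))
  }
  sets <- list(a = mk(), b = mk(), c = mk())
  un3 <- pairwise_dmr_sets(sets)
  oracle <- brute_union(do.call(rbind, sets)[, c("start", "end")])
  expect_equal(un3$start, oracle$start)
  expect_equal(un3$end, oracle$end)
})

test_that("promoter annotation assigns the nearest TSS within the window", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chrS",
                      tss = c(5000L, 9000L), strand = c("+", "-"))
  dmrs <- data.frame(chrom = "chrS",
                     start = c(4950L, 7100L, 200L),
                     end = c(5050L, 7140L, 300L))
  ann <- annotate_promoter(dmrs, genes, window = 2000)
  expect_identical(ann$annotated_gene, c("g1", "g2", NA_character_))

  ## boundary: midpoint exactly window + 1 away stays unassigned
  d2 <- data.frame(chrom = "chrS", start = 6998L, end = 7000L)  # mid 6999
  expect_identical(annotate_promoter(d2, genes, window = 2000)$annotated_gene,
                   "g1")
  d3 <- data.frame(chrom = "chrS", start = 7002L, end = 7004L)  # mid 7003: 2003 from g1, 1997 from g2
  expect_identical(annotate_promoter(d3, genes, window = 1996)$annotated_gene,
                   NA_character_)

  ## random set against a brute-force nearest scan
  set.seed(23)
  g <- data.frame(gene = sprintf("g%02d", 1:30), chrom = "chrS",
                  tss = sort(sample.int(1e6, 30)), strand = "+")
  d <- data.frame(chrom = "chrS", start = sort(sample.int(1e6, 50)))
  d$end <- d$start + 100L
  ann2 <- annotate_promoter(d, g, window = 2000)
  mid <- floor((d$start + d$end) / 2)
  for (i in seq_len(nrow(d))) {
    dist <- abs(g$tss - mid[i])
    exp_gene <- if (min(dist) <= 2000) g$gene[which.min(dist)] else NA_character_
    expect_identical(ann2$annotated_gene[i], exp_gene)
  }
})

test_that("the null methylome yields no DMRs", {
  clean <- vapply(1:5, function(s) {
    ns <- make_methylome(n_cpg = 20000, n_dmr = 0, delta = 0, seed = 100 + s)
    nrow(call_dmrs(ns$table)) == 0
  }, logical(1))
  expect_true(all(clean))
})

test_that("planted DMR recall grows with effect size and coverage", {
  rec <- vapply(c(0.15, 0.45), function(delta) {
    ## high deltas may clamp at the methylation boundary, by design
    sim <- suppressWarnings(
      make_methylome(n_cpg = 15000, n_dmr = 20, delta = delta,
                     coverage_mean = 30, seed = 41))
    interval_recall(call_dmrs(sim$table), sim$truth$dmr_intervals)
  }, numeric(1))
  expect_gte(rec[2], rec[1])
  rec_cov <- vapply(c(5, 40), function(cov) {
    sim <- make_methylome(n_cpg = 15000, n_dmr = 20, delta = 0.3,
                          coverage_mean = cov, seed = 43)
    interval_recall(call_dmrs(sim$table), sim$truth$dmr_intervals)
  }, numeric(1))
  expect_gte(rec_cov[2], rec_cov[1])
})
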