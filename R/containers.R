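#' Feature-by-cell (or feature-by-sample) count container
#'
#' The universal container for expression and accessibility counts: an integer
#' matrix with features as rows and cells/samples as columns, plus per-feature
#' and per-cell metadata tables keyed one-to-one to the matrix axes.
#'
#' On construction, per-cell QC covariates are derived from the raw counts:
#' `n_umi` (column sums), `n_genes_detected` (features with count > 0),
#' `pct_mito` and `pct_ribo` (percent of counts on features whose name matches
#' the mitochondrial / ribosomal prefix patterns).
#'
#' @param counts integer matrix, features x cells; must have rownames and
#'   colnames.
#' @param feature_meta data.frame of per-feature annotation (optional columns
#'   `chrom`, `tss`, `strand`, `biotype`, `length`); rownames or a `name`
#'   column must match `rownames(counts)`.
#' @param cell_meta data.frame of per-cell annotation (e.g. `library`,
#'   `timepoint`, `condition`); rownames must match `colnames(counts)`.
#' @param mito_pattern,ribo_pattern regular expressions identifying
#'   mitochondrial and ribosomal genes (mouse defaults).
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `feature_meta`, `cell_meta`.
#' @export
count_matrix <- function(counts, feature_meta = NULL, cell_meta = NULL,
                         mito_pattern = "^mt-", ribo_pattern = "^Rp[sl]") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")

  if (is.null(feature_meta)) {
    feature_meta <- data.frame(row.names = rownames(counts))
  }
  feature_meta <- as.data.frame(feature_meta)
  if (!is.null(feature_meta$name) && is.null(rownames(feature_meta))) {
    rownames(feature_meta) <- feature_meta$name
  }
  if (!identical(rownames(feature_meta), rownames(counts))) {
    feature_meta <- feature_meta[rownames(counts), , drop = FALSE]
    rownames(feature_meta) <- rownames(counts)
  }

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(counts))
  }
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta must have one row per cell")
  }
  rownames(cell_meta) <- colnames(counts)

  mito <- grepl(mito_pattern, rownames(counts))
  ribo <- grepl(ribo_pattern, rownames(counts))
  tot <- colSums(counts)
  cell_meta$n_umi <- as.integer(tot)
  cell_meta$n_genes_detected <- as.integer(colSums(counts > 0))
  cell_meta$pct_mito <- ifelse(tot > 0, 100 * colSums(counts[mito, , drop = FALSE]) / tot, 0)
  cell_meta$pct_ribo <- ifelse(tot > 0, 100 * colSums(counts[ribo, , drop = FALSE]) / tot, 0)

  structure(list(counts = counts, feature_meta = feature_meta,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d cells/samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$cell_meta) > 0) {
    cat("  cell_meta columns:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count_matrix by features and/or cells
#'
#' QC covariates (`n_umi`, `n_genes_detected`, `pct_mito`, `pct_ribo`) are
#' carried over unchanged, so they keep referring to the original library.
#'
#' @param m a `count_matrix`.
#' @param features,cells index vectors (logical, integer or names); `NULL`
#'   keeps all.
#' @return a `count_matrix`.
#' @export
subset_counts <- function(m, features = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(features)) features <- seq_len(nrow(m$counts))
  if (is.null(cells)) cells <- seq_len(ncol(m$counts))
  out <- m
  out$counts <- m$counts[features, cells, drop = FALSE]
  out$feature_meta <- m$feature_meta[features, , drop = FALSE]
  out$cell_meta <- m$cell_meta[cells, , drop = FALSE]
  out
}

## ---- genomic intervals -----------------------------------------------------

#' Convert a 0-based half-open interval table to GRanges
#'
#' Intervals throughout the package follow BED convention (0-based start,
#' half-open end); Bioconductor ranges are 1-based closed, so start shifts by
#' one on the way in and back on the way out.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return a `GRanges`.
#' @export
intervals_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  strand <- if ("strand" %in% colnames(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if ("name" %in% colnames(df)) gr$name <- df$name
  if ("score" %in% colnames(df)) gr$score <- df$score
  gr
}

#' @rdname intervals_to_granges
#' @param gr a `GRanges`.
#' @export
granges_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc) > 0) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

## ---- simple text IO --------------------------------------------------------

#' Read / write interval tables as BED
#'
#' Minimal BED6 writer/reader for peaks, blacklists and DMRs (plain text,
#' 0-based half-open, tab separated, no header).
#'
#' @param df interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% colnames(df)) df$name else ".",
    score = if ("score" %in% colnames(df)) df$score else 0,
    strand = if ("strand" %in% colnames(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  colnames(df) <- cols[seq_len(ncol(df))]
  df
}

#' Write a count_matrix as MTX + features/barcodes TSV (10x-style triplet)
#'
#' @param m a `count_matrix`.
#' @param dir output directory (created if absent).
#' @export
write_counts_mtx <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- Matrix::Matrix(m$counts, sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  if (ncol(m$cell_meta) > 0) {
    write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  sp <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- as.matrix(sp)
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cm <- NULL
  meta_path <- file.path(dir, "cell_meta.tsv")
  if (file.exists(meta_path)) {
    cm <- read.delim(meta_path, row.names = 1, stringsAsFactors = FALSE)
    cm <- cm[, setdiff(colnames(cm),
                       c("n_umi", "n_genes_detected", "pct_mito", "pct_ribo")),
             drop = FALSE]
  }
  count_matrix(counts, cell_meta = cm)
}
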