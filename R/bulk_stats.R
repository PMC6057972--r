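#' Counts per million for bulk samples
#'
#' @param bulk a [bulk_counts].
#' @return genes x samples matrix; each column sums to 1e6.
#' @export
cpm_matrix <- function(bulk) {
  stopifnot(inherits(bulk, "bulk_counts"))
  totals <- colSums(bulk$counts)
  if (any(totals <= 0)) stop("zero-total sample")
  sweep(bulk$counts, 2, totals, `/`) * 1e6
}

#' Expressed-gene filter on CPM
#'
#' Keeps genes whose CPM strictly exceeds `cpm_min` in at least
#' `min_samples` samples (a gene at CPM exactly 1 everywhere is dropped).
#'
#' @param bulk a [bulk_counts].
#' @param cpm_min CPM threshold (default 1, strict).
#' @param min_samples samples required above threshold (default 2).
#' @return character vector of retained gene names.
#' @export
filter_expressed <- function(bulk, cpm_min = 1, min_samples = 2) {
  stopifnot(inherits(bulk, "bulk_counts"), ncol(bulk$counts) >= min_samples)
  cpm <- cpm_matrix(bulk)
  keep <- rowSums(cpm > cpm_min) >= min_samples
  rownames(bulk$counts)[keep]
}

#' Reads per kilobase per million
#'
#' `RPKM = count * 1e9 / (sample_total * gene_length)`.
#'
#' @param bulk a [bulk_counts] with gene lengths.
#' @return genes x samples RPKM matrix.
#' @export
rpkm_matrix <- function(bulk) {
  stopifnot(inherits(bulk, "bulk_counts"))
  if (is.null(bulk$gene_length)) stop("gene lengths required for RPKM")
  totals <- colSums(bulk$counts)
  if (any(totals <= 0)) stop("zero-total sample")
  sweep(bulk$counts, 2, totals, `/`) * 1e9 / bulk$gene_length
}

#' Pairwise sample concordance on log RPKM
#'
#' Coefficient of determination (squared Pearson correlation) for every
#' pair of samples on `log2(RPKM + pseudocount)` over the expressed gene
#' subset. RPKM is depth-invariant, so a sample and a uniformly
#' depth-scaled copy of it give R-squared 1. The log base cancels in the
#' correlation; the pseudocount (default 1) keeps zero counts finite.
#'
#' @param bulk a [bulk_counts] with gene lengths.
#' @param genes expressed gene subset (e.g. from [filter_expressed]);
#'   needs >= 2 genes.
#' @param pseudocount added before the log (default 1).
#' @return symmetric samples x samples matrix with unit diagonal.
#' @export
rpkm_r2 <- function(bulk, genes = rownames(bulk$counts), pseudocount = 1) {
  if (length(genes) < 2) stop("need at least 2 expressed genes")
  lr <- log2(rpkm_matrix(bulk)[genes, , drop = FALSE] + pseudocount)
  r2 <- stats::cor(lr)^2
  diag(r2) <- 1
  r2
}

#' Threshold filter on an externally supplied DE table
#'
#' Partitions a differential-expression table into up- and down-regulated
#' gene lists using strict cutoffs: `FDR < fdr_max` and
#' `logFC > abs_logfc_min` (up) or `logFC < -abs_logfc_min` (down).
#' A gene at exactly the logFC cutoff is excluded. The two lists are
#' disjoint by construction.
#'
#' @param de data.frame with columns `gene`, `logFC` (log2), `FDR`.
#' @param fdr_max FDR cutoff (default 0.01).
#' @param abs_logfc_min absolute logFC cutoff (default 1.5).
#' @return list with `up` and `down` character vectors.
#' @export
deg_filter <- function(de, fdr_max = 0.01, abs_logfc_min = 1.5) {
  stopifnot(all(c("gene", "logFC", "FDR") %in% names(de)),
            all(de$FDR >= 0 & de$FDR <= 1))
  sig <- de$FDR < fdr_max
  list(up = de$gene[sig & de$logFC > abs_logfc_min],
       down = de$gene[sig & de$logFC < -abs_logfc_min])
}
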