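#' Sparse single-cell UMI count container
#'
#' Bundles a genes x cells sparse UMI matrix with per-cell metadata
#' (condition, optional sample of origin) and per-gene metadata
#' (mitochondrial flag). Genes are rows and cells are columns throughout
#' the package, matching the 10x triplet convention.
#'
#' @param counts a genes x cells matrix coercible to `dgCMatrix`; entries
#'   must be non-negative integers (UMI counts). Duplicate triplets are
#'   summed during coercion.
#' @param condition character vector of per-cell condition labels
#'   (e.g. `"CTRL"`, `"ALL"`, `"IFN+ALL"`), length `ncol(counts)`.
#' @param sample optional character vector of per-cell sample labels.
#' @param mito optional logical per-gene mitochondrial flag; if `NULL`,
#'   derived from `mito_prefix` on the rownames.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @return an object of class `sparse_counts`: a list with elements
#'   `counts` (dgCMatrix), `cell_meta` (data.frame: barcode, condition,
#'   sample) and `gene_meta` (data.frame: gene, mito).
#' @export
sparse_counts <- function(counts, condition = NULL, sample = NULL,
                          mito = NULL, mito_prefix = "mt-") {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  }
  v <- counts@x
  if (any(v < 0)) stop("UMI counts must be non-negative")
  if (any(abs(v - round(v)) > 1e-8)) stop("UMI counts must be integral")
  if (is.null(condition)) condition <- rep("unknown", ncol(counts))
  condition <- rep_len(as.character(condition), ncol(counts))
  if (is.null(sample)) sample <- condition
  sample <- rep_len(as.character(sample), ncol(counts))
  if (is.null(mito)) {
    mito <- startsWith(rownames(counts), mito_prefix)
  }
  stopifnot(length(mito) == nrow(counts))
  structure(list(
    counts = counts,
    cell_meta = data.frame(barcode = colnames(counts), condition = condition,
                           sample = sample, stringsAsFactors = FALSE),
    gene_meta = data.frame(gene = rownames(counts), mito = mito,
                           stringsAsFactors = FALSE)
  ), class = "sparse_counts")
}

#' @method print sparse_counts
#' @export
print.sparse_counts <- function(x, ...) {
  cat(sprintf("sparse_counts: %d genes x %d cells (%d non-zero, %d mito genes)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              sum(x$gene_meta$mito)))
  cat("conditions:", paste(names(table(x$cell_meta$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a sparse_counts object by genes and/or cells
#' @param x a `sparse_counts` object
#' @param genes,cells index vectors (logical, integer or names); `NULL` keeps all
#' @return a `sparse_counts` restricted to the selection
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "sparse_counts"))
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  m <- x$counts[genes, cells, drop = FALSE]
  gi <- match(rownames(m), x$gene_meta$gene)
  ci <- match(colnames(m), x$cell_meta$barcode)
  structure(list(counts = m,
                 cell_meta = x$cell_meta[ci, , drop = FALSE],
                 gene_meta = x$gene_meta[gi, , drop = FALSE]),
            class = "sparse_counts")
}

#' Bulk RNA-seq count container
#'
#' @param counts genes x samples matrix of non-negative integer read counts.
#' @param gene_length per-gene transcript length in bases (for RPKM);
#'   must be positive.
#' @param condition per-sample condition labels.
#' @return object of class `bulk_counts`.
#' @export
bulk_counts <- function(counts, gene_length = NULL, condition = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("bulk counts must be non-negative")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
  }
  if (!is.null(gene_length)) {
    gene_length <- rep_len(as.numeric(gene_length), nrow(counts))
    if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  }
  if (is.null(condition)) condition <- colnames(counts)
  condition <- rep_len(as.character(condition), ncol(counts))
  structure(list(counts = counts, gene_length = gene_length,
                 condition = condition),
            class = "bulk_counts")
}

#' @method print bulk_counts
#' @export
print.bulk_counts <- function(x, ...) {
  cat(sprintf("bulk_counts: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' TCR-beta repertoire sample
#'
#' One sequenced repertoire: unique CDR templates (amino-acid level) with
#' their read/template counts. Duplicate template rows are summed.
#'
#' @param template character vector of CDR amino-acid sequences.
#' @param count non-negative counts (raw templates or cpm), same length.
#' @param sample_id,mouse_id,timepoint identifying labels; timepoint is an
#'   ordinal label such as `"T0"`, `"T1"`, `"T2"`.
#' @return a `repertoire_table`: data.frame with columns `template`, `count`
#'   and attributes `sample_id`, `mouse_id`, `timepoint`.
#' @export
repertoire_table <- function(template, count, sample_id = "sample",
                             mouse_id = "mouse", timepoint = "T0") {
  if (length(template) != length(count)) stop("template/count length mismatch")
  if (length(template) == 0) stop("repertoire table must have at least one row")
  count <- as.numeric(count)
  if (any(is.na(count)) || any(count < 0)) {
    stop("counts must be non-negative numbers")
  }
  agg <- rowsum(count, group = as.character(template))
  out <- data.frame(template = rownames(agg), count = agg[, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (sum(out$count) <= 0) stop("repertoire table needs at least one count > 0")
  attr(out, "sample_id") <- sample_id
  attr(out, "mouse_id") <- mouse_id
  attr(out, "timepoint") <- timepoint
  class(out) <- c("repertoire_table", "data.frame")
  out
}

rep_attr <- function(x, which) attr(x, which, exact = TRUE)

#' @method print repertoire_table
#' @export
print.repertoire_table <- function(x, ...) {
  cat(sprintf("repertoire_table %s (mouse %s, %s): %d templates, total %.0f\n",
              rep_attr(x, "sample_id"), rep_attr(x, "mouse_id"),
              rep_attr(x, "timepoint"), nrow(x), sum(x$count)))
  invisible(x)
}
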