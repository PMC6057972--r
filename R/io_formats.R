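#' Read a 10x-style MatrixMarket triplet matrix
#'
#' Loads a sparse genes x cells UMI matrix from a MatrixMarket coordinate
#' file plus one-entry-per-line gene and barcode files, with an optional
#' metadata table mapping barcodes to condition (and sample) labels.
#' Duplicate (gene, cell) triplets are summed on load, so the result is
#' independent of triplet order.
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param genes_path path to the gene list (first column used).
#' @param barcodes_path path to the barcode list (first column used).
#' @param metadata_path optional TSV with header columns `barcode`,
#'   `condition` and optionally `sample`. Barcodes missing from the table
#'   are labelled `"unknown"` with a warning.
#' @param mito_prefix gene-symbol prefix flagging mitochondrial genes
#'   (default `"mt-"`, the mouse convention).
#' @return a [sparse_counts] object.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path,
                             metadata_path = NULL, mito_prefix = "mt-") {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes)) {
    stop(sprintf("matrix header declares %d genes but gene file lists %d",
                 nrow(m), length(genes)))
  }
  if (ncol(m) != length(barcodes)) {
    stop(sprintf("matrix header declares %d cells but barcode file lists %d",
                 ncol(m), length(barcodes)))
  }
  dimnames(m) <- list(genes, barcodes)
  condition <- rep("unknown", length(barcodes))
  sample <- NULL
  if (!is.null(metadata_path)) {
    meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    idx <- match(barcodes, meta$barcode)
    if (anyNA(idx)) {
      warning(sprintf("%d barcode(s) missing from metadata; labelled 'unknown'",
                      sum(is.na(idx))))
    }
    condition <- ifelse(is.na(idx), "unknown", meta$condition[idx])
    if ("sample" %in% names(meta)) {
      sample <- ifelse(is.na(idx), "unknown", meta$sample[idx])
    }
  }
  sparse_counts(m, condition = condition, sample = sample,
                mito_prefix = mito_prefix)
}

#' Write a sparse_counts object as MatrixMarket triplet files
#'
#' Inverse of [read_mtx_triplet]; used so synthetic data can exercise the
#' full I/O path.
#'
#' @param x a [sparse_counts] object.
#' @param dir output directory (created if needed). Writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`, `metadata.tsv`.
#' @return the directory path, invisibly.
#' @export
write_mtx_triplet <- function(x, dir) {
  stopifnot(inherits(x, "sparse_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a TCR repertoire TSV (immunoSEQ-style export)
#'
#' Expects a tab-separated table with a template-sequence column (named
#' `template`, `aminoAcid` or `amino_acid`) and a count column (`count`
#' or `templates`). Duplicate template rows are summed.
#'
#' @param path TSV file path.
#' @param sample_id,mouse_id,timepoint identifying labels, usually taken
#'   from a manifest (see [read_repertoire_manifest]).
#' @return a [repertoire_table].
#' @export
read_repertoire_tsv <- function(path, sample_id = basename(path),
                                mouse_id = sample_id, timepoint = "T0") {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("cannot parse repertoire file '%s': %s",
                                     path, conditionMessage(e))))
  if (nrow(tab) == 0) stop(sprintf("repertoire file '%s' has no rows", path))
  tcol <- intersect(c("template", "aminoAcid", "amino_acid"), names(tab))[1]
  ccol <- intersect(c("count", "templates", "count (templates)"), names(tab))[1]
  if (is.na(tcol) || is.na(ccol)) {
    stop("repertoire TSV must have template and count columns")
  }
  cnt <- suppressWarnings(as.numeric(tab[[ccol]]))
  if (anyNA(cnt)) stop("non-numeric count in repertoire file")
  if (any(cnt < 0)) stop("negative count in repertoire file")
  repertoire_table(tab[[tcol]], cnt, sample_id = sample_id,
                   mouse_id = mouse_id, timepoint = timepoint)
}

#' Read a repertoire cohort from a manifest
#'
#' @param manifest_path TSV with header columns `path`, `mouse_id`,
#'   `timepoint` and optionally `sample_id`. Relative paths are resolved
#'   against the manifest's directory.
#' @return a list of [repertoire_table] objects.
#' @export
read_repertoire_manifest <- function(manifest_path) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("path", "mouse_id", "timepoint") %in% names(man)))
  if (!"sample_id" %in% names(man)) {
    man$sample_id <- paste(man$mouse_id, man$timepoint, sep = "_")
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_repertoire_tsv(p, sample_id = man$sample_id[i],
                        mouse_id = man$mouse_id[i],
                        timepoint = man$timepoint[i])
  })
}

#' Read a bulk gene-by-sample count TSV
#'
#' @param path TSV with gene identifiers in the first column and one column
#'   per sample.
#' @param lengths_path optional TSV (gene, length_bases) for RPKM.
#' @param condition optional per-sample condition labels.
#' @return a [bulk_counts] object.
#' @export
read_bulk_tsv <- function(path, lengths_path = NULL, condition = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  lens <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.table(lengths_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    lens <- lt[[2]][match(rownames(tab), lt[[1]])]
    if (anyNA(lens)) stop("gene lengths missing for some genes")
  }
  bulk_counts(as.matrix(tab), gene_length = lens, condition = condition)
}

#' Write an analysis result to CSV or JSON
#'
#' Tabular results (marker tables, repertoire statistics, ...) round-trip
#' exactly: `read_results(write_results(x, p, f), f)` equals `x`. MST
#' trajectories are serialized to JSON as `nodes` / `edges` arrays.
#'
#' @param object a data.frame or an `mst_trajectory`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(object, "mst_trajectory")) {
    if (format != "json") stop("MST trajectories are written as JSON")
    payload <- list(nodes = object$nodes, edges = object$edges,
                    centroids = as.data.frame(object$centroids))
    jsonlite::write_json(payload, path, digits = NA, dataframe = "rows")
    return(invisible(path))
  }
  object <- as.data.frame(object)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(object, path, row.names = FALSE)
    } else {
      jsonlite::write_json(object, path, digits = NA, dataframe = "rows")
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write results to '%s'", path))
  invisible(path)
}

#' Read back a result written by [write_results]
#' @param path file path
#' @param format `"csv"` or `"json"`
#' @return a data.frame
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
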