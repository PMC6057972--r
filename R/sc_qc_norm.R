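#' Single-cell QC parameters
#'
#' Thresholds follow the strict-inequality reading of the source pipeline:
#' cells expressing fewer than `min_genes` unique genes are discarded
#' (a 300-gene cell is kept), cells whose mitochondrial/endogenous count
#' ratio exceeds `max_mito_ratio` are discarded (a ratio of exactly 0.1 is
#' kept), and genes with mean normalized expression below `min_gene_mean`
#' are dropped after normalization.
#'
#' @param min_genes minimum unique genes per cell (default 300).
#' @param max_mito_ratio maximum mito/endogenous expression ratio (0.1).
#' @param min_gene_mean minimum mean normalized expression per gene (0.01).
#' @export
qc_params <- function(min_genes = 300, max_mito_ratio = 0.1,
                      min_gene_mean = 0.01) {
  stopifnot(min_genes >= 0, max_mito_ratio > 0, max_mito_ratio <= 1)
  structure(list(min_genes = min_genes, max_mito_ratio = max_mito_ratio,
                 min_gene_mean = min_gene_mean), class = "qc_params")
}

#' Quality-control filter for single-cell UMI counts
#'
#' Applies, in order: (1) drop cells with fewer than `min_genes` expressed
#' genes (count > 0); (2) drop cells whose mitochondrial-to-endogenous
#' count ratio strictly exceeds `max_mito_ratio`; (3) drop genes whose
#' mean normalized expression (mean of `exp(N) - 1` after
#' [log_normalize]) across the retained cells falls below
#' `min_gene_mean`. Idempotent: filtering an already-filtered matrix
#' removes nothing.
#'
#' @param counts a [sparse_counts].
#' @param params a [qc_params].
#' @param scale_factor normalization scale factor used for the gene-mean
#'   filter (default 1e4).
#' @return list with `counts` (filtered [sparse_counts]) and `report`
#'   (cells_in, cells_dropped_genes, cells_dropped_mito, cells_out,
#'   genes_in, genes_dropped, genes_out).
#' @export
qc_filter <- function(counts, params = qc_params(), scale_factor = 1e4) {
  stopifnot(inherits(counts, "sparse_counts"), inherits(params, "qc_params"))
  m <- counts$counts
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty matrix")
  genes_per_cell <- Matrix::colSums(m > 0)
  keep1 <- genes_per_cell >= params$min_genes
  mito <- counts$gene_meta$mito
  mito_counts <- Matrix::colSums(m[mito, , drop = FALSE])
  endo_counts <- Matrix::colSums(m[!mito, , drop = FALSE])
  ratio <- ifelse(endo_counts > 0, mito_counts / endo_counts, Inf)
  keep2 <- keep1 & (ratio <= params$max_mito_ratio)
  if (!any(keep2)) stop("QC removed every cell")
  filtered <- subset_counts(counts, cells = which(keep2))
  norm <- log_normalize(filtered, scale_factor = scale_factor)
  gene_means <- Matrix::rowMeans(expm1_sparse(norm$N))
  keep_genes <- gene_means >= params$min_gene_mean
  out <- subset_counts(filtered, genes = which(keep_genes))
  report <- list(cells_in = ncol(m),
                 cells_dropped_genes = sum(!keep1),
                 cells_dropped_mito = sum(keep1 & !keep2),
                 cells_out = ncol(out$counts),
                 genes_in = nrow(m),
                 genes_dropped = sum(!keep_genes),
                 genes_out = nrow(out$counts))
  list(counts = out, report = report)
}

# expm1 on a sparse matrix, preserving sparsity
expm1_sparse <- function(N) {
  out <- N
  out@x <- expm1(out@x)
  out
}

#' Log-normalize UMI counts
#'
#' `N[i, j] = ln(1 + count[i, j] * scale_factor / total[j])` with
#' per-cell totals; sparse zeros are preserved. The per-cell identity
#' `sum(exp(N) - 1) = scale_factor` holds exactly.
#'
#' @param counts a [sparse_counts].
#' @param scale_factor library-size target (default 1e4).
#' @return a `normalized_matrix`: list with `N` (sparse genes x cells),
#'   `scale_factor`, `totals`, `cell_meta`, `gene_meta`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "sparse_counts"))
  totals <- Matrix::colSums(counts$counts)
  if (any(totals <= 0)) stop("cells with zero total count; run QC first")
  N <- counts$counts
  N@x <- log1p(N@x * scale_factor / rep.int(totals, diff(N@p)))
  structure(list(N = N, scale_factor = scale_factor, totals = totals,
                 cell_meta = counts$cell_meta, gene_meta = counts$gene_meta),
            class = "normalized_matrix")
}

#' Per-cell covariates for regression scaling
#'
#' Computes UMI totals and the mitochondrial expression ratio from raw
#' counts; cell-cycle scores default to zero until [cell_cycle_scores]
#' fills them in.
#'
#' @param counts a [sparse_counts].
#' @return data.frame: barcode, n_umi, mito_ratio, s_score, g2m_score,
#'   cc_difference.
#' @export
cell_covariates <- function(counts) {
  stopifnot(inherits(counts, "sparse_counts"))
  m <- counts$counts
  mito <- counts$gene_meta$mito
  n_umi <- Matrix::colSums(m)
  mito_ratio <- ifelse(n_umi > 0, Matrix::colSums(m[mito, , drop = FALSE]) / n_umi, 0)
  data.frame(barcode = colnames(m), n_umi = as.numeric(n_umi),
             mito_ratio = as.numeric(mito_ratio),
             s_score = 0, g2m_score = 0, cc_difference = 0,
             stringsAsFactors = FALSE)
}

#' Cell-cycle phase scores
#'
#' For each phase gene set the score is the mean normalized expression of
#' the set minus the mean of an expression-matched control set: all genes
#' are binned into `n_ctrl_bins` by mean expression and, for every gene in
#' the set, `ctrl_per_gene` control genes are sampled (with replacement if
#' needed) from the same bin. `cc_difference = s_score - g2m_score`.
#' Deterministic given `seed`.
#'
#' @param norm a `normalized_matrix` from [log_normalize].
#' @param covariates data.frame from [cell_covariates].
#' @param s_genes,g2m_genes character vectors of phase marker genes.
#' @param n_ctrl_bins expression bins for control matching (default 25).
#' @param ctrl_per_gene control genes drawn per signature gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return the covariates data.frame with scores filled in.
#' @export
cell_cycle_scores <- function(norm, covariates, s_genes, g2m_genes,
                              n_ctrl_bins = 25, ctrl_per_gene = 100,
                              seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  genes <- rownames(norm$N)
  score_set <- function(set, rng_offset) {
    set <- intersect(set, genes)
    if (length(set) == 0) stop("gene set shares no genes with the matrix")
    gene_means <- Matrix::rowMeans(norm$N)
    bins <- cut(rank(gene_means, ties.method = "first"),
                breaks = n_ctrl_bins, labels = FALSE)
    names(bins) <- genes
    set.seed(as.integer(seed) + rng_offset)
    ctrl <- unique(unlist(lapply(set, function(g) {
      pool <- setdiff(genes[bins == bins[[g]]], set)
      if (length(pool) == 0) pool <- setdiff(genes, set)
      sample(pool, min(ctrl_per_gene, length(pool)))
    })))
    set_mean <- Matrix::colMeans(norm$N[set, , drop = FALSE])
    ctrl_mean <- Matrix::colMeans(norm$N[ctrl, , drop = FALSE])
    as.numeric(set_mean - ctrl_mean)
  }
  covariates$s_score <- score_set(s_genes, 0L)
  covariates$g2m_score <- score_set(g2m_genes, 1L)
  covariates$cc_difference <- covariates$s_score - covariates$g2m_score
  covariates
}

#' Regress out technical covariates and z-score per gene
#'
#' Per gene, fits ordinary least squares of normalized expression on UMI
#' total, mitochondrial ratio and the S-minus-G2M cell-cycle difference;
#' residuals are z-scored per gene (mean 0, sd 1) and clipped at
#' `clip_max` to bound outlier leverage. Constant genes (sd 0) scale to
#' all zeros. With all-constant covariates this reduces exactly to plain
#' per-gene z-scoring.
#'
#' @param norm a `normalized_matrix`.
#' @param covariates data.frame with `n_umi`, `mito_ratio`,
#'   `cc_difference` for every cell (matched by position).
#' @param clip_max symmetric clip bound on scaled values (default 10).
#' @return dense genes x cells matrix of scaled residuals.
#' @export
regress_and_scale <- function(norm, covariates, clip_max = 10) {
  stopifnot(inherits(norm, "normalized_matrix"),
            nrow(covariates) == ncol(norm$N))
  X <- cbind(1, covariates$n_umi, covariates$mito_ratio,
             covariates$cc_difference)
  qrX <- qr(X)
  dense <- as.matrix(norm$N)
  # residuals of each gene (row) on the shared design
  resid <- t(qr.resid(qrX, t(dense)))
  sds <- apply(resid, 1, stats::sd)
  mus <- rowMeans(resid)
  # genes fitted (near-)exactly by the covariates carry no residual signal
  flat <- sds < 1e-10
  scaled <- (resid - mus) / ifelse(flat, 1, sds)
  scaled[flat, ] <- 0
  scaled[scaled > clip_max] <- clip_max
  scaled[scaled < -clip_max] <- -clip_max
  dimnames(scaled) <- dimnames(norm$N)
  scaled
}

#' Highly-variable-gene selection parameters
#'
#' @param mean_low,mean_high bounds on mean normalized expression (genes
#'   with mean `<= mean_low` or `> mean_high` are excluded). Defaults
#'   0.01 and 3.
#' @param dispersion_z_cutoff keep genes with binned dispersion z-score
#'   strictly above this value (default 0.5).
#' @param n_bins equal-frequency mean-expression bins for the z-score
#'   (default 20).
#' @export
hvg_params <- function(mean_low = 0.01, mean_high = 3,
                       dispersion_z_cutoff = 0.5, n_bins = 20) {
  stopifnot(mean_low < mean_high, n_bins >= 1)
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 dispersion_z_cutoff = dispersion_z_cutoff, n_bins = n_bins),
            class = "hvg_params")
}

#' Select highly variable genes by binned dispersion z-score
#'
#' Per gene, mean and dispersion (variance/mean) are computed on
#' `exp(N) - 1`; genes are cut into `n_bins` equal-frequency bins by mean,
#' dispersion is z-scored within each bin (a single-gene or zero-variance
#' bin gets z = 0), and genes are kept when the mean lies in
#' `(mean_low, mean_high]` and the z-score exceeds the cutoff.
#'
#' @param norm a `normalized_matrix`.
#' @param params an [hvg_params].
#' @return character vector of selected gene names, with the full
#'   per-gene table as attribute `"table"`.
#' @export
select_hvg <- function(norm, params = hvg_params()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  C <- expm1_sparse(norm$N)
  n <- ncol(C)
  mu <- Matrix::rowMeans(C)
  ex2 <- Matrix::rowMeans(C^2)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- min(params$n_bins, length(mu))
  bins <- cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    i <- which(bins == b)
    s <- stats::sd(disp[i])
    z[i] <- if (length(i) < 2 || is.na(s) || s == 0) 0 else
      (disp[i] - mean(disp[i])) / s
  }
  keep <- mu > params$mean_low & mu <= params$mean_high &
    z > params$dispersion_z_cutoff
  tab <- data.frame(gene = rownames(norm$N), mean = mu, dispersion = disp,
                    dispersion_z = z, hvg = keep, stringsAsFactors = FALSE)
  out <- tab$gene[keep]
  attr(out, "table") <- tab
  out
}

#' PCA embedding of cells on highly variable genes
#'
#' Principal components of the HVG-restricted scaled matrix, with cells
#' as observations. Component signs are fixed by convention: the loading
#' with the largest magnitude on each axis is made positive, so the
#' embedding is deterministic.
#'
#' @param scaled genes x cells matrix from [regress_and_scale].
#' @param hvg character vector of genes to use (must be rows of `scaled`).
#' @param n_pcs number of components (default 25).
#' @return cells x n_pcs matrix of PC scores; attribute `"sdev"` carries
#'   the component standard deviations, `"loadings"` the gene loadings.
#' @export
pca_embed <- function(scaled, hvg, n_pcs = 25) {
  hvg <- intersect(hvg, rownames(scaled))
  if (length(hvg) < n_pcs) {
    stop(sprintf("need at least %d HVGs for %d PCs (have %d)",
                 n_pcs, n_pcs, length(hvg)))
  }
  X <- t(scaled[hvg, , drop = FALSE]) # cells x genes
  if (n_pcs > min(dim(X))) stop("n_pcs exceeds matrix rank bound")
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs) %*% diag(flip, n_pcs)
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("PC", seq_len(n_pcs))
  attr(emb, "sdev") <- sv$d / sqrt(max(1, nrow(X) - 1))
  attr(emb, "loadings") <- sweep(sv$v, 2, flip, `*`)
  emb
}
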