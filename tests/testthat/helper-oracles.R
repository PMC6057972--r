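# Independent oracles and fixture builders used across the suite.

# Shannon entropy / clonality by direct summation (independent of the
# package implementation).
oracle_clonality <- function(counts) {
  x <- counts[counts > 0]
  p <- x / sum(x)
  Hp <- -sum(p * log(p))
  1 - Hp / log(length(x))
}

oracle_bray_curtis_sim <- function(s, m) 1 - sum(abs(s - m)) / sum(s + m)

# Dense brute-force cluster-enrichment logFC (double loop, no sparsity).
oracle_logfc <- function(N_dense, in_cells, eps = 1e-9) {
  C <- exp(N_dense) - 1
  out <- numeric(nrow(C))
  for (i in seq_len(nrow(C))) {
    mean_in <- mean(C[i, in_cells])
    mean_out <- mean(C[i, -in_cells])
    out[i] <- log2(mean_in + eps) - log2(mean_out + eps)
  }
  out
}

# Naive double-loop QC filter mirroring the stated rules.
oracle_qc <- function(dense, mito, min_genes, max_mito, min_gene_mean,
                      scale_factor = 1e4) {
  keep_cells <- logical(ncol(dense))
  for (j in seq_len(ncol(dense))) {
    n_expr <- sum(dense[, j] > 0)
    ratio <- sum(dense[mito, j]) / sum(dense[!mito, j])
    keep_cells[j] <- n_expr >= min_genes && ratio <= max_mito
  }
  sub <- dense[, keep_cells, drop = FALSE]
  norm <- sapply(seq_len(ncol(sub)), function(j) {
    log1p(sub[, j] * scale_factor / sum(sub[, j]))
  })
  keep_genes <- rowMeans(exp(norm) - 1) >= min_gene_mean
  list(cells = which(keep_cells), genes = which(keep_genes))
}

# Exhaustive minimum-spanning-tree weight via Prufer-sequence enumeration
# (n^(n-2) labelled trees).
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  stopifnot(n >= 3, n <= 6)
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 1L
    seq <- c(seq, 0L)
    for (k in seq_len(n - 2)) {
      leaf <- min(which(degree == 1L))
      edges[ptr, ] <- c(leaf, seq[k]); ptr <- ptr + 1L
      degree[leaf] <- 0L
      degree[seq[k]] <- degree[seq[k]] - 1L
    }
    edges[ptr, ] <- which(degree == 1L)
    edges
  }
  grids <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    e <- prufer_to_edges(as.integer(grids[r, ]))
    wt <- sum(w[e])
    if (wt < best) best <- wt
  }
  best
}

# Small random sparse_counts fixture.
random_counts_fixture <- function(n_genes = 30, n_cells = 20, seed = 1,
                                  n_mito = 3, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  rownames(m) <- c(sprintf("mt-G%02d", seq_len(n_mito)),
                   sprintf("G%04d", seq_len(n_genes - n_mito)))
  colnames(m) <- sprintf("bc%03d", seq_len(n_cells))
  # guarantee no zero-total cell
  m[1, colSums(m) == 0] <- 1
  sparse_counts(m, condition = rep(c("CTRL", "ALL"), length.out = n_cells))
}

random_repertoire <- function(n = 5, seed = 1, ...) {
  set.seed(seed)
  repertoire_table(sprintf("CASS%04d", seq_len(n)),
                   sample(1:50, n, replace = TRUE), ...)
}

# Four-cell fixture probing both QC thresholds exactly at the boundary.
make_boundary_fixture <- function() {
  # 400 endogenous genes + 1 mito gene; four cells probing both thresholds
  n_genes <- 401
  m <- matrix(0, n_genes, 4)
  rownames(m) <- c("mt-Nd1", sprintf("G%03d", seq_len(400)))
  colnames(m) <- c("genes299", "genes300", "mito_at", "mito_over")
  m[2:300, 1] <- 1          # 299 expressed genes
  m[2:301, 2] <- 1          # 300 expressed genes
  m[2:401, 3] <- 1          # 400 endogenous counts
  m[1, 3] <- 40             # ratio exactly 0.1
  m[2:401, 4] <- 1
  m[1, 4] <- 41             # ratio 0.1025 > 0.1
  sparse_counts(m)
}

as_sparse <- function(m) {
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}
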