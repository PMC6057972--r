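#' Graph-based clustering parameters
#'
#' @param n_neighbors neighbors for the shared-nearest-neighbor graph
#'   (default 20, including the cell itself).
#' @param resolution modularity resolution; 0.23 for the main clustering,
#'   0.5 for sub-clustering.
#' @param method community detection algorithm, `"louvain"` or `"leiden"`.
#' @param prune minimum SNN Jaccard weight to keep an edge (default 1/15).
#' @param seed RNG seed for the community detection.
#' @export
cluster_params <- function(n_neighbors = 20, resolution = 0.23,
                           method = c("louvain", "leiden"),
                           prune = 1 / 15, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n_neighbors >= 2, resolution > 0)
  structure(list(n_neighbors = n_neighbors, resolution = resolution,
                 method = method, prune = prune, seed = as.integer(seed)),
            class = "cluster_params")
}

# SNN graph: k Euclidean nearest neighbors (self included), Jaccard overlap
snn_graph <- function(embedding, k, prune) {
  n <- nrow(embedding)
  d <- as.matrix(stats::dist(embedding))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)] # self is rank 1 (distance 0)
    A[i, nb] <- 1
  }
  shared <- A %*% t(A)
  jac <- shared / (2 * k - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' Cluster cells on a PC embedding via an SNN graph
#'
#' Builds a shared-nearest-neighbor graph (Jaccard-weighted) on
#' `n_neighbors` Euclidean neighbors in PC space and partitions it by
#' modularity community detection (Louvain or Leiden) at the requested
#' resolution. Cluster labels are renumbered 1..k by decreasing size.
#' Deterministic given the seed.
#'
#' @param embedding cells x PCs matrix from [pca_embed].
#' @param params a [cluster_params].
#' @return integer vector of cluster labels (1..k), named by cell.
#' @export
cluster_cells <- function(embedding, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  n <- nrow(embedding)
  if (n < params$n_neighbors) {
    stop(sprintf("need at least n_neighbors = %d cells (have %d)",
                 params$n_neighbors, n))
  }
  g <- snn_graph(embedding, params$n_neighbors, params$prune)
  set.seed(params$seed)
  comm <- if (params$method == "louvain") {
    igraph::cluster_louvain(g, resolution = params$resolution)
  } else {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = params$resolution, n_iterations = 5)
  }
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  new_id <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                            names(sizes))
  labels <- as.integer(new_id[as.character(memb)])
  names(labels) <- rownames(embedding)
  labels
}

# marker logFC core: log2(mean_in + eps) - log2(mean_out + eps) on C = e^N - 1
logfc_in_out <- function(C_expr, in_cells, eps = 1e-9) {
  n_in <- length(in_cells)
  n_out <- ncol(C_expr) - n_in
  sum_all <- Matrix::rowSums(C_expr)
  sum_in <- Matrix::rowSums(C_expr[, in_cells, drop = FALSE])
  mean_in <- sum_in / n_in
  mean_out <- (sum_all - sum_in) / n_out
  log2(mean_in + eps) - log2(mean_out + eps)
}

#' Cluster-enrichment markers by log fold change
#'
#' For each cluster K and gene i, expression is back-transformed as
#' `C = exp(N) - 1` and the enrichment is
#' `logFC = log2(mean_in + eps) - log2(mean_out + eps)` where the means
#' are over cells inside / outside the cluster. A pseudocount
#' `eps = 1e-9` keeps the ratio defined when a gene is absent from one
#' side and preserves two-cluster antisymmetry. Genes are retained when
#' expressed (count > 0) in at least `min_frac` of the cluster's cells
#' and ranked by decreasing logFC (ties broken by gene identifier).
#'
#' @param norm a `normalized_matrix`.
#' @param assignment integer cluster labels per cell.
#' @param min_frac minimum expressed fraction within the cluster (0.2).
#' @param eps pseudocount inside both log2 terms.
#' @return data.frame: cluster, gene, logFC, frac_in, frac_out.
#' @export
cluster_markers <- function(norm, assignment, min_frac = 0.2, eps = 1e-9) {
  stopifnot(inherits(norm, "normalized_matrix"),
            length(assignment) == ncol(norm$N))
  ks <- sort(unique(assignment))
  if (length(ks) < 2) stop("need at least 2 clusters for marker enrichment")
  C <- expm1_sparse(norm$N)
  expressed <- norm$N > 0
  out <- lapply(ks, function(k) {
    in_cells <- which(assignment == k)
    lfc <- logfc_in_out(C, in_cells, eps)
    frac_in <- Matrix::rowSums(expressed[, in_cells, drop = FALSE]) /
      length(in_cells)
    frac_out <- Matrix::rowSums(expressed[, -in_cells, drop = FALSE]) /
      (ncol(C) - length(in_cells))
    keep <- frac_in >= min_frac
    d <- data.frame(cluster = k, gene = rownames(C)[keep],
                    logFC = lfc[keep], frac_in = frac_in[keep],
                    frac_out = frac_out[keep], stringsAsFactors = FALSE)
    d[order(-d$logFC, d$gene), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Condition contrast within one cluster
#'
#' Applies the same logFC machinery with the two condition groups playing
#' the in/out roles. Genes are considered only when expressed (count > 0)
#' in at least `min_cell_frac` of the cells of at least one group; when
#' `sample_labels` is supplied, the fraction is evaluated per sample and
#' a gene qualifies if any single sample reaches the threshold. Returns
#' the `top_n` genes by decreasing (up) and increasing (down) logFC.
#'
#' @param norm a `normalized_matrix` restricted to the focal cluster.
#' @param conditions per-cell condition labels.
#' @param cond_a,cond_b the two conditions contrasted (A vs B; positive
#'   logFC means higher in A).
#' @param top_n genes reported per direction (default 100).
#' @param min_cell_frac expression-fraction threshold (default 0.05).
#' @param sample_labels optional per-cell sample labels for the
#'   per-sample filter mode.
#' @param eps pseudocount as in [cluster_markers].
#' @return list with `up`, `down` (character vectors) and `table`
#'   (gene, logFC, frac_a, frac_b for all qualifying genes).
#' @export
condition_contrast <- function(norm, conditions, cond_a, cond_b,
                               top_n = 100, min_cell_frac = 0.05,
                               sample_labels = NULL, eps = 1e-9) {
  stopifnot(inherits(norm, "normalized_matrix"),
            length(conditions) == ncol(norm$N))
  ia <- which(conditions == cond_a)
  ib <- which(conditions == cond_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop(sprintf("both conditions must be present ('%s': %d cells, '%s': %d)",
                 cond_a, length(ia), cond_b, length(ib)))
  }
  cells <- c(ia, ib)
  Nsub <- norm$N[, cells, drop = FALSE]
  C <- expm1_sparse(Nsub)
  expressed <- Nsub > 0
  frac_in_group <- function(idx_local) {
    Matrix::rowSums(expressed[, idx_local, drop = FALSE]) / length(idx_local)
  }
  la <- seq_along(ia)
  lb <- length(ia) + seq_along(ib)
  if (is.null(sample_labels)) {
    qual <- frac_in_group(la) >= min_cell_frac |
      frac_in_group(lb) >= min_cell_frac
  } else {
    sl <- sample_labels[cells]
    fracs <- vapply(split(seq_along(cells), sl), frac_in_group,
                    numeric(nrow(Nsub)))
    qual <- apply(fracs >= min_cell_frac, 1, any)
  }
  lfc <- logfc_in_out(C, la, eps)
  tab <- data.frame(gene = rownames(Nsub)[qual], logFC = lfc[qual],
                    frac_a = frac_in_group(la)[qual],
                    frac_b = frac_in_group(lb)[qual],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$logFC, tab$gene), ]
  rownames(tab) <- NULL
  list(up = utils::head(tab$gene, top_n),
       down = utils::head(tab$gene[order(tab$logFC, tab$gene)], top_n),
       table = tab)
}

#' Default differential-expression ranker for signature derivation
#'
#' Per-gene two-sample t-test on log2(CPM + 1) with Benjamini-Hochberg
#' correction across genes. The pooled per-gene variance is moderated by
#' shrinking it, with `prior_df` prior degrees of freedom
#' (empirical-Bayes style), toward a mean-variance trend (a lowess fit of
#' pooled variance on mean log-CPM), which stabilises the statistic at
#' the small replicate numbers typical of sorted reference profiles; the
#' test degrees of freedom increase accordingly. The log fold change is
#' the difference of group means on the log2-CPM scale. Serves as the
#' pluggable `(logFC, FDR)` provider when no external model fit is
#' supplied.
#'
#' @param counts genes x samples count matrix.
#' @param idx_a,idx_b column indices of the two groups (each >= 2).
#' @param prior_df prior degrees of freedom of the variance shrinkage
#'   (default 10; 0 gives the ordinary pooled-variance t-test).
#' @return data.frame: gene, logFC, FDR.
#' @export
default_de_ranker <- function(counts, idx_a, idx_b, prior_df = 10) {
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("default ranker requires at least 2 replicates per group")
  }
  cpm <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  lg <- log2(cpm + 1)
  a <- lg[, idx_a, drop = FALSE]
  b <- lg[, idx_b, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  na <- ncol(a); nb <- ncol(b)
  df_resid <- na + nb - 2
  pooled <- (apply(a, 1, stats::var) * (na - 1) +
             apply(b, 1, stats::var) * (nb - 1)) / df_resid
  grand_mean <- (ma * na + mb * nb) / (na + nb)
  trend <- stats::lowess(grand_mean, pooled, f = 0.5)
  v0 <- pmax(stats::approx(trend$x, trend$y, xout = grand_mean,
                           rule = 2, ties = "ordered")$y,
             1e-8)
  v_mod <- (prior_df * v0 + df_resid * pooled) / (prior_df + df_resid)
  se <- sqrt(v_mod * (1 / na + 1 / nb))
  t_stat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t_stat), df_resid + prior_df)
  p[se == 0] <- ifelse(ma[se == 0] == mb[se == 0], 1, 0)
  p[is.na(p)] <- 1
  data.frame(gene = rownames(counts), logFC = ma - mb,
             FDR = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

#' Derive cell-type gene signatures from reference profiles
#'
#' For each cell type T and each other type T', the DE ranker compares
#' T's replicates against T''s; genes significant at `FDR < fdr` and
#' up-regulated in T are ranked by decreasing fold change and the top
#' `top_k` retained. The signature of T is the intersection of all its
#' pairwise lists (ordered by mean rank across lists). `top_n_override`
#' truncates the final signature to its first n genes, reproducing the
#' short-signature variant used for monocyte subsets.
#'
#' @param reference a [bulk_counts] whose `condition` gives the cell type
#'   of each replicate column (>= 2 types, >= 2 replicates each).
#' @param de_ranker function `(counts, idx_a, idx_b) -> data.frame(gene,
#'   logFC, FDR)`; defaults to [default_de_ranker].
#' @param fdr significance cutoff (default 1e-4).
#' @param top_k genes retained per pairwise list (default 200).
#' @param top_n_override optional cap on the final signature length.
#' @return named list of signatures; each is a list with `cell_type`,
#'   `genes` (ordered character vector) and `meta` (fdr, top_k,
#'   n_lists).
#' @export
derive_signatures <- function(reference, de_ranker = default_de_ranker,
                              fdr = 1e-4, top_k = 200,
                              top_n_override = NULL) {
  stopifnot(inherits(reference, "bulk_counts"))
  types <- unique(reference$condition)
  if (length(types) < 2) stop("need at least 2 cell types")
  reps <- split(seq_along(reference$condition), reference$condition)
  if (any(vapply(reps, length, 0L) < 2)) {
    stop("every cell type needs at least 2 replicate profiles")
  }
  out <- lapply(types, function(ty) {
    others <- setdiff(types, ty)
    lists <- lapply(others, function(ot) {
      res <- de_ranker(reference$counts, reps[[ty]], reps[[ot]])
      res <- res[res$FDR < fdr & res$logFC > 0, ]
      res <- res[order(-res$logFC, res$gene), ]
      utils::head(res$gene, top_k)
    })
    sig <- Reduce(intersect, lists)
    if (length(sig) > 1) {
      mean_rank <- rowMeans(vapply(lists, function(l) match(sig, l),
                                   numeric(length(sig))))
      sig <- sig[order(mean_rank, sig)]
    }
    if (!is.null(top_n_override)) sig <- utils::head(sig, top_n_override)
    list(cell_type = ty, genes = sig,
         meta = list(fdr = fdr, top_k = top_k, n_lists = length(lists)),
         pairwise_lists = stats::setNames(lists, others))
  })
  stats::setNames(out, types)
}

#' Annotate clusters with cell-type signatures
#'
#' Scores each cluster against each signature as the mean, over signature
#' genes, of the per-gene z-score (across clusters) of the cluster's mean
#' normalized expression, and assigns the argmax type. Clusters whose
#' score vector is entirely zero (e.g. a constant matrix) are flagged
#' ambiguous.
#'
#' @param norm a `normalized_matrix`.
#' @param assignment cluster labels per cell.
#' @param signatures output of [derive_signatures] (or any named list
#'   with `genes` elements).
#' @return data.frame: cluster, cell_type, score, margin, ambiguous;
#'   attribute `"score_matrix"` holds the full clusters x signatures
#'   matrix.
#' @export
annotate_clusters <- function(norm, assignment, signatures) {
  stopifnot(inherits(norm, "normalized_matrix"),
            length(assignment) == ncol(norm$N))
  ks <- sort(unique(assignment))
  cluster_mean <- vapply(ks, function(k) {
    Matrix::rowMeans(norm$N[, assignment == k, drop = FALSE])
  }, numeric(nrow(norm$N)))
  colnames(cluster_mean) <- paste0("cluster", ks)
  sds <- apply(cluster_mean, 1, stats::sd)
  z <- (cluster_mean - rowMeans(cluster_mean)) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  scores <- vapply(signatures, function(sig) {
    genes <- intersect(sig$genes, rownames(norm$N))
    if (length(genes) == 0) {
      warning(sprintf("signature '%s' shares no genes with the matrix",
                      sig$cell_type))
      return(rep(NA_real_, length(ks)))
    }
    colMeans(z[genes, , drop = FALSE])
  }, numeric(length(ks)))
  scores <- matrix(scores, nrow = length(ks),
                   dimnames = list(paste0("cluster", ks), names(signatures)))
  res <- do.call(rbind, lapply(seq_along(ks), function(i) {
    s <- scores[i, ]
    if (all(is.na(s)) || all(s == 0, na.rm = TRUE)) {
      return(data.frame(cluster = ks[i], cell_type = NA_character_,
                        score = NA_real_, margin = NA_real_,
                        ambiguous = TRUE, stringsAsFactors = FALSE))
    }
    best <- which.max(s)
    sorted <- sort(s, decreasing = TRUE)
    data.frame(cluster = ks[i], cell_type = names(s)[best],
               score = s[[best]],
               margin = if (length(sorted) > 1) sorted[1] - sorted[2] else NA,
               ambiguous = FALSE, stringsAsFactors = FALSE)
  }))
  attr(res, "score_matrix") <- scores
  res
}
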