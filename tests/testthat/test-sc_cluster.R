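blob_embedding <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  emb <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[k, ], `+`)
  }))
  rownames(emb) <- sprintf("c%04d", seq_len(nrow(emb)))
  emb
}

test_that("well-separated blobs cluster perfectly; one blob stays whole", {
  skip_if_not_installed("mclust")
  emb <- blob_embedding(rbind(c(0, 0), c(12, 0)), 60, seed = 2)
  truth <- rep(1:2, each = 60)
  cl <- cluster_cells(emb, cluster_params(resolution = 0.23, seed = 1))
  expect_equal(length(unique(cl)), 2)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)

  single <- blob_embedding(rbind(c(0, 0)), 80, seed = 3)
  cl1 <- cluster_cells(single, cluster_params(resolution = 0.23, seed = 1))
  expect_equal(length(unique(cl1)), 1)

  expect_error(cluster_cells(emb[1:5, ], cluster_params()), "n_neighbors")
})

test_that("clustering is seed-stable and permutation-equivariant", {
  skip_if_not_installed("mclust")
  emb <- blob_embedding(rbind(c(0, 0), c(9, 0), c(0, 9)), 40, seed = 5)
  p <- cluster_params(resolution = 0.5, seed = 7)
  a <- cluster_cells(emb, p)
  b <- cluster_cells(emb, p)
  expect_identical(a, b)
  perm <- sample(nrow(emb))
  cp <- cluster_cells(emb[perm, ], p)
  expect_equal(mclust::adjustedRandIndex(cp, a[perm]), 1)
})

test_that("the full pipeline recovers planted cell types", {
  skip_if_not_installed("mclust")
  spec <- sc_sim_spec(n_cell_types = 4, cells_per_type = 100, n_genes = 1000,
                      conditions = "CTRL", module_fc = c(CTRL = 1),
                      marker_fc = 8, seed = 11)
  sim <- simulate_sc(spec)
  qc <- qc_filter(sim$counts)
  norm <- log_normalize(qc$counts)
  cov <- cell_covariates(qc$counts)
  scaled <- regress_and_scale(norm, cov)
  hvg <- select_hvg(norm, hvg_params(mean_high = Inf))
  emb <- pca_embed(scaled, hvg, n_pcs = 25)
  cl <- cluster_cells(emb, cluster_params(resolution = 0.23, seed = 1))
  truth <- sim$truth$type[match(colnames(qc$counts$counts),
                                colnames(sim$counts$counts))]
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)
})

test_that("marker logFC follows the back-transformed mean equations", {
  # planted in/out means: C = 2 inside, 0.5 outside -> logFC = 2
  n_in <- 10; n_out <- 30
  N <- rbind(c(rep(log(3), n_in), rep(log(1.5), n_out)),
             c(rep(log(2), n_in), rep(log(2), n_out))) # identical -> 0
  rownames(N) <- c("planted", "flat")
  colnames(N) <- sprintf("c%02d", seq_len(n_in + n_out))
  norm <- structure(list(N = as_sparse(N),
                         scale_factor = 1e4),
                    class = "normalized_matrix")
  mk <- cluster_markers(norm, c(rep(1, n_in), rep(2, n_out)), min_frac = 0)
  planted <- mk[mk$gene == "planted" & mk$cluster == 1, ]
  expect_equal(planted$logFC, log2(2 + 1e-9) - log2(0.5 + 1e-9),
               tolerance = 1e-12)
  expect_equal(planted$logFC, 2, tolerance = 1e-8)
  expect_equal(mk$logFC[mk$gene == "flat" & mk$cluster == 1], 0,
               tolerance = 1e-12)
  # two-cluster antisymmetry is exact up to the shared pseudocount
  k1 <- mk[mk$cluster == 1, ]; k1 <- k1[order(k1$gene), ]
  k2 <- mk[mk$cluster == 2, ]; k2 <- k2[order(k2$gene), ]
  expect_equal(k1$logFC, -k2$logFC, tolerance = 1e-12)
})

test_that("marker logFC matches a dense brute-force oracle on random data", {
  set.seed(41)
  n_genes <- 100; n_cells <- 200
  N <- matrix(0, n_genes, n_cells,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("c%03d", 1:n_cells)))
  nz <- sample(length(N), 4000)
  N[nz] <- runif(4000, 0.1, 3)
  assignment <- sample(1:3, n_cells, replace = TRUE)
  norm <- structure(list(N = as_sparse(N)),
                    class = "normalized_matrix")
  mk <- cluster_markers(norm, assignment, min_frac = 0)
  for (k in 1:3) {
    oracle <- oracle_logfc(N, which(assignment == k))
    got <- mk[mk$cluster == k, ]
    expect_equal(got$logFC, oracle[match(got$gene, rownames(N))],
                 tolerance = 1e-10)
  }
  # expression-fraction filter: frac_in below threshold is dropped
  mk20 <- cluster_markers(norm, assignment, min_frac = 0.2)
  expect_true(all(mk20$frac_in >= 0.2))
})

test_that("condition contrasts recover a planted module and apply the 5% filter", {
  spec <- sc_sim_spec(n_cell_types = 1, cells_per_type = 150, n_genes = 600,
                      conditions = c("ALL", "IFN+ALL"),
                      module_fc = c("ALL" = 1, "IFN+ALL" = 6),
                      module_genes = 25, markers_per_type = 1, marker_fc = 1,
                      seed = 19)
  sim <- simulate_sc(spec)
  norm <- log_normalize(sim$counts)
  res <- condition_contrast(norm, sim$counts$cell_meta$condition,
                            "IFN+ALL", "ALL", top_n = 25)
  hits <- length(intersect(res$up, sim$truth$module_genes))
  expect_gte(hits, 20)

  # null contrast: tiny logFC everywhere
  null_spec <- sc_sim_spec(n_cell_types = 1, cells_per_type = 150,
                           n_genes = 600,
                           conditions = c("ALL", "IFN+ALL"),
                           module_fc = c("ALL" = 1, "IFN+ALL" = 1),
                           markers_per_type = 1, marker_fc = 1, seed = 19)
  nsim <- simulate_sc(null_spec)
  nres <- condition_contrast(log_normalize(nsim$counts),
                             nsim$counts$cell_meta$condition,
                             "IFN+ALL", "ALL", top_n = 25)
  # null logFC is small in bulk; rare genes can fluctuate on the log scale
  expect_lt(mean(abs(nres$table$logFC)), 0.2)
  expect_lt(unname(quantile(abs(nres$table$logFC), 0.9)), 0.75)

  expect_error(condition_contrast(norm, sim$counts$cell_meta$condition,
                                  "IFN+ALL", "CTRL"), "present")
})

test_that("genes below the expressed-fraction threshold are excluded", {
  # 100 cells per condition; gene expressed in 4% of each -> excluded
  N <- matrix(0, 2, 200, dimnames = list(c("rare", "common"), NULL))
  N["rare", c(1:4, 101:104)] <- 1
  N["common", ] <- 0.5
  colnames(N) <- sprintf("c%03d", 1:200)
  norm <- structure(list(N = as_sparse(N)),
                    class = "normalized_matrix")
  cond <- rep(c("A", "B"), each = 100)
  res <- condition_contrast(norm, cond, "A", "B", min_cell_frac = 0.05)
  expect_false("rare" %in% res$table$gene)
  expect_true("common" %in% res$table$gene)
  # per-sample mode: one sample of 40 cells holds all 4 positives -> 10% > 5%
  samp <- rep(c("s1", "s2", "s3", "s4", "s5"), each = 40)
  res2 <- condition_contrast(norm, cond, "A", "B", min_cell_frac = 0.05,
                             sample_labels = samp)
  expect_true("rare" %in% res2$table$gene)
})

test_that("signature derivation recovers planted markers without contamination", {
  ref <- simulate_reference_profiles(n_cell_types = 5, n_genes = 2000,
                                     markers_per_type = 20, fold_change = 16,
                                     seed = 33)
  sigs <- derive_signatures(ref$profiles, fdr = 1e-4, top_k = 200)
  for (ty in names(sigs)) {
    own <- ref$truth_markers[[ty]]
    other <- setdiff(unlist(ref$truth_markers), own)
    expect_gte(length(intersect(sigs[[ty]]$genes, own)) / length(own), 0.9)
    expect_length(intersect(sigs[[ty]]$genes, other), 0)
    # intersection property: every signature gene is in every pairwise list
    for (l in sigs[[ty]]$pairwise_lists) {
      expect_true(all(sigs[[ty]]$genes %in% l))
    }
  }
  # monotone in top_k
  s100 <- derive_signatures(ref$profiles, top_k = 100)
  for (ty in names(sigs)) {
    expect_true(all(s100[[ty]]$genes %in% sigs[[ty]]$genes))
  }
  # short-signature variant
  s5 <- derive_signatures(ref$profiles, top_n_override = 5)
  expect_true(all(vapply(s5, function(s) length(s$genes), 0L) <= 5))
})

test_that("identical cell types yield empty signatures and single replicates error", {
  ref <- simulate_reference_profiles(n_cell_types = 3, n_genes = 400,
                                     fold_change = 1, seed = 44)
  sigs <- derive_signatures(ref$profiles)
  expect_true(all(vapply(sigs, function(s) length(s$genes), 0L) <= 1))

  bc <- bulk_counts(matrix(rpois(300, 20), 100, 3),
                    condition = c("a", "a", "b"))
  expect_error(derive_signatures(bc), "replicate")
})

test_that("the default ranker agrees with an established moderated fit", {
  skip_if_not_installed("limma")
  ref <- simulate_reference_profiles(seed = 3)
  cond <- ref$profiles$condition
  ia <- which(cond == "type1"); ib <- which(cond == "type2")
  mine <- default_de_ranker(ref$profiles$counts, ia, ib)
  sub <- ref$profiles$counts[, c(ia, ib)]
  lg <- log2(sweep(sub, 2, colSums(sub), `/`) * 1e6 + 1)
  design <- cbind(1, rep(c(1, 0), c(length(ia), length(ib))))
  fit <- limma::eBayes(limma::lmFit(lg, design), trend = TRUE)
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  expect_gte(length(intersect(order(tt$P.Value)[1:50],
                              order(mine$FDR, -abs(mine$logFC))[1:50])), 40)
  expect_equal(mine$logFC, tt$logFC, tolerance = 1e-8)
})

test_that("cluster annotation assigns generating types and flags degenerate input", {
  spec <- sc_sim_spec(n_cell_types = 4, cells_per_type = 60, n_genes = 800,
                      conditions = "CTRL", module_fc = c(CTRL = 1), seed = 55)
  sim <- simulate_sc(spec)
  norm <- log_normalize(sim$counts)
  ref <- simulate_reference_profiles(n_cell_types = 4, n_genes = 800,
                                     markers_per_type = 25, seed = 56,
                                     marker_sets = sim$truth$markers,
                                     gene_names = rownames(sim$counts$counts),
                                     cell_types = paste0("type", 1:4))
  sigs <- derive_signatures(ref$profiles)
  truth_int <- as.integer(factor(sim$truth$type))
  ann <- annotate_clusters(norm, truth_int, sigs)
  expect_equal(ann$cell_type, paste0("type", ann$cluster))
  expect_false(any(ann$ambiguous))

  # permuting signature gene order changes nothing
  sigs_perm <- lapply(sigs, function(s) { s$genes <- rev(s$genes); s })
  ann2 <- annotate_clusters(norm, truth_int, sigs_perm)
  expect_equal(attr(ann2, "score_matrix"), attr(ann, "score_matrix"))

  # constant matrix: all scores zero, flagged ambiguous
  const <- structure(list(N = methods::as(
    matrix(1, 800, 20, dimnames = list(rownames(sim$counts$counts), NULL)),
    "CsparseMatrix")), class = "normalized_matrix")
  ann3 <- annotate_clusters(const, rep(1:2, 10), sigs)
  expect_true(all(ann3$ambiguous))
})
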