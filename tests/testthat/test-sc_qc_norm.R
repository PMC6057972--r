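test_that("QC thresholds are strict inequalities at both boundaries", {
  x <- make_boundary_fixture()
  res <- qc_filter(x, qc_params(min_genes = 300, max_mito_ratio = 0.1,
                                min_gene_mean = 0))
  kept <- res$counts$cell_meta$barcode
  expect_false("genes299" %in% kept)   # "less than 300" drops 299
  expect_true("genes300" %in% kept)    # 300 is kept
  expect_true("mito_at" %in% kept)     # exactly 0.1 is kept
  expect_false("mito_over" %in% kept)  # "exceeding 0.1" drops it
  expect_equal(res$report$cells_dropped_genes, 1)
  expect_equal(res$report$cells_dropped_mito, 1)
})

test_that("QC agrees with a brute-force oracle and is idempotent", {
  x <- random_counts_fixture(n_genes = 40, n_cells = 30, seed = 11, lambda = 2)
  par <- qc_params(min_genes = 10, max_mito_ratio = 0.15, min_gene_mean = 100)
  res <- qc_filter(x, par)
  oracle <- oracle_qc(as.matrix(x$counts), x$gene_meta$mito,
                      10, 0.15, 100)
  expect_equal(res$counts$cell_meta$barcode,
               colnames(x$counts)[oracle$cells])
  expect_equal(sort(res$counts$gene_meta$gene),
               sort(rownames(x$counts)[oracle$genes]))
  again <- qc_filter(res$counts, par)
  expect_equal(again$counts$cell_meta$barcode, res$counts$cell_meta$barcode)
  expect_equal(again$report$cells_dropped_genes +
                 again$report$cells_dropped_mito + again$report$genes_dropped, 0)
})

test_that("log-normalization matches its defining formula", {
  x <- random_counts_fixture(seed = 13)
  norm <- log_normalize(x, scale_factor = 1e4)
  m <- as.matrix(x$counts)
  totals <- colSums(m)
  expect_equal(as.matrix(norm$N), log1p(sweep(m, 2, totals, `/`) * 1e4))
  # zero counts stay exactly zero (sparsity preserved)
  expect_equal(length(norm$N@x), length(x$counts@x))
  # per-cell sum(exp(N) - 1) equals the scale factor
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(norm$N)))),
               rep(1e4, ncol(m)), tolerance = 1e-8)
  # single count in a 10000-total cell -> ln 2
  y <- matrix(c(1, 9999), 2, 1)
  expect_equal(log_normalize(sparse_counts(y))$N[1, 1], log(2))
})

test_that("cell-cycle scores respond to planted phase expression", {
  set.seed(17)
  n_genes <- 120; n_cells <- 60
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  rownames(m) <- sprintf("G%03d", seq_len(n_genes))
  s_genes <- rownames(m)[1:8]
  hot <- 1:30 # half the cells strongly express S genes
  m[1:8, hot] <- m[1:8, hot] + 30
  x <- sparse_counts(m)
  norm <- log_normalize(x)
  cov <- cell_covariates(x)
  cov <- cell_cycle_scores(norm, cov, s_genes = s_genes,
                           g2m_genes = rownames(m)[9:16], seed = 1)
  expect_gt(mean(cov$s_score[hot]), mean(cov$s_score[-hot]))
  expect_equal(cov$cc_difference, cov$s_score - cov$g2m_score)

  # identical gene sets cancel exactly
  cov2 <- cell_cycle_scores(norm, cell_covariates(x), s_genes = s_genes,
                            g2m_genes = s_genes, seed = 1)
  expect_equal(cov2$cc_difference, rep(0, n_cells))

  # constant matrix scores zero
  const <- sparse_counts(matrix(2, 50, 20,
                                dimnames = list(sprintf("G%02d", 1:50), NULL)))
  nc <- log_normalize(const)
  cc <- cell_cycle_scores(nc, cell_covariates(const),
                          s_genes = sprintf("G%02d", 1:5),
                          g2m_genes = sprintf("G%02d", 6:10), seed = 1)
  expect_equal(cc$s_score, rep(0, 20), tolerance = 1e-12)

  expect_error(cell_cycle_scores(norm, cov, s_genes = c("NOPE1", "NOPE2"),
                                 g2m_genes = s_genes), "no genes")
})

test_that("covariate regression matches a normal-equations oracle", {
  set.seed(23)
  x <- random_counts_fixture(n_genes = 25, n_cells = 40, seed = 23)
  norm <- log_normalize(x)
  cov <- cell_covariates(x)
  cov$cc_difference <- rnorm(40)
  scaled <- regress_and_scale(norm, cov, clip_max = 1e6)
  X <- cbind(1, cov$n_umi, cov$mito_ratio, cov$cc_difference)
  dense <- as.matrix(norm$N)
  for (i in sample(nrow(dense), 10)) {
    beta <- solve(t(X) %*% X, t(X) %*% dense[i, ])
    r <- dense[i, ] - as.vector(X %*% beta)
    expect_equal(unname(scaled[i, ]), unname((r - mean(r)) / sd(r)),
                 tolerance = 1e-8)
  }
})

test_that("regression degenerates gracefully", {
  x <- random_counts_fixture(n_genes = 20, n_cells = 30, seed = 5)
  norm <- log_normalize(x)
  # gene exactly linear in a covariate scales to all zeros
  cov <- cell_covariates(x)
  dense <- as.matrix(norm$N)
  dense[1, ] <- 2 + 0.5 * cov$n_umi
  norm$N <- as_sparse(dense)
  scaled <- regress_and_scale(norm, cov)
  expect_equal(unname(scaled[1, ]), rep(0, 30), tolerance = 1e-8)

  # constant covariates reduce to a plain per-gene z-score
  cov0 <- cov
  cov0$n_umi <- 1; cov0$mito_ratio <- 0.5; cov0$cc_difference <- 0
  scaled0 <- regress_and_scale(norm, cov0, clip_max = 1e6)
  z <- t(apply(dense, 1, function(r) if (sd(r) > 0) (r - mean(r)) / sd(r) else r * 0))
  expect_equal(unname(scaled0), unname(z), tolerance = 1e-10)
})

test_that("HVG selection applies mean bounds and binned dispersion z-scores", {
  set.seed(29)
  n_cells <- 80
  means <- c(0.005, runif(58, 0.05, 2.5), 10)
  m <- sapply(seq_len(n_cells), function(j) rpois(60, means * 100))
  rownames(m) <- sprintf("G%03d", 1:60)
  m[2, ] <- rep(c(0, 60), length.out = n_cells) * 5 # high dispersion plant
  m[1, 1] <- 1 # keep matrix total sane
  x <- sparse_counts(m)
  norm <- log_normalize(x)
  par <- hvg_params(mean_low = 0.01, mean_high = 500,
                    dispersion_z_cutoff = 0.5, n_bins = 5)
  hvg <- select_hvg(norm, par)
  tab <- attr(hvg, "table")
  # low-mean gene excluded regardless of dispersion
  lowg <- tab$gene[tab$mean <= 0.01]
  expect_false(any(lowg %in% hvg))
  expect_true("G002" %in% hvg)

  # brute-force binned z-score oracle
  C <- exp(as.matrix(norm$N)) - 1
  mu <- rowMeans(C); v <- apply(C, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), 5, labels = FALSE)
  z <- ave(disp, bins, FUN = function(d) {
    if (length(d) < 2 || sd(d) == 0) rep(0, length(d)) else (d - mean(d)) / sd(d)
  })
  keep <- mu > 0.01 & mu <= 500 & z > 0.5
  expect_equal(sort(hvg), sort(rownames(m)[keep]))

  # identical genes: nothing passes
  const <- sparse_counts(matrix(3, 40, 25,
                                dimnames = list(sprintf("G%02d", 1:40), NULL)))
  expect_length(as.character(select_hvg(log_normalize(const),
                                        hvg_params(mean_high = 1e6))), 0)
})

test_that("PCA embedding is a faithful, sign-fixed spectral decomposition", {
  set.seed(31)
  # rank-2 matrix: components 3+ carry no variance
  A <- matrix(rnorm(50 * 2), 50, 2) %*% matrix(rnorm(2 * 30), 2, 30)
  rownames(A) <- sprintf("G%02d", 1:50)
  colnames(A) <- sprintf("c%02d", 1:30)
  emb <- pca_embed(A, rownames(A), n_pcs = 10)
  sdev <- attr(emb, "sdev")
  expect_lt(sum(sdev[3:10]^2), 1e-8)
  expect_true(all(diff(sdev) <= 1e-12))

  # pairwise cell distances match a dense eigendecomposition oracle
  B <- matrix(rnorm(50 * 30), 50, 30,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("c%02d", 1:30)))
  emb <- pca_embed(B, rownames(B), n_pcs = 29)
  Xc <- scale(t(B), center = TRUE, scale = FALSE)
  eig <- eigen(Xc %*% t(Xc), symmetric = TRUE)
  scores <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(scores[, 1:29])),
               tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(pca_embed(B, rownames(B), n_pcs = 40), "exceeds|at least")
})

test_that("normalization and scaling are equivariant under cell permutation", {
  x <- random_counts_fixture(n_genes = 30, n_cells = 24, seed = 37)
  norm <- log_normalize(x)
  cov <- cell_covariates(x)
  scaled <- regress_and_scale(norm, cov)
  perm <- sample(24)
  xp <- subset_counts(x, cells = perm)
  np <- log_normalize(xp)
  sp <- regress_and_scale(np, cell_covariates(xp))
  expect_equal(as.matrix(np$N), as.matrix(norm$N)[, perm])
  expect_equal(sp, scaled[, perm])
})
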