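#!/usr/bin/env Rscript
# Sub-cluster trajectory of a focal cluster: re-select variable genes,
# re-scale, re-embed the subset, cluster at r = 0.5, and connect the
# sub-cluster centroids by a minimum spanning tree whose diameter path is
# reported as the trajectory backbone, with per-node condition
# composition.

suppressMessages(library(tmetools))
seed <- 1L
dir.create("results", showWarnings = FALSE)

counts <- read_mtx_triplet("results/data/sc/matrix.mtx",
                           "results/data/sc/genes.tsv",
                           "results/data/sc/barcodes.tsv",
                           "results/data/sc/metadata.tsv")
qc <- qc_filter(counts)
norm <- log_normalize(qc$counts)
cov <- cell_covariates(qc$counts)
scaled <- regress_and_scale(norm, cov)
hvg <- select_hvg(norm, hvg_params(mean_high = Inf))
emb <- pca_embed(scaled, hvg, n_pcs = 25)
cl <- cluster_cells(emb, cluster_params(resolution = 0.23, seed = seed))

cells <- which(cl == 1) # focal cluster: the largest (labels sorted by size)
message(sprintf("sub-clustering cluster 1 (%d cells) at r = 0.5",
                length(cells)))

sub <- subcluster(norm, cov, cells, hvg_par = hvg_params(mean_high = Inf),
                  params = cluster_params(resolution = 0.5, seed = seed))
message(sprintf("%d sub-clusters", length(unique(sub$assignment))))

conds <- qc$counts$cell_meta$condition[cells]
traj <- mst_over_centroids(sub$assignment, sub$embedding, conds)
write_results(traj, "results/trajectory_mst.json", "json")
print(traj)
print(traj$nodes, row.names = FALSE)

if (nrow(traj$nodes) >= 2) {
  rep_ <- trajectory_report(traj)
  message("backbone: ", paste(rep_$backbone, collapse = " -> "))
  message(sprintf("backbone length %.3f; endpoint conditions: %s, %s",
                  rep_$length, rep_$nodes$dominant_condition[1],
                  rep_$nodes$dominant_condition[nrow(rep_$nodes)]))
  write_results(rep_$nodes, "results/trajectory_backbone.csv", "csv")
}
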