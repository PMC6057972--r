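#!/usr/bin/env Rscript
# Generates every synthetic input used by the downstream analyses and
# writes it in the external formats the pipeline reads (MTX triplet,
# repertoire TSVs + manifest, reference/bulk count TSVs), so later steps
# exercise the full I/O path.

suppressMessages(library(tmetools))
seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## single-cell experiment: 4 myeloid-like populations under three
## conditions, with an interferon-stimulated module induced in IFN+ALL
spec <- sc_sim_spec(n_cell_types = 4, cells_per_type = 40, n_genes = 1000,
                    conditions = c("CTRL", "ALL", "IFN+ALL"),
                    module_fc = c("CTRL" = 1, "ALL" = 1, "IFN+ALL" = 6),
                    marker_fc = 8, seed = seed)
sim <- simulate_sc(spec)
write_mtx_triplet(sim$counts, file.path(out, "sc"))
saveRDS_free <- function(x, path) { # plain-text truth tables only
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
saveRDS_free(data.frame(barcode = colnames(sim$counts$counts),
                        type = sim$truth$type),
             file.path(out, "sc_truth_types.tsv"))
saveRDS_free(data.frame(type = rep(names(sim$truth$markers),
                                   lengths(sim$truth$markers)),
                        gene = unlist(sim$truth$markers)),
             file.path(out, "sc_truth_markers.tsv"))
writeLines(sim$truth$module_genes, file.path(out, "sc_truth_module.txt"))
message(sprintf("single-cell: %d genes x %d cells",
                nrow(sim$counts$counts), ncol(sim$counts$counts)))

## TCR-beta repertoires: 8 mice, three timepoints, shared top clones
## expanded 50x at T2 (emulating re-challenge of surviving mice)
cohort <- simulate_repertoire(rep_sim_spec(n_mice = 8,
                                           expansion = c(1, 1, 50),
                                           expanded_clones = 3,
                                           reads = 1e5, seed = seed))
man <- do.call(rbind, lapply(cohort, function(r) {
  f <- sprintf("rep_%s.tsv", attr(r, "sample_id"))
  utils::write.table(r[, c("template", "count")], file.path(out, f),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  data.frame(path = f, mouse_id = attr(r, "mouse_id"),
             timepoint = attr(r, "timepoint"),
             sample_id = attr(r, "sample_id"))
}))
utils::write.table(man, file.path(out, "rep_manifest.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("repertoires: %d samples, %d reads each", nrow(man), 1e5))

## reference expression profiles matching the single-cell marker truth
ref <- simulate_reference_profiles(n_cell_types = 4, n_genes = 1000,
                                   markers_per_type = 25, seed = seed + 1L,
                                   marker_sets = sim$truth$markers,
                                   gene_names = rownames(sim$counts$counts),
                                   cell_types = paste0("type", 1:4))
utils::write.table(cbind(gene = rownames(ref$profiles$counts),
                         as.data.frame(ref$profiles$counts)),
                   file.path(out, "reference_profiles.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(ref$profiles$condition, file.path(out, "reference_celltypes.txt"))

## bulk counts for the preprocessing filters
set.seed(seed + 2L)
bulk <- matrix(rnbinom(2000 * 6, mu = rlnorm(2000, 3, 2.5), size = 25),
               2000, 6, dimnames = list(sprintf("Gene%04d", 1:2000),
                                        sprintf("s%d", 1:6)))
utils::write.table(cbind(gene = rownames(bulk), as.data.frame(bulk)),
                   file.path(out, "bulk_counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
set.seed(seed + 3L)
utils::write.table(data.frame(gene = rownames(bulk),
                              length = sample(500:5000, 2000, TRUE)),
                   file.path(out, "bulk_lengths.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote synthetic inputs under ", out)
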