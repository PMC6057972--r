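#!/usr/bin/env Rscript
# Bulk RNA-seq preprocessing: expressed-gene filter (CPM > 1 in >= 2
# samples), pairwise sample concordance (R^2 on log2 RPKM of expressed
# genes), and the threshold filter (FDR < 0.01, |logFC| > 1.5) applied
# to an externally supplied differential-expression table.

suppressMessages(library(tmetools))
dir.create("results", showWarnings = FALSE)

bulk <- read_bulk_tsv("results/data/bulk_counts.tsv",
                      "results/data/bulk_lengths.tsv",
                      condition = rep(c("CTRL", "ALL"), each = 3))
expressed <- filter_expressed(bulk, cpm_min = 1, min_samples = 2)
message(sprintf("expressed genes: %d / %d", length(expressed),
                nrow(bulk$counts)))
writeLines(expressed, "results/bulk_expressed_genes.txt")

r2 <- rpkm_r2(bulk, expressed)
write_results(cbind(sample = rownames(r2), as.data.frame(round(r2, 4))),
              "results/bulk_rpkm_r2.csv", "csv")
message("sample concordance (R^2 on log2 RPKM):")
print(round(r2, 3))

# external DE table stand-in: synthetic effects on the expressed genes
set.seed(2L)
de <- data.frame(gene = expressed,
                 logFC = rnorm(length(expressed), 0, 1.2),
                 FDR = runif(length(expressed))^2)
deg <- deg_filter(de, fdr_max = 0.01, abs_logfc_min = 1.5)
message(sprintf("DEGs at FDR < 0.01, |logFC| > 1.5: %d up, %d down",
                length(deg$up), length(deg$down)))
write_results(data.frame(gene = c(deg$up, deg$down),
                         direction = rep(c("up", "down"),
                                         c(length(deg$up),
                                           length(deg$down)))),
              "results/bulk_deg_filtered.csv", "csv")
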