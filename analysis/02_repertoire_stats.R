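#!/usr/bin/env Rscript
# TCR-beta repertoire statistics: per-sample clonality (1 - Pielou's
# evenness) and similarity to the timepoint mean (1 - Bray-Curtis), with
# per-mouse T0 -> T2 arrows. Finds that clonality and cross-mouse
# similarity both rise after the simulated re-challenge expansion.

suppressMessages(library(tmetools))
dir.create("results", showWarnings = FALSE)

cohort <- read_repertoire_manifest("results/data/rep_manifest.tsv")
message(sprintf("loaded %d repertoire samples", length(cohort)))

ls <- longitudinal_summary(cohort)
write_results(ls$per_sample, "results/repertoire_per_sample.csv", "csv")
write_results(ls$arrows, "results/repertoire_arrows.csv", "csv")
write_results(ls$timepoint_means, "results/repertoire_timepoint_means.csv",
              "csv")

print(ls$timepoint_means, row.names = FALSE)
message(sprintf("mice with increased clonality at T2: %d / %d",
                sum(ls$arrows$delta_clonality > 0), nrow(ls$arrows)))
message(sprintf("mean similarity T0 -> T2: %.3f -> %.3f",
                ls$timepoint_means$mean_similarity[1],
                ls$timepoint_means$mean_similarity[
                  nrow(ls$timepoint_means)]))
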