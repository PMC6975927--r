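#!/usr/bin/env Rscript
# Differential screen scoring (experimental minus averaged controls) on the
# simulated score tables, and the sgRNA off-target mismatch scan for the
# UBE2R2-targeting guide.

suppressPackageStartupMessages(library(ubikin))
dir.create("results", showWarnings = FALSE)

experimental <- read_gene_scores("results/data/screen_experimental.tsv",
                                 label = "experimental")
controls <- lapply(1:2, function(i) {
  read_gene_scores(sprintf("results/data/screen_control%d.tsv", i),
                   label = paste0("control", i))
})
diff <- differential_scores(experimental, controls)
ranked <- diff[order(diff$score), ]
cat("top depleted genes (differential score):\n")
print(utils::head(ranked, 5), row.names = FALSE)
cat("planted synthetic-lethal gene ranks #",
    which(ranked$gene == "gene0500"), " of ", nrow(ranked), "\n", sep = "")
write_gene_scores(ranked, "results/screen_differential.tsv")

g <- sgrna_fixtures()
hits <- offtarget_scan(g$guide, g$candidate_sites, max_mismatch = 2)
cat("\noff-target scan of guide ", g$guide, ":\n", sep = "")
print(hits, row.names = FALSE)
utils::write.table(hits, "results/offtarget_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/screen_differential.tsv, results/offtarget_hits.tsv\n")
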