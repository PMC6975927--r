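#!/usr/bin/env Rscript
# Convert the simulated SILAC-SRM spike-in measurements into copies per cell
# and nanomolar cellular concentrations (spherical cell-volume model), and
# compare with the generating truths.

suppressPackageStartupMessages(library(ubikin))
dir.create("results", showWarnings = FALSE)

srm <- utils::read.csv("results/data/srm_samples.csv")
out <- srm_concentration(srm)
truth <- conc_fixtures()
truth <- truth[truth$cell_line == "293T-FiTx", c("protein", "conc_nM")]
names(truth)[2] <- "true_conc_nM"
out <- merge(out, truth, by = "protein")
out$rel_err_pct <- 100 * (out$conc_nM - out$true_conc_nM) / out$true_conc_nM

for (i in seq_len(nrow(out))) {
  cat(sprintf("%-14s %7.0f copies/cell   %7.1f +/- %4.1f nM  (true %6.0f nM, err %+5.1f%%)\n",
              out$protein[i], out$copies_per_cell[i], out$conc_nM[i],
              out$sem_nM[i], out$true_conc_nM[i], out$rel_err_pct[i]))
}
utils::write.csv(out, "results/cell_concentrations.csv", row.names = FALSE)
cat("\nassay concentrations use a 2x enrichment multiplier",
    "(nuclear enrichment of the elongation E2)\n")
cat("wrote results/cell_concentrations.csv\n")
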