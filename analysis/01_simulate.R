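#!/usr/bin/env Rscript
# Generate the synthetic study inputs for every downstream stage: duplicate
# quench-flow time courses for each reference rate set, 2-fold MM titration
# series for each reference Km/kcat pair, replicated SRM spike-in samples,
# and a screen score-table trio with one planted synthetic-lethal gene.

suppressPackageStartupMessages(library(ubikin))
seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("== simulating quench-flow time courses (sd 0.02, duplicates) ==\n")
for (nm in names(quench_fixtures())) {
  d <- gen_quenchflow(quench_fixtures()[[nm]],
                      noise = noise_spec(additive_sd = 0.02, replicates = 2,
                                         seed = seed))
  path <- file.path(out_dir, paste0("quench_", nm, ".csv"))
  write_time_course(d, path)
  cat("  ", nm, ": ", length(d[[1]]$times), " time points x 2 replicates -> ",
      path, "\n", sep = "")
}

cat("== simulating MM titrations (5% CV, duplicates, 10-point 2-fold series) ==\n")
mm <- mm_fixtures()
for (nm in rownames(mm)) {
  p <- mm[nm, ]
  d <- gen_mm_titration(p$kcat_min, p$Km_nM, scf_conc = 10,
                        substrate_conc = 5000, top_conc = 10000,
                        n_dilutions = 10, time = 1,
                        noise = noise_spec(multiplicative_cv = 0.05,
                                           replicates = 2, seed = seed),
                        substrate = p$substrate)
  path <- file.path(out_dir, paste0("mm_", nm, ".csv"))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  cat("  ", nm, " (true Km ", p$Km_nM, " nM, kcat ", p$kcat_min,
      " min^-1) -> ", path, "\n", sep = "")
}

cat("== simulating SRM spike-ins (5% CV, 4 replicates/protein) ==\n")
cc <- conc_fixtures()
cc <- cc[cc$cell_line == "293T-FiTx", ]
srm <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
  gen_srm(cc$conc_nM[i], diameter_um = 12, n_cells = 1e6, spike_fmol = 50,
          noise = noise_spec(multiplicative_cv = 0.05, replicates = 4,
                             seed = seed + i),
          protein = cc$protein[i])
}))
utils::write.csv(srm, file.path(out_dir, "srm_samples.csv"), row.names = FALSE)
cat("  ", nrow(srm), " samples (", length(unique(srm$protein)),
    " proteins) -> ", file.path(out_dir, "srm_samples.csv"), "\n", sep = "")

cat("== simulating CRISPR screen score tables (1000 genes, planted -3 effect) ==\n")
tb <- gen_screen(1000, planted_hits = c(gene0500 = -3),
                 noise = noise_spec(additive_sd = 0.3, seed = seed))
write_gene_scores(tb$experimental, file.path(out_dir, "screen_experimental.tsv"))
for (i in seq_along(tb$controls)) {
  write_gene_scores(tb$controls[[i]],
                    file.path(out_dir, paste0("screen_control", i, ".tsv")))
}
cat("  planted synthetic-lethal effect: gene0500 (-3) among 1000 genes\n")
cat("done.\n")
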