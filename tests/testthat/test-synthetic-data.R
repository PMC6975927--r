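test_that("noise specification validates its fields", {
  expect_error(noise_spec(additive_sd = -1), ">= 0")
  expect_error(noise_spec(replicates = 0), "replicates")
  n <- noise_spec(additive_sd = 0.02, replicates = 2, seed = 7)
  expect_equal(n$replicates, 2L)
})

test_that("quench-flow generator is exact at zero noise and seed-reproducible", {
  k <- c(0.5, 0.2, 0.08)
  clean <- gen_quenchflow(k, noise = noise_spec(additive_sd = 0))
  truth <- closed_form_fractions(k, clean[[1]]$times)
  expect_equal(clean[[1]]$fractions, truth$fractions, tolerance = 1e-12)

  a <- gen_quenchflow(k, noise = noise_spec(additive_sd = 0.02, replicates = 2,
                                            seed = 5))
  b <- gen_quenchflow(k, noise = noise_spec(additive_sd = 0.02, replicates = 2,
                                            seed = 5))
  expect_identical(lapply(a, `[[`, "fractions"), lapply(b, `[[`, "fractions"))
  expect_false(identical(a[[1]]$fractions, a[[2]]$fractions))
  expect_equal(attr(a, "params")$rates, k)
})

test_that("noisy lanes still normalize to unit total per time point", {
  d <- gen_quenchflow(c(1, 0.5), noise = noise_spec(additive_sd = 0.05,
                                                    replicates = 2, seed = 9))
  for (tc in d) expect_equal(rowSums(tc$fractions), rep(1, length(tc$times)))
})

test_that("titration generator inverts the velocity formula", {
  d <- gen_mm_titration(3.7, 317, scf_conc = 10, substrate_conc = 5000,
                        top_conc = 10000, n_dilutions = 10, time = 1,
                        noise = noise_spec())
  # 2-fold series: lowest concentration is top / 2^9
  expect_equal(min(d$enzyme_conc_nM), 10000 / 2^9)
  expect_equal(max(d$enzyme_conc_nM), 10000)
  fit <- fit_michaelis(d)
  expect_equal(fit$Km, 317, tolerance = 1e-6)
  expect_equal(fit$kcat, 3.7, tolerance = 1e-6)
})

test_that("titration generator flags and rejects over-conversion regimes", {
  # long incubation pushes top-concentration conversion past 20%
  d <- gen_mm_titration(3.7, 317, scf_conc = 100, substrate_conc = 5000,
                        top_conc = 10000, n_dilutions = 6, time = 4,
                        noise = noise_spec())
  expect_true(any(d$over_conversion))
  expect_error(
    gen_mm_titration(3.7, 317, scf_conc = 1000, substrate_conc = 500,
                     top_conc = 10000, n_dilutions = 5, time = 10,
                     noise = noise_spec()),
    "fraction_converted > 1")
  expect_error(
    gen_mm_titration(3.7, 317, 10, 5000, 10000, n_dilutions = 2,
                     noise = noise_spec()),
    "n_dilutions")
})

test_that("SRM generator round-trips exactly at zero noise", {
  d <- gen_srm(200, diameter_um = 15, n_cells = 2e6, spike_fmol = 80,
               noise = noise_spec(replicates = 3))
  out <- srm_concentration(d)
  expect_equal(out$conc_nM, 200, tolerance = 1e-9)
  a <- gen_srm(200, 15, 2e6, 80,
               noise = noise_spec(multiplicative_cv = 0.05, replicates = 3,
                                  seed = 4))
  b <- gen_srm(200, 15, 2e6, 80,
               noise = noise_spec(multiplicative_cv = 0.05, replicates = 3,
                                  seed = 4))
  expect_identical(a, b)
})

test_that("screen generator plants recoverable synthetic-lethal effects", {
  tb <- gen_screen(1000, planted_hits = c(gene0042 = -3),
                   noise = noise_spec(additive_sd = 0.3, seed = 11))
  d <- differential_scores(tb$experimental, tb$controls)
  expect_equal(d$gene[which.min(d$score)], "gene0042")

  # no planted hits: differentials centered at zero
  null_tb <- gen_screen(500, noise = noise_spec(additive_sd = 0.3, seed = 3))
  d0 <- differential_scores(null_tb$experimental, null_tb$controls)
  expect_lt(abs(mean(d0$score)), 3 * 0.3 * sqrt(1.5) / sqrt(500))

  a <- gen_screen(100, noise = noise_spec(additive_sd = 0.3, seed = 8))
  b <- gen_screen(100, noise = noise_spec(additive_sd = 0.3, seed = 8))
  expect_identical(a$experimental$score, b$experimental$score)

  expect_error(gen_screen(10, planted_hits = c(`11` = -2)), "out of range")
  expect_error(gen_screen(10, planted_hits = c(geneXYZ = -2)), "out of range")
})

test_that("fixture catalog exposes the reference parameter sets", {
  qf <- quench_fixtures()
  expect_true(all(c("arih1_cycE", "ube2d3_bcat", "ube2r2_sat",
                    "ube2g1_ubcycE") %in% names(qf)))
  expect_equal(qf$arih1_cycE$rates, c(0.5, 0.2, 0.08))
  mm <- mm_fixtures()
  expect_equal(mm["ube2r2_ubcycE", "Km_nM"], 317)
  expect_equal(mm["ube2g1_ubcycE", "kcat_min"], 2.3)
  cc <- conc_fixtures()
  expect_equal(nrow(cc), 24L)
  expect_true("UBE2R1" %in% cc$protein)
  expect_true(all(c("arih1_cycE", "ube2r2_ubcycE") %in% list_fixtures()))
})
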