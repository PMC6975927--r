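test_that("reaction velocity implements the normalization arithmetic", {
  expect_equal(as.numeric(reaction_velocity(0, 1000, 10, 2)), 0)
  expect_equal(as.numeric(reaction_velocity(0.1, 1000, 10, 2)), 5.0)
  expect_error(reaction_velocity(0.1, 1000, 10, 0), "time")
  expect_error(reaction_velocity(0.1, 1000, -1, 2), "scf_conc")
  expect_warning(v <- reaction_velocity(0.5, 1000, 10, 2), "20%")
  expect_true(attr(v, "over_conversion"))
})

test_that("velocity scales linearly and inverse-linearly in its arguments", {
  set.seed(9)
  for (i in 1:10) {
    f <- stats::runif(1, 0, 0.2); s <- stats::runif(1, 100, 5000)
    e <- stats::runif(1, 1, 50); t <- stats::runif(1, 0.5, 10)
    a <- stats::runif(1, 0.5, 3)
    v <- as.numeric(reaction_velocity(f, s, e, t))
    expect_equal(as.numeric(reaction_velocity(f, a * s, e, t)), a * v)
    expect_equal(as.numeric(reaction_velocity(f, s, a * e, t)), v / a)
    expect_equal(as.numeric(reaction_velocity(f, s, e, a * t)), v / a)
  }
})

test_that("Michaelis-Menten fit recovers exact parameters and the half-saturation identity", {
  kcat <- 3.7; Km <- 317    # elongation E2 on mono-ubiquitylated substrate
  d <- gen_mm_titration(kcat, Km, scf_conc = 10, substrate_conc = 5000,
                        top_conc = 10000, n_dilutions = 10, time = 1,
                        noise = noise_spec())
  fit <- fit_michaelis(d)
  expect_true(fit$converged)
  expect_equal(fit$Km, Km, tolerance = 1e-6)
  expect_equal(fit$kcat, kcat, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # fitted curve at [E] = Km gives kcat / 2
  v_at_km <- fit$kcat * Km / (fit$Km + Km)
  expect_equal(v_at_km, kcat / 2, tolerance = 1e-6)
})

test_that("noisy duplicate titrations recover parameters within 20%", {
  kcat <- 3.7; Km <- 317
  d <- gen_mm_titration(kcat, Km, scf_conc = 10, substrate_conc = 5000,
                        top_conc = 10000, n_dilutions = 10, time = 1,
                        noise = noise_spec(multiplicative_cv = 0.05,
                                           replicates = 2, seed = 3))
  fit <- fit_michaelis(d)
  expect_lt(abs(fit$Km - Km) / Km, 0.20)
  expect_lt(abs(fit$kcat - kcat) / kcat, 0.20)
  expect_true(fit$Km_se > 0 && fit$kcat_se > 0)
})

test_that("fitted velocity is monotone in concentration with asymptote kcat", {
  d <- gen_mm_titration(2, 500, scf_conc = 10, substrate_conc = 5000,
                        top_conc = 8000, n_dilutions = 8, time = 1,
                        noise = noise_spec())
  fit <- fit_michaelis(d)
  conc <- sort(unique(d$enzyme_conc_nM))
  v <- fit$kcat * conc / (fit$Km + conc)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < fit$kcat))
})

test_that("degenerate titrations are rejected or flagged", {
  expect_error(
    fit_michaelis(data.frame(enzyme_conc_nM = c(10, 20), velocity = c(1, 2))),
    "insufficient titration points")
  flat <- data.frame(enzyme_conc_nM = c(10, 100, 1000, 10000),
                     velocity = rep(2, 4))
  fit <- suppressWarnings(fit_michaelis(flat))
  expect_true(!fit$converged || fit$Km < 10 || fit$Km > 10000)
})

test_that("catalytic efficiencies reproduce the published comparisons", {
  fast <- catalytic_efficiency(kobs = 40, Km = 317)
  slow <- catalytic_efficiency(kobs = 1.0, Km = 1300)
  expect_equal(fast$efficiency_reported, 1.3e8)
  expect_equal(slow$efficiency_reported, 7.7e5)
  expect_equal(catalytic_efficiency(0, 100)$efficiency, 0)
  expect_error(catalytic_efficiency(1, 0), "positive")
  # unit consistency: doubling Km halves the raw efficiency exactly
  expect_equal(catalytic_efficiency(2, 600)$efficiency,
               catalytic_efficiency(2, 300)$efficiency / 2)
})

test_that("fold ratios reproduce the published initiation-rate comparisons", {
  expect_equal(fold_ratio(5, 0.1)$fold, 50)    # fast priming vs slow substrate
  expect_equal(fold_ratio(5, 0.2)$fold, 25)    # between priming enzymes
  expect_equal(fold_ratio(0.5, 0.1)$fold, 5)
  expect_equal(fold_ratio(3, 3)$fold, 1)
  expect_equal(fold_ratio(5, 0.1)$ratio, 50, tolerance = 1e-12)
  expect_error(fold_ratio(1, 0), "positive")
})
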