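test_that("rate_set validates its inputs", {
  expect_s3_class(rate_set(c(0.5, 0.2)), "rate_set")
  expect_error(rate_set(numeric(0)), "at least one")
  expect_error(rate_set(c(0.5, -0.1)), "non-negative")
  expect_error(rate_set(c(0.5, Inf)), "finite")
  expect_error(rate_set(0.5, dissociation_rate = -1), "non-negative")
})

test_that("no-flux and single-exponential identities hold", {
  tc <- closed_form_fractions(0, times = c(0.5, 1, 100))
  expect_equal(unname(tc$fractions[, "S0"]), rep(1, 3))

  t_half <- log(2) / 0.5
  tc <- closed_form_fractions(0.5, times = t_half)
  expect_equal(unname(tc$fractions[1, "S0"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(tc$fractions[1, "S_ge_1"]), 0.5, tolerance = 1e-12)
})

test_that("three-step chain matches the independent ODE integrator", {
  k <- c(0.5, 0.2, 0.08)
  times <- c(0.1, 1, 5, 10)
  tc <- closed_form_fractions(k, times)
  expect_equal(unname(tc$fractions[4, "S0"]), exp(-5), tolerance = 1e-10)
  # analytic: k1/(k2-k1) (e^{-k1 t} - e^{-k2 t}) at t = 10
  expect_equal(unname(tc$fractions[4, "S1"]),
               0.5 / (0.2 - 0.5) * (exp(-5) - exp(-2)), tolerance = 1e-10)
  oracle <- ode_fractions(k, times)
  expect_lt(max(abs(tc$fractions - oracle)), 1e-8)
})

test_that("degenerate and near-degenerate rate sets stay accurate", {
  times <- c(0.2, 1, 3)
  # exactly equal rates: S1(t) = k t e^{-kt}
  tc <- closed_form_fractions(c(1, 1), times)
  expect_equal(unname(tc$fractions[, "S1"]), times * exp(-times),
               tolerance = 1e-10)
  # gap far below float resolution of the Bateman denominators
  k <- c(0.3, 0.3 + 1e-9, 0.05)
  tc <- closed_form_fractions(k, times)
  expect_lt(max(abs(tc$fractions - ode_fractions(k, times))), 1e-8)
})

test_that("dissociation freezes substrate in its current observed state", {
  k <- c(0.4, 0.15)
  rs <- rate_set(k, dissociation_rate = 0.1)
  times <- c(0.5, 2, 10)
  tc <- closed_form_fractions(rs, times)
  expect_equal(rowSums(tc$fractions), rep(1, 3), tolerance = 1e-9)
  oracle <- ode_fractions(k, times, dissociation_rate = 0.1)
  expect_lt(max(abs(tc$fractions - oracle)), 1e-8)
  # with release active, less substrate reaches the terminal aggregate
  tc0 <- closed_form_fractions(rate_set(k), times)
  expect_lt(tc$fractions[3, "S_ge_2"], tc0$fractions[3, "S_ge_2"])
})

test_that("closed form rejects invalid rates and grids", {
  expect_error(closed_form_fractions(c(0.5, -1), 1), "non-negative")
  expect_error(closed_form_fractions(0.5, c(2, 1)), "strictly increasing")
  expect_error(closed_form_fractions(0.5, -1), "non-negative")
  expect_error(closed_form_fractions(c(0.5, 0.2), 1, n_tracked = 3), "n_tracked")
})

test_that("conservation and monotonicity hold for random rate sets", {
  set.seed(42)
  for (i in 1:25) {
    k <- random_rate_set(sample(1:4, 1), degenerate = i %% 5 == 0)
    times <- sort(10^stats::runif(8, -2, 1.2))
    tc <- closed_form_fractions(k, times)
    expect_true(all(abs(rowSums(tc$fractions) - 1) <= 1e-9))
    expect_true(all(tc$fractions >= 0 & tc$fractions <= 1))
    expect_true(all(diff(tc$fractions[, 1]) <= 1e-12))
    expect_true(all(diff(tc$fractions[, ncol(tc$fractions)]) >= -1e-12))
  }
})

test_that("stochastic simulator is seed-reproducible and converges to the closed form", {
  k <- c(0.5, 0.2, 0.08)
  times <- c(1, 5, 10)
  a <- stochastic_encounter(k, 10000, times, seed = 1)
  b <- stochastic_encounter(k, 10000, times, seed = 1)
  expect_identical(a$fractions, b$fractions)

  truth <- closed_form_fractions(k, times)$fractions
  bound <- 3 * sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(a$fractions - truth) <= pmax(bound, 1e-12) + 1e-12))

  # no-flux chain leaves every molecule unmodified
  z <- stochastic_encounter(c(0, 0), 500, times, seed = 2)
  expect_equal(unname(z$fractions[, "S0"]), rep(1, 3))
  expect_error(stochastic_encounter(k, 0, times, seed = 1), "n_molecules")
})

test_that("stochastic simulator honours dissociation on average", {
  k <- c(1, 1)
  times <- c(0.5, 2)
  rs <- rate_set(k, dissociation_rate = 0.5)
  emp <- stochastic_encounter(rs, 20000, times, seed = 7)$fractions
  truth <- closed_form_fractions(rs, times)$fractions
  expect_lt(max(abs(emp - truth)), 4 * sqrt(0.25 / 20000) + 0.005)
})

test_that("distribution summaries compute weighted chain-length statistics", {
  # distribution entirely S0
  tc <- closed_form_fractions(0, times = 10)
  s <- distribution_summary(tc, 10, threshold_length = 4)
  expect_equal(s$mean_length, 0)
  expect_equal(s$fraction_ge, 0)

  # hand-built {S1: 0.5, S3(terminal): 0.5}
  tc2 <- time_course(10, matrix(c(0, 0.5, 0, 0.5), 1,
                                dimnames = list(NULL, c("S0", "S1", "S2", "S_ge_3"))))
  s2 <- distribution_summary(tc2, 10, threshold_length = 3)
  expect_equal(s2$mean_length, 2.0)
  expect_equal(s2$fraction_ge, 0.5)

  # summary equals hand-computed weighted sums from the closed-form vector
  k <- c(0.5, 0.2, 0.08)
  tc3 <- closed_form_fractions(k, times = c(1, 10))
  s3 <- distribution_summary(tc3, 10, threshold_length = 2)
  frac <- tc3$fractions[2, ]
  expect_equal(s3$mean_length, sum(frac * c(0, 1, 2, 3)))
  expect_equal(s3$fraction_ge, unname(frac[3] + frac[4]))

  expect_error(distribution_summary(tc3, 3.3), "not on the time grid")
  s_int <- distribution_summary(tc3, 3.3, threshold_length = 2,
                                interpolate = TRUE)
  expect_true(s_int$mean_length > 0)
  # threshold beyond the tracked chain warns that the tail is a lower bound
  expect_warning(distribution_summary(tc3, 10, threshold_length = 4),
                 "lower bound")
})

test_that("time-course CSV round-trips replicates", {
  d <- gen_quenchflow(c(0.5, 0.2), times = c(0.1, 1, 10),
                      noise = noise_spec(additive_sd = 0.01, replicates = 2,
                                         seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_time_course(d, path)
  back <- read_time_course(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$fractions, d[[1]]$fractions, tolerance = 1e-12)
  expect_equal(back[[2]]$replicate_id, "rep2")
})
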