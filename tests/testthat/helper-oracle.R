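# Independent numerical oracle for the sequential-chain model: adaptive ODE
# integration of the rate equations (deSolve::lsoda), written directly from
# the derivative definitions rather than any closed form.
ode_fractions <- function(rates, times, dissociation_rate = 0) {
  n <- length(rates)
  deriv <- function(t, y, parms) {
    k <- parms$k
    d <- parms$d
    b <- y[seq_len(n)]                       # bound S0 .. S(n-1)
    inflow <- c(0, k[-n] * b[-n])
    db <- inflow - (k + d) * b
    dr <- d * b                              # released pools per state
    dterm <- k[n] * b[n]
    list(c(db, dr, dterm))
  }
  y0 <- c(1, rep(0, 2 * n))
  tgrid <- times
  prepend0 <- tgrid[1] > 0
  if (prepend0) tgrid <- c(0, tgrid)
  sol <- deSolve::lsoda(y0, tgrid, deriv,
                        parms = list(k = rates, d = dissociation_rate),
                        rtol = 1e-12, atol = 1e-14)
  sol <- sol[, -1, drop = FALSE]
  if (prepend0) sol <- sol[-1, , drop = FALSE]
  obs <- sol[, seq_len(n), drop = FALSE] + sol[, n + seq_len(n), drop = FALSE]
  cbind(obs, sol[, 2 * n + 1])
}

# log-uniform random rate sets over the plausible kobs range, optionally
# forcing a near-degenerate pair (absolute gap below `degenerate_gap`)
random_rate_set <- function(n_rates, degenerate = FALSE,
                            degenerate_gap = 1e-6) {
  k <- 10^stats::runif(n_rates, log10(0.01), log10(50))
  if (degenerate && n_rates >= 2) {
    i <- sample(n_rates, 2)
    k[i[2]] <- k[i[1]] + stats::runif(1, -degenerate_gap, degenerate_gap)
    k[i[2]] <- max(k[i[2]], 1e-6)
  }
  k
}
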