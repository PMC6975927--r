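#' Per-step ubiquitin-transfer rate constants
#'
#' Container for the ordered transfer rate constants of a sequential
#' single-encounter poly-ubiquitylation chain S0 -> S1 -> ... -> S(n-1) ->
#' S(>=n).  `rates[i]` is the first-order rate constant (per second) of the
#' i-th ubiquitin transfer, i.e. conversion of species S(i-1) into S(i).
#' An optional per-state dissociation rate models substrate release from the
#' ligase; released substrate keeps the chain length it had at release, so
#' observed species are the sum of bound and released molecules.
#'
#' @param rates numeric vector of transfer rate constants, per second, all
#'   finite and >= 0, at least one element.
#' @param dissociation_rate single finite number >= 0, per second; substrate
#'   release rate applied uniformly to every non-terminal state. Default 0
#'   (rates interpreted as observed single-encounter kobs).
#' @return an object of class `rate_set`.
#' @export
rate_set <- function(rates, dissociation_rate = 0) {
  if (length(rates) < 1L) {
    stop("'rates' must contain at least one transfer rate constant")
  }
  if (!is.numeric(rates) || anyNA(rates) || any(!is.finite(rates))) {
    stop("'rates' must be finite numeric values")
  }
  if (any(rates < 0)) {
    stop("'rates' must be non-negative")
  }
  if (!is.numeric(dissociation_rate) || length(dissociation_rate) != 1L ||
      !is.finite(dissociation_rate) || dissociation_rate < 0) {
    stop("'dissociation_rate' must be a single finite non-negative number")
  }
  structure(
    list(rates = as.numeric(rates),
         dissociation_rate = as.numeric(dissociation_rate)),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Sequential transfer rate set (", length(x$rates), " steps)\n", sep = "")
  cat("  k (s^-1): ", paste(signif(x$rates, 4), collapse = ", "), "\n", sep = "")
  if (x$dissociation_rate > 0) {
    cat("  dissociation (s^-1): ", signif(x$dissociation_rate, 4), "\n", sep = "")
  }
  invisible(x)
}

as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) x else rate_set(x)
}

species_labels <- function(n_tracked) {
  c(paste0("S", seq_len(n_tracked) - 1L), paste0("S_ge_", n_tracked))
}

#' Time course of species fractions
#'
#' A time grid and matrix of species fractions S0 .. S(m-1) plus the terminal
#' aggregate S_ge_m.  Model output rows sum to 1 within 1e-9; measured data
#' may deviate within its declared noise tolerance.
#'
#' @param times numeric vector of times in seconds, strictly increasing, >= 0.
#' @param fractions numeric matrix, one row per time point, columns named
#'   `S0, S1, ..., S_ge_<m>`.
#' @param replicate_id optional replicate label.
#' @param check if `TRUE` (default), enforce model-output invariants
#'   (rows sum to 1 within 1e-9, entries in \[0, 1\]).
#' @return an object of class `time_course`.
#' @export
time_course <- function(times, fractions, replicate_id = NULL, check = TRUE) {
  times <- as.numeric(times)
  fractions <- as.matrix(fractions)
  if (anyNA(times) || any(times < 0)) stop("'times' must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (nrow(fractions) != length(times)) {
    stop("'fractions' must have one row per time point")
  }
  if (is.null(colnames(fractions))) {
    colnames(fractions) <- species_labels(ncol(fractions) - 1L)
  }
  if (check) {
    if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9)) {
      stop("fractions must lie in [0, 1]")
    }
    if (any(abs(rowSums(fractions) - 1) > 1e-9)) {
      stop("each fraction row must sum to 1 within 1e-9")
    }
  }
  structure(
    list(times = times, fractions = fractions, replicate_id = replicate_id),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat("Ubiquitylation time course: ", length(x$times), " time points, ",
      ncol(x$fractions), " species (", paste(colnames(x$fractions), collapse = ", "),
      ")\n", sep = "")
  if (!is.null(x$replicate_id)) cat("  replicate: ", x$replicate_id, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  df <- data.frame(time_s = x$times, x$fractions, check.names = FALSE)
  if (!is.null(x$replicate_id)) df$replicate <- x$replicate_id
  df
}

# Bateman sum-of-exponentials for pairwise-distinct rates, no dissociation.
# Returns [time x (n_tracked + 1)] fraction matrix.
bateman_fractions <- function(k, times) {
  n <- length(k)
  out <- matrix(0, length(times), n + 1L)
  decay <- exp(-outer(times, k))          # [t x n]
  out[, 1L] <- decay[, 1L]
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {          # species S_i, i = 1 .. n-1
      idx <- seq_len(i + 1L)
      coef <- vapply(idx, function(j) {
        1 / prod(k[setdiff(idx, j)] - k[j])
      }, numeric(1))
      out[, i + 1L] <- prod(k[seq_len(i)]) * drop(decay[, idx, drop = FALSE] %*% coef)
    }
  }
  out[, n + 1L] <- pmax(0, 1 - rowSums(out[, seq_len(n), drop = FALSE]))
  out
}

# Lower-bidiagonal generator of the bound-state chain, optionally augmented
# with released-substrate pools when dissociation is active.
chain_generator <- function(k, dissociation_rate = 0) {
  n <- length(k)
  if (dissociation_rate == 0) {
    q <- matrix(0, n + 1L, n + 1L)
    for (i in seq_len(n)) {
      q[i, i] <- -k[i]
      q[i + 1L, i] <- k[i]
    }
    q
  } else {
    # states: bound S0..S(n-1) [1..n], released S0..S(n-1) [n+1..2n],
    # terminal aggregate [2n+1]
    d <- dissociation_rate
    q <- matrix(0, 2L * n + 1L, 2L * n + 1L)
    for (i in seq_len(n)) {
      q[i, i] <- -(k[i] + d)
      q[n + i, i] <- d
      if (i < n) q[i + 1L, i] <- k[i] else q[2L * n + 1L, i] <- k[i]
    }
    q
  }
}

expm_fractions <- function(k, times, dissociation_rate = 0) {
  n <- length(k)
  q <- chain_generator(k, dissociation_rate)
  p0 <- numeric(nrow(q)); p0[1L] <- 1
  out <- matrix(0, length(times), n + 1L)
  for (ti in seq_along(times)) {
    p <- as.numeric(Matrix::expm(q * times[ti]) %*% p0)
    if (dissociation_rate == 0) {
      out[ti, ] <- p
    } else {
      out[ti, seq_len(n)] <- p[seq_len(n)] + p[n + seq_len(n)]
      out[ti, n + 1L] <- p[2L * n + 1L]
    }
  }
  pmin(pmax(out, 0), 1)
}

# Bateman denominators lose ~1e-8 absolute accuracy once relative rate gaps
# shrink below ~1e-7, so the switch to the matrix exponential happens well
# before that.
DEGENERACY_TOL <- 1e-5

rates_degenerate <- function(k) {
  mx <- max(k)
  if (mx == 0) return(TRUE)
  if (length(k) == 1L) return(FALSE)
  min(abs(diff(sort(k)))) / mx < DEGENERACY_TOL
}

#' Closed-form species fractions of the sequential chain
#'
#' Exact solution of dS0/dt = -k1 S0, dSi/dt = ki S(i-1) - k(i+1) Si for
#' i < n_tracked, with the terminal aggregate S_ge_n absorbing the flux
#' kn S(n-1) and initial condition S0(0) = 1.  Pairwise-distinct rates use
#' the Bateman sum-of-exponentials; near-degenerate rate sets (or any run
#' with dissociation) fall back to a matrix exponential of the chain
#' generator, which avoids catastrophic cancellation.
#'
#' @param rates a [rate_set] or numeric vector of transfer rates (s^-1).
#' @param times numeric vector of times (seconds), strictly increasing, >= 0.
#' @param n_tracked number of explicitly tracked species beyond S0 (i.e. the
#'   number of transfer steps modelled); defaults to `length(rates)`.
#' @return a [time_course] with columns `S0 .. S(n_tracked-1), S_ge_<n_tracked>`.
#' @examples
#' tc <- closed_form_fractions(c(0.5, 0.2, 0.08), times = c(1, 5, 10))
#' as.data.frame(tc)
#' @export
closed_form_fractions <- function(rates, times, n_tracked = NULL) {
  rs <- as_rate_set(rates)
  times <- as.numeric(times)
  if (anyNA(times) || any(times < 0)) stop("'times' must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (is.null(n_tracked)) n_tracked <- length(rs$rates)
  if (n_tracked < 1L || n_tracked > length(rs$rates)) {
    stop("'n_tracked' must be between 1 and the number of rates")
  }
  k <- rs$rates[seq_len(n_tracked)]
  frac <- if (rs$dissociation_rate > 0 || rates_degenerate(k)) {
    expm_fractions(k, times, rs$dissociation_rate)
  } else {
    bateman_fractions(k, times)
  }
  colnames(frac) <- species_labels(n_tracked)
  # clip float dust so model-output invariants hold exactly
  frac <- pmin(pmax(frac, 0), 1)
  frac <- frac / rowSums(frac)
  time_course(times, frac)
}

#' Stochastic single-encounter simulation of the chain
#'
#' Simulates each substrate molecule independently through the sequential
#' chain with exponential waiting times at each transfer step, and returns
#' the empirical species fractions on the requested time grid.  With a fixed
#' seed the output is reproducible; as `n_molecules` grows the fractions
#' converge to [closed_form_fractions()].
#'
#' @inheritParams closed_form_fractions
#' @param n_molecules number of independent substrate molecules (>= 1).
#' @param seed integer RNG seed.
#' @return a [time_course] of empirical fractions.
#' @export
stochastic_encounter <- function(rates, n_molecules, times, seed,
                                 n_tracked = NULL) {
  rs <- as_rate_set(rates)
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L || n_molecules < 1) {
    stop("'n_molecules' must be a single count >= 1")
  }
  n_molecules <- as.integer(n_molecules)
  times <- as.numeric(times)
  if (anyNA(times) || any(times < 0)) stop("'times' must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (is.null(n_tracked)) n_tracked <- length(rs$rates)
  if (n_tracked < 1L || n_tracked > length(rs$rates)) {
    stop("'n_tracked' must be between 1 and the number of rates")
  }
  k <- rs$rates[seq_len(n_tracked)]
  d <- rs$dissociation_rate

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  # waiting time in each state; Inf where the transfer rate is zero
  draw_wait <- function(rate) {
    w <- rep(Inf, n_molecules)
    if (rate > 0) w <- stats::rexp(n_molecules, rate)
    w
  }
  # time at which molecule completes step i (cumulative); dissociation
  # freezes a molecule in its current observed state
  completion <- matrix(Inf, n_molecules, n_tracked)
  now <- numeric(n_molecules)
  frozen <- rep(FALSE, n_molecules)
  for (i in seq_len(n_tracked)) {
    wait <- draw_wait(k[i])
    if (d > 0) {
      release <- stats::rexp(n_molecules, d)
      frozen_here <- !frozen & release < wait
      frozen <- frozen | frozen_here
    }
    now <- now + wait
    completion[!frozen, i] <- now[!frozen]
    completion[frozen, i] <- Inf
  }

  frac <- matrix(0, length(times), n_tracked + 1L)
  for (ti in seq_along(times)) {
    n_done <- rowSums(completion <= times[ti])
    counts <- tabulate(n_done + 1L, nbins = n_tracked + 1L)
    frac[ti, ] <- counts / n_molecules
  }
  colnames(frac) <- species_labels(n_tracked)
  time_course(times, frac)
}

#' Species distribution and chain-length summaries at a fixed time
#'
#' Extracts the per-species distribution at time `t` from a time course and
#' summarises it as the mean number of ubiquitins per substrate molecule and
#' the fraction of substrate carrying at least `threshold_length` ubiquitins.
#' The terminal aggregate S_ge_n is counted at its lower bound of n
#' ubiquitins, so the mean is itself a lower bound when the aggregate is
#' occupied.
#'
#' @param tc a [time_course].
#' @param t time in seconds; must be on the grid unless `interpolate = TRUE`,
#'   in which case fractions are interpolated linearly.
#' @param threshold_length chain-length threshold (>= 1) for the tail
#'   fraction.
#' @param interpolate allow linear interpolation at off-grid times
#'   (default `FALSE`).
#' @return an object of class `species_distribution` with elements
#'   `fractions`, `mean_length`, `fraction_ge`, `threshold_length`, `time`.
#' @export
distribution_summary <- function(tc, t, threshold_length = 4L,
                                 interpolate = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  if (threshold_length < 1L) stop("'threshold_length' must be >= 1")
  hit <- which(abs(tc$times - t) <= 1e-9)
  if (length(hit) == 1L) {
    frac <- tc$fractions[hit, ]
  } else if (interpolate) {
    if (t < min(tc$times) || t > max(tc$times)) {
      stop("'t' outside the time grid; cannot interpolate")
    }
    frac <- apply(tc$fractions, 2L, function(y) {
      stats::approx(tc$times, y, xout = t)$y
    })
    frac <- frac / sum(frac)
  } else {
    stop("'t' is not on the time grid (set interpolate = TRUE to interpolate)")
  }
  n_tracked <- length(frac) - 1L
  lengths <- c(seq_len(n_tracked) - 1L, n_tracked)  # terminal counted as n
  mean_length <- sum(frac * lengths)
  in_tail <- lengths >= threshold_length
  fraction_ge <- sum(frac[in_tail])
  if (threshold_length > n_tracked && frac[n_tracked + 1L] > 0) {
    warning("threshold exceeds tracked chain length; tail fraction is a lower bound")
  }
  structure(
    list(fractions = frac, mean_length = mean_length,
         fraction_ge = fraction_ge, threshold_length = threshold_length,
         time = t),
    class = "species_distribution"
  )
}

#' @export
print.species_distribution <- function(x, ...) {
  cat("Species distribution at t = ", x$time, " s\n", sep = "")
  print(signif(x$fractions, 4))
  cat("  mean ubiquitins/substrate: ", signif(x$mean_length, 4), "\n", sep = "")
  cat("  fraction with >= ", x$threshold_length, " ubiquitins: ",
      signif(x$fraction_ge, 4), "\n", sep = "")
  invisible(x)
}

#' Read / write time-course CSV
#'
#' CSV dialect: columns `time_s, S0, S1, ..., S_ge_<n>[, replicate]`, one row
#' per time point per replicate.
#'
#' @param path file path.
#' @return `read_time_course()` returns a list of [time_course] objects, one
#'   per replicate.
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column")
  species <- grep("^S[0-9]+$|^S_ge_[0-9]+$", names(df), value = TRUE)
  if (length(species) < 2L) stop("need at least two species columns")
  reps <- if ("replicate" %in% names(df)) unique(df$replicate) else NA
  lapply(reps, function(r) {
    sub <- if (is.na(r)[1]) df else df[df$replicate == r, , drop = FALSE]
    sub <- sub[order(sub$time_s), , drop = FALSE]
    frac <- as.matrix(sub[species])
    rownames(frac) <- NULL
    time_course(sub$time_s, frac,
                replicate_id = if (is.na(r)[1]) NULL else r,
                check = FALSE)
  })
}

#' @param tcs a [time_course] or list of them (replicates).
#' @rdname read_time_course
#' @export
write_time_course <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  df <- do.call(rbind, lapply(tcs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
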