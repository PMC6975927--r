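#' Multi-turnover reaction velocity
#'
#' Velocity of a multi-turnover ubiquitylation reaction, normalized for
#' substrate and ligase concentrations:
#' v = (fraction_converted * substrate_conc) / (scf_conc * time),
#' in substrate turnovers per SCF per minute.  Points that converted more
#' than 20% of substrate violate the initial-velocity assumption and are
#' flagged (attribute `over_conversion`) with a warning.
#'
#' @param fraction_converted fraction of substrate converted to product,
#'   in \[0, 1\]; vectorized.
#' @param substrate_conc substrate concentration, nM.
#' @param scf_conc SCF (ligase) concentration, nM.
#' @param time incubation time, minutes.
#' @return numeric velocity (min^-1) with logical attribute
#'   `over_conversion`.
#' @examples
#' reaction_velocity(0.1, substrate_conc = 1000, scf_conc = 10, time = 2)
#' @export
reaction_velocity <- function(fraction_converted, substrate_conc, scf_conc,
                              time) {
  if (any(time <= 0)) stop("'time' must be positive")
  if (any(scf_conc <= 0)) stop("'scf_conc' must be positive")
  if (any(substrate_conc <= 0)) stop("'substrate_conc' must be positive")
  if (any(fraction_converted < 0 | fraction_converted > 1)) {
    stop("'fraction_converted' must lie in [0, 1]")
  }
  over <- fraction_converted > 0.20
  if (any(over)) {
    warning(sum(over), " point(s) exceed 20% substrate conversion; ",
            "initial-velocity assumption may not hold")
  }
  v <- (fraction_converted * substrate_conc) / (scf_conc * time)
  attr(v, "over_conversion") <- over
  v
}

#' Titration dataset for Michaelis-Menten fitting
#'
#' @param df data.frame with columns `enzyme_conc_nM, fraction_converted,
#'   substrate_conc_nM, scf_conc_nM, time_min` and optionally `replicate`.
#' @param substrate substrate identity label.
#' @return an object of class `mm_dataset` (a data.frame).
#' @export
mm_dataset <- function(df, substrate = NA_character_) {
  need <- c("enzyme_conc_nM", "fraction_converted", "substrate_conc_nM",
            "scf_conc_nM", "time_min")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(unique(df$enzyme_conc_nM)) < 3L) {
    stop("insufficient titration points: need >= 3 distinct enzyme concentrations")
  }
  structure(df, class = c("mm_dataset", "data.frame"), substrate = substrate)
}

#' Read a titration CSV
#'
#' Columns: `enzyme_conc_nM, fraction_converted, substrate_conc_nM,
#' scf_conc_nM, time_min[, replicate]`.
#'
#' @param path file path.
#' @param substrate optional substrate label.
#' @export
read_mm_dataset <- function(path, substrate = NA_character_) {
  mm_dataset(utils::read.csv(path), substrate = substrate)
}

#' Fit the Michaelis-Menten equation to a titration series
#'
#' Nonlinear least squares fit of v = kcat * \[E\] / (Km + \[E\]) to reaction
#' velocities computed from a 2-fold enzyme dilution series, where the
#' titrated E2/E3 takes the role of the varied species.  Initialization:
#' Km at the median titration concentration, kcat at 1.2x the maximum
#' observed velocity.  R-squared is computed against the mean model
#' (1 - SS_res / SS_tot).
#'
#' @param data an [mm_dataset], or a data.frame with columns
#'   `enzyme_conc_nM` and `velocity`.
#' @return an object of class `mm_fit`: `Km` (nM), `kcat` (min^-1),
#'   `Km_se`, `kcat_se`, `r_squared`, `converged`.
#' @export
fit_michaelis <- function(data) {
  if (inherits(data, "mm_dataset")) {
    v <- suppressWarnings(reaction_velocity(
      data$fraction_converted, data$substrate_conc_nM,
      data$scf_conc_nM, data$time_min))
    df <- data.frame(conc = data$enzyme_conc_nM, v = as.numeric(v))
  } else {
    if (!all(c("enzyme_conc_nM", "velocity") %in% names(data))) {
      stop("need columns 'enzyme_conc_nM' and 'velocity'")
    }
    df <- data.frame(conc = data$enzyme_conc_nM, v = data$velocity)
  }
  if (length(unique(df$conc)) < 3L) {
    stop("insufficient titration points: need >= 3 distinct enzyme concentrations")
  }

  start <- list(Km = stats::median(unique(df$conc)), kcat = 1.2 * max(df$v))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * conc / (Km + conc), data = df, start = start,
                      lower = c(Km = 1e-9, kcat = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(Km = NA_real_, kcat = NA_real_, Km_se = NA_real_,
                          kcat_se = NA_real_, r_squared = NA_real_,
                          converged = FALSE),
                     class = "mm_fit"))
  }
  co <- summary(fit)$coefficients
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$v - mean(df$v))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  km <- co["Km", "Estimate"]
  if (km < min(df$conc) || km > max(df$conc)) {
    warning("fitted Km lies outside the titration range; estimate may be poorly constrained")
  }
  structure(
    list(Km = km, kcat = co["kcat", "Estimate"],
         Km_se = co["Km", "Std. Error"], kcat_se = co["kcat", "Std. Error"],
         r_squared = r2, converged = TRUE, fit = fit),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit: DID NOT CONVERGE\n")
    return(invisible(x))
  }
  cat("Michaelis-Menten fit\n")
  cat("  Km   = ", signif(x$Km, 3), " +/- ", signif(x$Km_se, 2), " nM\n", sep = "")
  cat("  kcat = ", signif(x$kcat, 3), " +/- ", signif(x$kcat_se, 2), " min^-1\n", sep = "")
  cat("  R^2  = ", round(x$r_squared, 2), "\n", sep = "")
  invisible(x)
}

#' Catalytic efficiency kobs / Km
#'
#' Converts an observed single-encounter transfer rate (s^-1) and a
#' Michaelis constant (nM) into a second-order catalytic efficiency in
#' M^-1 s^-1 (the nM Km is converted to molar internally).  The reported
#' value is rounded to `sig_figs` significant figures; the raw value is
#' retained.
#'
#' @param kobs observed transfer rate constant, s^-1 (>= 0).
#' @param Km Michaelis constant, nM (> 0).
#' @param sig_figs significant figures for the reported value (default 2).
#' @return an object of class `efficiency_record`: `kobs`, `Km_nM`,
#'   `efficiency` (raw, M^-1 s^-1), `efficiency_reported` (rounded),
#'   `sig_figs`.
#' @examples
#' catalytic_efficiency(kobs = 40, Km = 317)   # ~1.3e8 M^-1 s^-1
#' @export
catalytic_efficiency <- function(kobs, Km, sig_figs = 2L) {
  if (any(kobs < 0)) stop("'kobs' must be >= 0")
  if (any(Km <= 0)) stop("'Km' must be positive")
  eff <- kobs / (Km * 1e-9)
  structure(
    list(kobs = kobs, Km_nM = Km, efficiency = eff,
         efficiency_reported = signif(eff, sig_figs), sig_figs = sig_figs),
    class = "efficiency_record"
  )
}

#' @export
print.efficiency_record <- function(x, ...) {
  cat("Catalytic efficiency: ",
      format(x$efficiency_reported, scientific = TRUE), " M^-1 s^-1",
      " (kobs = ", x$kobs, " s^-1, Km = ", x$Km_nM, " nM)\n", sep = "")
  invisible(x)
}

#' Fold ratio between two rates or efficiencies
#'
#' @param a,b positive rates or efficiencies in the same units; `b > 0`.
#' @return list with `ratio` (unrounded a/b) and `fold` (nearest integer).
#' @examples
#' fold_ratio(5, 0.1)$fold   # 50
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) stop("'b' must be positive")
  ratio <- a / b
  list(ratio = ratio, fold = round(ratio))
}
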