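#' Noise specification for synthetic datasets
#'
#' @param additive_sd additive Gaussian SD applied on the fraction scale to
#'   raw band intensities (pre-normalization) for densitometry-like data,
#'   or directly to scores for screen tables.
#' @param multiplicative_cv coefficient of variation of multiplicative
#'   Gaussian noise for velocities and spike-in ratios.
#' @param replicates number of technical replicates (>= 1).
#' @param seed integer RNG seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(additive_sd = 0, multiplicative_cv = 0,
                       replicates = 1L, seed = 1L) {
  if (additive_sd < 0 || multiplicative_cv < 0) {
    stop("noise magnitudes must be >= 0")
  }
  if (replicates < 1L) stop("'replicates' must be >= 1")
  structure(list(additive_sd = additive_sd,
                 multiplicative_cv = multiplicative_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(code)
}

BAND_SCALE <- 1e4

#' Synthetic quench-flow densitometry time courses
#'
#' Generates replicate time courses the way a gel produces them: closed-form
#' species fractions are scaled to band intensities (total lane signal 1e4),
#' additive Gaussian noise is applied on the intensity scale, negatives are
#' clipped to zero, and each lane is renormalized to fractions.  Applying
#' noise before normalization induces the mild anticorrelation between
#' species fractions seen in real lane data.
#'
#' @param rates a [rate_set] or numeric rate vector (s^-1).
#' @param times time grid in seconds (default: 20 log-spaced points,
#'   0.01-10 s, the quench-flow range).
#' @param noise a [noise_spec]; `additive_sd` is interpreted on the fraction
#'   scale.
#' @return list of [time_course] objects, one per replicate, tagged
#'   `rep1, rep2, ...`; the generating parameters are attached as the
#'   `params` attribute.
#' @export
gen_quenchflow <- function(rates, times = default_quench_times(),
                           noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  rs <- as_rate_set(rates)
  clean <- closed_form_fractions(rs, times)
  with_seed(noise$seed, {
    out <- lapply(seq_len(noise$replicates), function(r) {
      bands <- clean$fractions * BAND_SCALE
      if (noise$additive_sd > 0) {
        bands <- bands + stats::rnorm(length(bands),
                                      sd = noise$additive_sd * BAND_SCALE)
        bands[bands < 0] <- 0
      }
      frac <- t(apply(bands, 1L, lane_to_fractions))
      colnames(frac) <- colnames(clean$fractions)
      time_course(clean$times, frac, replicate_id = paste0("rep", r),
                  check = FALSE)
    })
    attr(out, "params") <- list(rates = rs$rates,
                                dissociation_rate = rs$dissociation_rate,
                                noise = noise)
    out
  })
}

#' Synthetic Michaelis-Menten titration series
#'
#' Builds a 2-fold enzyme dilution series from `top_conc` downwards, computes
#' true velocities from the MM equation, converts them to observed
#' fraction-converted values by inverting the velocity formula, and applies
#' multiplicative noise.  Points whose true conversion exceeds the 20%
#' initial-velocity rule are flagged.
#'
#' @param kcat turnover number, min^-1.
#' @param Km Michaelis constant, nM.
#' @param scf_conc SCF concentration, nM.
#' @param substrate_conc substrate concentration, nM.
#' @param top_conc highest enzyme concentration of the series, nM.
#' @param n_dilutions number of 2-fold dilutions (>= 3).
#' @param time incubation time, minutes.
#' @param noise a [noise_spec]; `multiplicative_cv` applies to the
#'   fraction-converted values.
#' @param substrate substrate label.
#' @return an [mm_dataset] with one row per concentration per replicate and
#'   a logical `over_conversion` column.
#' @export
gen_mm_titration <- function(kcat, Km, scf_conc, substrate_conc, top_conc,
                             n_dilutions = 10L, time = 2,
                             noise = noise_spec(),
                             substrate = NA_character_) {
  stopifnot(inherits(noise, "noise_spec"))
  if (n_dilutions < 3L) stop("'n_dilutions' must be >= 3")
  conc <- top_conc / 2^(seq_len(n_dilutions) - 1L)
  v_true <- kcat * conc / (Km + conc)
  frac_true <- v_true * scf_conc * time / substrate_conc
  if (any(frac_true > 1)) {
    stop("parameters imply fraction_converted > 1; shorten 'time' or raise 'substrate_conc'")
  }
  with_seed(noise$seed, {
    rows <- do.call(rbind, lapply(seq_len(noise$replicates), function(r) {
      frac <- frac_true
      if (noise$multiplicative_cv > 0) {
        frac <- frac * (1 + stats::rnorm(length(frac),
                                         sd = noise$multiplicative_cv))
        frac <- pmin(pmax(frac, 0), 1)
      }
      data.frame(enzyme_conc_nM = conc, fraction_converted = frac,
                 substrate_conc_nM = substrate_conc, scf_conc_nM = scf_conc,
                 time_min = time, replicate = paste0("rep", r),
                 over_conversion = frac_true > 0.20)
    }))
    mm_dataset(rows, substrate = substrate)
  })
}

#' Synthetic SILAC-SRM spike-in measurements
#'
#' Inverts the quantification arithmetic: the true concentration, spherical
#' cell volume and cell count determine the true heavy:light ratio, to which
#' multiplicative CV noise is applied.  Zero noise round-trips exactly
#' through [srm_concentration()].
#'
#' @param true_conc_nM true cellular concentration, nM.
#' @param diameter_um mean cell diameter, micrometers.
#' @param n_cells cells lysed per sample.
#' @param spike_fmol femtomoles of recombinant standard spiked.
#' @param noise a [noise_spec]; `multiplicative_cv` applies to the ratio.
#' @param protein protein label.
#' @return data.frame of samples, one row per replicate, with the columns
#'   [srm_concentration()] expects.
#' @export
gen_srm <- function(true_conc_nM, diameter_um, n_cells, spike_fmol,
                    noise = noise_spec(), protein = "protein") {
  stopifnot(inherits(noise, "noise_spec"))
  if (true_conc_nM < 0) stop("'true_conc_nM' must be >= 0")
  vol <- cell_volume_from_diameter(diameter_um)
  copies <- true_conc_nM * 1e-9 * AVOGADRO * vol
  ratio_true <- copies * n_cells / AVOGADRO / (spike_fmol * 1e-15)
  with_seed(noise$seed, {
    ratio <- rep(ratio_true, noise$replicates)
    if (noise$multiplicative_cv > 0) {
      ratio <- ratio * (1 + stats::rnorm(length(ratio),
                                         sd = noise$multiplicative_cv))
      ratio <- pmax(ratio, 0)
    }
    data.frame(protein = protein, heavy_light_ratio = ratio,
               spike_fmol = spike_fmol, n_cells = n_cells,
               mean_diameter_um = diameter_um,
               replicate = paste0("rep", seq_len(noise$replicates)))
  })
}

#' Synthetic CRISPR screen score tables with planted effects
#'
#' Control screens draw gene scores from Normal(0, sd); the experimental
#' screen draws from the same null and adds the planted (typically negative,
#' synthetic-lethal) effects.  Differential scoring should rank planted
#' genes first.
#'
#' @param n_genes number of genes (>= 1); identifiers are `gene0001, ...`.
#' @param planted_hits named numeric vector of effects; names are gene
#'   identifiers or integer indices in `1:n_genes`.
#' @param noise a [noise_spec]; `additive_sd` is the score SD.
#' @param n_controls number of control screens (default 2).
#' @return list with elements `experimental` (a [gene_score_table]) and
#'   `controls` (list of control tables).
#' @export
gen_screen <- function(n_genes, planted_hits = numeric(0),
                       noise = noise_spec(additive_sd = 0.3),
                       n_controls = 2L) {
  stopifnot(inherits(noise, "noise_spec"))
  if (n_genes < 1L) stop("'n_genes' must be >= 1")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  effects <- stats::setNames(numeric(n_genes), genes)
  if (length(planted_hits)) {
    nm <- names(planted_hits)
    if (is.null(nm)) stop("'planted_hits' must be named")
    idx <- suppressWarnings(as.integer(nm))
    if (!anyNA(idx)) {
      if (any(idx < 1L | idx > n_genes)) stop("planted gene index out of range")
      nm <- genes[idx]
    } else if (!all(nm %in% genes)) {
      stop("planted gene index out of range")
    }
    effects[nm] <- planted_hits
  }
  with_seed(noise$seed, {
    controls <- lapply(seq_len(n_controls), function(i) {
      gene_score_table(genes, stats::rnorm(n_genes, sd = noise$additive_sd),
                       label = paste0("control", i))
    })
    experimental <- gene_score_table(
      genes, stats::rnorm(n_genes, sd = noise$additive_sd) + effects,
      label = "experimental")
    list(experimental = experimental, controls = controls)
  })
}
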