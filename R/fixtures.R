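#' Reference kinetic parameter sets
#'
#' Named scenario catalog of published estimates for SCF-associated
#' chain-initiating and chain-elongating enzymes, used as generating truths
#' for the synthetic-data module and as inputs to the efficiency
#' comparisons.
#'
#' `quench_fixtures()` returns per-step ubiquitin-transfer rate constants
#' (kobs, s^-1; saturating enzyme for SCF) for single-encounter reactions;
#' rows where the third transfer was not determined carry two rates.
#' `mm_fixtures()` returns Michaelis constants (nM) and turnover numbers
#' (min^-1) from multi-turnover titrations; `Ub-` prefixed substrates are
#' mono-ubiquitylated peptides (chain-elongation context).
#' `conc_fixtures()` returns estimated cellular concentrations (nM +/- SEM)
#' of the enzymes across four cell lines.  `sgrna_fixtures()` returns the
#' UBE2R2-targeting guide with its near-match site in UBE2R1.
#'
#' @return `quench_fixtures()`: named list of [rate_set] objects.
#' @examples
#' quench_fixtures()$arih1_cycE
#' mm_fixtures()["ube2r2_ubcycE", ]
#' @export
quench_fixtures <- function() {
  list(
    arih1_cycE    = rate_set(c(0.5, 0.2, 0.08)),
    arih1_bcat    = rate_set(c(0.2, 0.3)),
    ube2d3_cycE   = rate_set(c(0.1, 0.2)),
    ube2d3_bcat   = rate_set(c(5, 0.2)),
    ube2r2_sat    = rate_set(c(0.2, 40, 4)),
    ube2r2_bcat   = rate_set(c(0.1, 30, 7)),
    ube2g1_ubcycE = rate_set(c(1.0, 1.0))
  )
}

#' @rdname quench_fixtures
#' @return `mm_fixtures()`: data.frame with columns `enzyme, substrate,
#'   Km_nM, Km_se, kcat_min, kcat_se, r_squared`, row names matching the
#'   scenario names.
#' @export
mm_fixtures <- function() {
  df <- data.frame(
    enzyme    = c("ARIH1", "ARIH1", "UBE2D3", "UBE2D3", "UBE2R2", "UBE2R2", "UBE2G1"),
    substrate = c("Cyclin E", "b-Catenin", "Cyclin E", "b-Catenin",
                  "Ub-Cyclin E", "Ub-b-Catenin", "Ub-Cyclin E"),
    Km_nM     = c(149, 486, 1673, 488, 317, 292, 1300),
    Km_se     = c(36, 138, 460, 53, 44, 35, 20),
    kcat_min  = c(0.29, 0.32, 0.77, 1.9, 3.7, 3.2, 2.3),
    kcat_se   = c(0.02, 0.03, 0.06, 0.04, 0.1, 0.1, 0.1),
    r_squared = c(0.90, 0.87, 0.89, 0.97, 0.96, 0.97, 0.96)
  )
  rownames(df) <- c("arih1_cycE", "arih1_bcat", "ube2d3_cycE", "ube2d3_bcat",
                    "ube2r2_ubcycE", "ube2r2_ubbcat", "ube2g1_ubcycE")
  df
}

#' @rdname quench_fixtures
#' @return `conc_fixtures()`: data.frame with columns `protein, cell_line,
#'   conc_nM, sem_nM`.
#' @export
conc_fixtures <- function() {
  proteins <- c("ARIH1", "UBE2D1/2/3/4", "UBE2R1", "UBE2R2", "CUL1", "SKP1")
  lines <- c("293T-FiTx", "293T/17", "HeLa", "MRC5")
  conc <- c(200, 148, 200, 160,
            2100, 1700, 1875, 1770,
            70, 134, 83, 82,
            132, 99, 280, 117,
            300, 340, 134, 176,
            2300, 1173, 1860, 1440)
  sem <- c(10, 7, 10, 10,
           100, 100, 7, 40,
           3, 3, 2, 2,
           7, 6, 30, 1,
           20, 10, 5, 1,
           100, 9, 20, 40)
  data.frame(protein = rep(proteins, each = 4L),
             cell_line = rep(lines, times = 6L),
             conc_nM = conc, sem_nM = sem)
}

#' @rdname quench_fixtures
#' @return `sgrna_fixtures()`: list with `guide` (the UBE2R2-targeting
#'   20-mer) and `candidate_sites` (named vector including the two-mismatch
#'   site found in UBE2R1).
#' @export
sgrna_fixtures <- function() {
  list(
    guide = "CGACCTCTACAACTGGGAGG",
    candidate_sites = c(UBE2R1_site = "CGATCTATACAACTGGGAGG")
  )
}

#' @rdname quench_fixtures
#' @return `list_fixtures()`: character vector of scenario names available
#'   from `quench_fixtures()` and `mm_fixtures()`.
#' @export
list_fixtures <- function() {
  sort(unique(c(names(quench_fixtures()), rownames(mm_fixtures()))))
}
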