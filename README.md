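# ubikin

Kinetic and quantitative analysis of SCF-catalyzed poly-ubiquitylation
pathways.

SCF (Skp1–Cullin 1–F-box) ubiquitin ligases degrade substrates by building
poly-ubiquitin chains through two distinct activities: *chain initiation*
(the first ubiquitin onto the naked substrate, by UBE2D3 or the E3 ARIH1)
and *chain elongation* (subsequent ubiquitins, by UBE2R1/2 or UBE2G1).
Whether an enzyme matters in vivo depends on its rate constants *and* on
its cellular concentration. `ubikin` is for biochemists and systems
biologists who want to analyze the measurements that settle this:
single-encounter quench-flow time courses, multi-turnover enzyme
titrations, SILAC spike-in SRM quantification, and genome-wide CRISPR
screen scores.

## What it computes

**Sequential chain model.** Under single-encounter conditions chain growth
is a series of irreversible first-order steps
S0 →(k1) S1 →(k2) S2 → … with S0(0) = 1, solved exactly
(sum-of-exponentials for distinct rates, matrix exponential of the
bidiagonal generator for near-degenerate ones, optional per-state
dissociation), plus a per-molecule stochastic simulator as cross-check.

**Rate fitting.** `fit_rates()` estimates per-step kobs (s⁻¹) from gel
densitometry fractions by multi-start Levenberg–Marquardt in log-rate
space, fitting all species and replicates simultaneously, with
Gauss–Newton standard errors and a chi-squared goodness-of-fit p-value.

**Michaelis–Menten.** `reaction_velocity()` computes
v = f·[S]/([SCF]·t) (flagging >20% conversion), `fit_michaelis()` fits
v = kcat·[E]/(Km+[E]), and `catalytic_efficiency()` reports kobs/Km in
M⁻¹ s⁻¹; `fold_ratio()` and `build_comparison_report()` make the
enzyme-vs-enzyme comparisons.

**Cellular quantification.** `copies_per_cell()`,
`cell_volume_from_diameter()` and `srm_concentration()` turn heavy:light
spike-in ratios into copies/cell and nanomolar concentrations.

**Screen analysis.** `differential_scores()` subtracts averaged control
screens from an experimental screen; `hamming_distance()` /
`offtarget_scan()` check sgRNAs against candidate off-target sites.

**Synthetic data.** `gen_quenchflow()`, `gen_mm_titration()`, `gen_srm()`
and `gen_screen()` are seeded generators that invert each analysis stage,
with published parameter sets shipped as named fixtures
(`quench_fixtures()`, `mm_fixtures()`, `conc_fixtures()`).

## Worked example

Simulate a duplicate quench-flow experiment at the ARIH1/Cyclin E reference
rates (0.5, 0.2, 0.08 s⁻¹) with 2% densitometry noise, and refit:

```r
library(ubikin)
d <- gen_quenchflow(quench_fixtures()$arih1_cycE,
                    noise = noise_spec(additive_sd = 0.02, replicates = 2, seed = 7))
fit_rates(d, n_rates = 3)
#> Fitted transfer rates (3 steps, 4 species fit)
#>  step k_per_s     se
#>     1   0.503 0.0066
#>     2   0.201 0.0037
#>     3   0.085 0.0035
```

All three generating rates are recovered within ~6%, each inside two
standard errors. The closed-form model behind the fit:

```r
tc <- closed_form_fractions(c(0.5, 0.2, 0.08), times = c(1, 5, 10))
round(as.data.frame(tc), 4)
#>   time_s     S0     S1     S2 S_ge_3
#> 1      1 0.6065 0.3537 0.0387 0.0011
#> 2      5 0.0821 0.4763 0.3733 0.0683
#> 3     10 0.0067 0.2143 0.5209 0.2580
distribution_summary(tc, 10, threshold_length = 3)
#> Species distribution at t = 10 s
#>   mean ubiquitins/substrate: 2.03
#>   fraction with >= 3 ubiquitins: 0.258
```

By 10 s only 0.7% of substrate is unmodified and a quarter carries chains
of three or more ubiquitins — the behaviour of an efficient initiator with
modest elongation. Comparing the two dedicated elongation E2s on
mono-ubiquitylated Cyclin E substrate:

```r
catalytic_efficiency(kobs = 40, Km = 317)
#> Catalytic efficiency: 1.3e+08 M^-1 s^-1 (kobs = 40 s^-1, Km = 317 nM)
catalytic_efficiency(kobs = 1.0, Km = 1300)
#> Catalytic efficiency: 7.7e+05 M^-1 s^-1 (kobs = 1 s^-1, Km = 1300 nM)
fold_ratio(5, 0.1)$fold   # UBE2D3 initiation: b-Catenin vs Cyclin E substrate
#> [1] 50
```

UBE2R2 is orders of magnitude more efficient than UBE2G1 at chain
elongation — yet UBE2G1's activity is what buffers cells against UBE2R1/2
loss, which is why concentrations matter as much as rate constants.

## The analysis workflow

The `analysis/` directory holds the numbered end-to-end drivers, each a
thin script over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic inputs for every stage
Rscript analysis/02_quench_fit.R   # per-step rate recovery vs truth
Rscript analysis/03_mm_fit.R       # Km/kcat recovery vs truth
Rscript analysis/04_cell_quant.R   # SRM ratios -> copies/cell -> nM
Rscript analysis/05_screen_diff.R  # screen differentials + off-target scan
Rscript analysis/06_report.R       # efficiency and fold-ratio comparison
```

The methods vignette (`vignettes/ubiquitylation-kinetics.Rmd`) documents
the model, the numerical choices, the noise model behind the generators,
and a genuine identifiability limit of fast-elongation rate sets.

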