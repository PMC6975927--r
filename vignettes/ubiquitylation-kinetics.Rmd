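---
title: "Modelling single-encounter poly-ubiquitylation and quantifying SCF pathway enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-encounter poly-ubiquitylation and quantifying SCF pathway enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubikin)
```

## The scientific setting

Cullin-RING ligases of the SCF family degrade regulatory proteins by
building poly-ubiquitin chains on bound substrates. Chain assembly divides
into *initiation* (the first ubiquitin transferred to the naked substrate,
by E2s such as UBE2D3 or the E3 ARIH1) and *elongation* (subsequent
ubiquitins added to the growing chain, by UBE2R1/2 or UBE2G1). Which enzyme
dominates depends both on its intrinsic rate constants and on how much of it
the cell actually contains. `ubikin` implements the quantitative analyses
that connect those two things:

1. a kinetic model of the sequential transfer chain and a fitter that
   extracts per-step rate constants from quench-flow densitometry;
2. Michaelis-Menten characterization of enzyme titrations and
   catalytic-efficiency (kobs/Km) comparisons;
3. conversion of SILAC spike-in SRM measurements into copies per cell and
   nanomolar concentrations;
4. differential scoring of genome-wide CRISPR screens, with an sgRNA
   off-target mismatch scan;
5. seeded generators that produce synthetic versions of every input, so the
   entire pipeline is testable without any experimental data.

Units are seconds and nanomolar throughout; conversions happen only at I/O
boundaries (femtomoles for spikes, M^-1 s^-1 for efficiencies).

## The sequential chain model

Under single-encounter conditions (excess unlabelled competitor peptide, so
each labelled substrate molecule is processed during at most one binding
event), chain growth is a sequence of irreversible first-order steps

$$S_0 \xrightarrow{k_1} S_1 \xrightarrow{k_2} S_2 \xrightarrow{k_3} \cdots$$

with $S_0(0) = 1$. The model tracks `n_tracked` explicit species plus one
absorbing aggregate $S_{\ge n}$ that collects everything with $n$ or more
ubiquitins. The aggregate reflects both how the data look (gels bin long
chains into a smear) and how many rates are actually estimable (published
per-step estimates stop at the third transfer).

For pairwise-distinct rates the solution is the classical sum of
exponentials for sequential decay chains,

$$S_i(t) = \left(\prod_{j=1}^{i} k_j\right)
  \sum_{j=1}^{i+1} \frac{e^{-k_j t}}{\prod_{l \ne j} (k_l - k_j)},$$

with the terminal aggregate as $1 - \sum_i S_i$. The denominators
$(k_l - k_j)$ make this form numerically fragile when rates nearly
coincide: at a relative gap of $10^{-7}$ the cancellation error already
reaches the $10^{-8}$ level we hold the solution to. `ubikin` therefore
switches to a matrix exponential of the lower-bidiagonal generator whenever
the smallest relative gap falls below $10^{-5}$ — comfortably before the
sum-of-exponentials degrades, while keeping the cheap closed form for the
overwhelming majority of inputs. The two paths agree to better than
$10^{-11}$ against an independent adaptive ODE integration (see the test
suite and `scripts/acceptance.R`).

An optional per-state dissociation rate models substrate release from the
ligase. A released molecule keeps the chain length it had at release, so
the *observed* species are bound plus released pools; this variant always
evaluates through the (augmented) matrix exponential. The default is zero
dissociation, i.e. rates are interpreted as observed single-encounter
kobs values. Not modelled at all, deliberately: E2~ubiquitin re-charging,
NEDD8 cycle dynamics and substrate rebinding — all excluded by the
single-encounter design itself.

`stochastic_encounter()` simulates the same chain molecule-by-molecule with
exponential waiting times. It exists as a cross-check of the closed form
(the two must agree within binomial error) and as a way to emulate finite
counting statistics.

## Estimating transfer rates from densitometry

A gel lane at time $t$ yields band intensities per species;
`lane_to_fractions()` divides by the lane total, which removes the unknown
exposure scale entirely (the estimator is invariant to uniform intensity
rescaling). `fit_rates()` then minimizes the summed squared difference
between observed and model fractions over **all** tracked species and all
replicates simultaneously.

Numerical choices that matter:

* **Log-rate parameterization.** Rates span more than two orders of
  magnitude across enzymes (0.08 to 40 s^-1), and positivity must hold;
  optimizing $\log k$ handles both.
* **Deterministic multi-start.** A log-spaced grid over
  $10^{-3}$–$10^{2}$ s^-1, plus a data-driven guess for $k_1$ from the
  initial $S_0$ decay, is screened by residual sum of squares; the best
  three candidates are polished by Levenberg-Marquardt. Multi-modality is
  real here (swapping adjacent rates changes the fit only subtly).
* **Unweighted least squares** by default: densitometry error is roughly
  constant on the fraction scale, and no species-specific weights are
  published for this assay type. Replicates enter as additional residuals,
  not as averages, so their spread is preserved.
* **Standard errors** come from the Gauss-Newton covariance approximation
  on the log scale, delta-transformed to the rate scale. Because each
  lane's fractions sum to one, a lane with $m$ species carries only $m-1$
  independent residuals; the residual variance uses this effective degree
  count. Without that correction the SEs are visibly anticonservative
  (empirical 2 SE coverage ~0.85 instead of ~0.92–0.96).
* **Goodness of fit** is a chi-squared statistic on residuals standardized
  by the replicate-estimated noise SD, df = (independent residuals − number
  of rates). With a single replicate the residual SD itself is used and the
  p-value degrades to an internal-consistency check; the method used is
  recorded in the output. Published tables do not state how their fit
  p-values were computed, so this definition is declared rather than
  inherited.
* **Reported uncertainty.** Whether published "±" values are fit SEs or
  replicate ranges is ambiguous; `fit_rates(per_replicate = TRUE)` reports
  both (the Gauss-Newton SE and the half-range of per-replicate refits).

An identifiability guard refuses to fit more rates than the data have
informative species columns: data showing only $S_0$ decay cannot constrain
anything beyond $k_1$.

## Michaelis-Menten characterization

Multi-turnover titrations vary the E2/E3 concentration against constant SCF
and substrate. The velocity of each point is
$v = f \cdot [\mathrm{S}] / ([\mathrm{SCF}] \cdot t)$ (turnovers per SCF per
minute), with a warning when the conversion $f$ exceeds 20% — past that
point the initial-velocity assumption behind the MM analysis is unsafe, the
same rule the wet-lab protocol enforces by quenching early.
`fit_michaelis()` fits $v = k_{cat} [E]/(K_m + [E])$ by nonlinear least
squares, initialized at $K_m$ = median titration concentration and
$k_{cat} = 1.2 \times$ the maximum observed velocity; $R^2$ is computed
against the mean model, the convention used by common curve-fitting
software. A warning flags fits whose $K_m$ lands outside the titrated
range. Catalytic efficiency is $k_{obs}/K_m$ converted to M^-1 s^-1
(×10^9 on 1/nM) and reported to two significant figures, matching how such
comparisons are usually printed; the raw value is kept alongside.

## From spike-in ratios to cellular concentrations

SILAC-heavy cells are lysed into buffer spiked with known femtomole amounts
of light recombinant standards, so the heavy:light SRM ratio directly
scales the spike: endogenous moles = ratio × spike. Copies per cell follow
by Avogadro's number over the cell count, and concentration by the cell
volume. The volume model is a sphere built from the counter's mean
diameter — the simplest assumption consistent with what a cell counter
reports — and is declared in the output metadata. An enrichment multiplier
(default 2, reflecting reported modest nuclear enrichment of the elongation
E2) produces the "assay concentration" at which in vitro reactions emulate
the relevant compartment. Isoform families quantified together (e.g.
UBE2D1/2/3/4) are treated as one pooled species; the module accepts one
pre-rolled ratio per protein per replicate, since transition-level roll-up
happens upstream in SRM software.

## Screen differentials and off-target scanning

Differential scores are experimental minus the mean of the control screens,
computed on the genes shared by every table; missing genes are dropped and
reported rather than imputed, because a differential against an absent
control is meaningless. Matching is by exact identifier (no aliasing). No
p-values are emitted: the published FDR machinery relies on a custom null
distribution that is not specified in reusable form. The off-target scan
is a plain Hamming comparison of a guide against supplied candidate sites
(genome-wide enumeration requires external annotation and is out of scope);
hits are returned sorted by mismatch count, then input order.

## What the synthetic generators emulate — and what they do not

Each generator is the measurable inverse of its analysis stage, and at zero
noise the round trip is exact; every generator is bit-reproducible under a
fixed seed and attaches its parameters to the output.

* `gen_quenchflow()` applies additive Gaussian noise on the *intensity*
  scale (lane total 10^4), clips negatives, and renormalizes — the order
  real densitometry imposes. Renormalization induces mild anticorrelation
  between species fractions, as in real lanes. The true noise magnitude of
  gel densitometry is not published; the default σ = 0.02 (2% of lane
  total) was chosen once as a realistic figure that makes recovery
  experiments meaningful, and is configurable. Not emulated: band
  saturation, smearing between adjacent species, and spatially correlated
  background — so passing recovery tests show estimator correctness under
  the declared noise model, not robustness to every gel artefact.
* `gen_mm_titration()` builds the 2-fold dilution series, inverts the
  velocity formula to fraction-converted, applies multiplicative CV noise
  (5% in the study conditions), and flags points violating the 20% rule.
* `gen_srm()` inverts the quantification arithmetic to produce ratios with
  multiplicative CV noise.
* `gen_screen()` draws control scores from Normal(0, sd) and adds planted
  effects to the experimental table; it does not simulate sgRNA counts,
  reads, or the gene-scoring algorithm itself.

The default time grid for quench-flow experiments is 20 log-spaced points
over 0.01–10 s, the range a quench-flow instrument covers, and duplicates
mirror the technical-replicate design used throughout the original
experiments.

## A real identifiability limit

The fast-elongation parameter sets (first transfer ~0.1–0.2 s^-1, second
~30–40 s^-1) are **not** recoverable from densitometry at σ = 0.02: the
steady occupancy of the intermediate species is bounded by
$k_1/k_2 \approx 0.005$, a quarter of the noise SD, and clipping negative
bands censors that species upward, biasing $k_2$ low. Self-consistency on
noise-free data recovers these sets exactly, and the residual surface over
$k_2$ is flat from 20 to 100 s^-1 at this noise — the information simply is
not in the data. The corresponding acceptance test asserts the recovery
property over *all* reference parameter sets and is expected to fail on
those steps; the acceptance script reports the shortfall as its own number
(`quench_recovery_ube2r2_median_rel_err_pct`) instead of hiding it.
Published SEs of ±10% on the fast steps imply raw data with several-fold
lower effective noise than this generator's default. A related visible
effect: with replicated noisy lanes the goodness-of-fit p-values are small
(~10^-4) even for the true model, because clipping makes the noise slightly
non-Gaussian near zero fractions — the chi-squared is doing its job.

## Problem sizes

The test suite and acceptance script use sizes chosen to give stable Monte
Carlo estimates at interactive runtimes: 1000 random rate sets for the
closed-form/ODE equivalence, 25 seeds × 10^4 molecules for stochastic
consistency, 50 seeds per rate-set fixture (duplicates, 20 time points) for
quench-flow recovery, 100 seeds per titration fixture for MM recovery, 100
seeds for the SRM and screen experiments.

## Known limitations

* The chain model is linear and memoryless; it cannot represent
  cooperative or chain-length-dependent transfer rates.
* The dissociation extension assumes a single uniform release rate across
  states.
* Mean chain length from `distribution_summary()` counts the terminal
  aggregate at its lower bound (n ubiquitins), so it underestimates when
  long chains are abundant.
* SRM quantification trusts a single rolled-up ratio per protein; peptide
  disagreement is invisible to it.
* Screen differentials come with no significance calls, by design.
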