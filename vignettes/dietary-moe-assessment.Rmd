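---
title: "Probabilistic MOE assessment of acrylamide in baby foods: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic MOE assessment of acrylamide in baby foods: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmoe)
```

## The problem

Market surveys of contaminants in infant foods usually publish a censor-aware
summary table — per product category: n, mean ± SD, median, 95th percentile,
minimum and maximum, with `<LOD` / `<LOQ` tokens where the statistic falls
below the analytical limits — while the raw per-sample measurements stay
unpublished. A probabilistic risk assessment, however, needs a concentration
*distribution*. `dietmoe` bridges that gap: it reconstructs one feasible
per-sample dataset from each summary row, then propagates it through the
standard exposure pipeline — bootstrap concentration model, log-normal
consumption model, Monte Carlo exposure simulation, and Margin of Exposure
(MOE) risk characterization for infants at 6, 12 and 18 months.

The packaged survey table (`table1_path()`) describes 90 baby-food samples in
six categories (whole biscuits, ground biscuits, multigrain meal, sweet
snacks, savory snacks, plum puree) analysed with LOD = 10 ng/g and
LOQ = 30 ng/g. The quantification limit is three times the detection limit by
construction (`lod_loq_from_calibration()` implements LOD = 3.3 σ/S,
LOQ = 3 × LOD), so `loq/lod = 3` holds exactly everywhere in the package.

## Censoring: the middle-bound substitution

Left-censored observations are known only to lie below LOD or LOQ. The
assessment substitutes LOD/2 = 5 ng/g and LOQ/2 = 15 ng/g (middle bound)
before any statistic is computed. Two alternative policies, lower bound
(0 and LOD) and upper bound (LOD and LOQ), are provided purely for
sensitivity analysis; every default in the package is middle-bound. The
substitution is deliberately non-parametric — no censored-likelihood fitting —
because the substitution rule *is* the method being implemented, and because
with 18 of 90 observations below LOD the choice of rule is transparent to the
reader in a way a parametric imputation would not be.

A consequence worth making explicit: the published biscuit range has a lower
end of exactly LOQ/2 = 15 ng/g, which is only consistent with the summary
statistics having been computed *after* middle-bound substitution. The
reconstruction therefore targets imputed-data statistics. Whether the original
mean/SD were computed on imputed or quantified-only values is not knowable
from the table alone; the imputed interpretation is adopted throughout and is
the only one that makes the printed range attainable.

## Reconstruction by constrained numerical adjustment

`reconstruct_category()` inverts one summary row. The algorithm:

1. **Censor counts are fixed first** (`default_censor_allocation()`): a row
   whose statistics are all `<LOD` is entirely below-LOD; a `<LOD` minimum
   implies two below-LOD observations (configurable); a `<LOQ` minimum
   implies one below-LOQ observation and no below-LOD ones; a censored
   maximum means nothing is quantified; a numeric maximum with a censored
   mean gets the minimal quantified set (two values when the printed P95 is
   also numeric, so the interpolated percentile can reach it). Under these
   defaults the packaged table yields 72 of 90 detectable samples (80%),
   where *detectable* means status ≠ below-LOD. The allocation is one
   feasible choice, not a unique inversion; it is exposed as an argument.
2. **Pinned order statistics**: the maximum (and, for even n, both middle
   order statistics; for fully quantified rows also the minimum) are set to
   their printed values exactly.
3. **Penalized least squares on the rest**: the free quantified order
   statistics, box-constrained to `[LOQ, max]` and to the intervals the pins
   induce, are optimized (L-BFGS-B, Nelder–Mead fallback) against the
   weighted squared residuals of mean, SD and P95, each scaled by its
   tolerance. Up to 25 restarts from seed-derived random initializations are
   tried; the first configuration inside tolerance wins. No rejection
   sampling is involved, and a fixed seed makes the result deterministic.

Default tolerances: 0.5 ng/g on mean, median, max and min; 1.0 ng/g on SD and
P95. The P95 tolerance widens to 2 ng/g when the row's median is censored,
because there the percentile interpolates between imputed censored values and
the original table's quantile convention is unrecoverable. The package's own
convention is fixed and documented: type-7 linear interpolation between
closest ranks, R's default. Sample SD uses the n − 1 denominator (the
conventional choice for laboratory summaries; the optimizer must match
whatever `summarize_category()` computes, so the convention lives in exactly
one place).

**Internally inconsistent rows.** The packaged ground-biscuit row prints
P95 = 63 above its own maximum of 55 — an impossibility for any dataset. By
default the P95 constraint of such a row is dropped with a warning naming the
conflict (`p95_action = "drop"`); `p95_action = "error"` turns it into a hard
infeasibility error instead. All other ordering violations (median above
maximum, a numeric minimum below the LOQ, ...) are always hard errors carrying
the violated constraint in the message.

**Display convention.** `summarize_category()` renders a statistic as `<LOD`
when its imputed value is below the LOD and as `<LOQ` when it is below the
LOQ (for categories containing censored observations). This value-threshold
rule reproduces every cell of the packaged table, including rows that mix
below-LOD, below-LOQ and quantified observations; a status-based rule
("render censored when all contributing observations are censored") cannot.
Rendered values round to integers; full precision is kept in the object.

```{r roundtrip}
rows <- read_summary_csv(table1_path())
rec <- reconstruct_category(rows[[1]], seed = 1)
rec$achieved_summary
rec$max_constraint_residual
```

## Concentration model: bootstrap with measurement error

The simulated distribution of the concentration C pools 1000 bootstrap
replicates of the imputed empirical values, adding independent N(0, 4 ng/g)
measurement error to **each drawn value** and clipping negatives to zero.
Three decisions deserve a note:

- *Per-draw noise*: adding the error once per empirical observation (rather
  than per bootstrap draw) would be an alternative reading; per-draw is
  adopted because the error represents assay uncertainty realized at each
  simulated measurement. Under per-draw noise the pool obeys a clean law of
  total variance, `Var(pool) → s²(n−1)/n + noise_sd²`, which the tests verify
  at 10,000 replicates within 2%.
- *Clipping*: concentrations are physical quantities, so negative
  noise-perturbed draws are set to 0. With the default data (minimum imputed
  value 5 ng/g, noise SD 4) clipping affects well under 1% of below-LOD draws
  and no biscuit draws, so the variance law above is unaffected in practice.
- *Pooling*: the default concentration pool combines whole and ground
  biscuits (40 imputed values with equal per-sample weight), the main
  contributors to intake; `pool_categories` makes this configurable.

Each Monte Carlo iteration then draws one C uniformly at random from the
pooled values — the bootstrap uncertainty is folded into the pool rather than
modelled as a separate outer loop (a one-dimensional simulation of
variability, not a two-dimensional variability/uncertainty separation).

## Consumption model: moment-matched log-normal

Daily consumption Q (g/day) is log-normal. Consumption databases report
natural-scale means and SDs, so `lognormal_from_moments()` converts by moment
matching: σ² = ln(1 + (sd/mean)²), μ = ln(mean) − σ²/2; the resulting
distribution has *exactly* the requested natural-scale moments, and the
round trip is property-tested across coefficients of variation up to 3.
A log-scale (μ, σ) parameterization is accepted directly via
`lognormal_from_logscale()` or the `{"mu": ..., "sigma": ...}` config form.
No upper truncation is applied by default.

The per-age parameter values belong to the run configuration, not the
package: the survey consumption statistics this assessment would ideally use
are not published alongside the concentration table. The shipped
`example_config.json` therefore carries clearly labelled illustrative values
(15/12, 22/16, 28/20 g/day mean/SD at 6/12/18 months — plausible magnitudes
for biscuit consumption at those ages, chosen once so the pipeline runs out
of the box). Any headline probability computed from them characterizes the
example, not the surveyed population; this is also why the package's checks
are property-based (scaling laws, orderings) rather than comparisons of
headline percentages.

## Exposure and MOE

Exposure per iteration is E = (Q × C) / BW in ng/kg bw/day, with body weights
8.0, 9.4 and 10.9 kg at 6, 12 and 18 months (WHO growth curves; one weight
for both sexes). C and Q are sampled independently — no dependence structure
between how much a child eats and how contaminated the product is. The
simulation seed is the configuration's master seed, so all age groups share
common random numbers: exposures differ across groups only through the
consumption model and the 1/BW factor. Two exact consequences, both tested:
E scales as 1/BW elementwise, and with a shared consumption model the concern
probability is nonincreasing in body weight.

MOE = BMDL₁₀ / E, with the BMDL₁₀ converted from mg to ng through a single
constant (10⁶ ng/mg) defined in one place. Packaged endpoints: neurotoxicity
0.43 mg/kg bw/day (concern threshold 125) and two carcinogenicity endpoints,
Harderian gland 0.17 and mammary gland 0.31 mg/kg bw/day (threshold 10,000).
Because MOE is inversely proportional to E, distributions under different
BMDL₁₀ values are exact elementwise rescalings of one another under a shared
seed — e.g. the 0.31 distribution equals the 0.17 distribution × 0.31/0.17 —
which orders the concern probabilities deterministically.

`prob_below()` uses strict inequality (MOE < threshold); the empirical CDF
(`moe_ecdf()`) keeps R's standard right-continuous `P(X ≤ t)` convention, so
the CDF evaluated just below the threshold equals `prob_below` at it. With
continuous simulated distributions the strict/non-strict distinction is
numerically irrelevant, but fixing it makes reported probabilities
reproducible bit for bit. Zero-exposure iterations map to +Inf MOE and can
never count as concern. Degenerate inputs (all-zero exposure) warn rather
than error.

```{r moe}
x <- impute(rec$observations)
pool <- bootstrap_concentration(x, replicates = 1000, noise_sd = 4, seed = 2)
ex <- simulate_exposure(pool, lognormal_from_moments(20, 15),
                        age_group("6 months", 8.0),
                        simulation_config(iterations = 10000, master_seed = 7))
compute_moe(ex, default_endpoints()$carcinogenic_harderian)
```

## What the synthetic data does and does not emulate

The generator reproduces the study *conditions*: category sizes
(20/20/14/12/12/12), the censoring pattern (80% detectable), the printed
summary statistics after middle-bound imputation, and the analytical limits.
It does not — and cannot — recover the true per-sample values: a summary row
underdetermines its dataset, and the reconstruction returns *one* feasible
dataset per seed. Features of real residue data that the generator does not
emulate include batch/brand clustering, analytical rounding of individual
values, and any dependence between category and measurement error. Passing
tests therefore demonstrate that the pipeline is a correct implementation of
the stated model under datasets consistent with the published summaries, not
that the published study's raw data are recovered.

## Numerical choices and problem sizes

- Optimizer: L-BFGS-B with per-coordinate boxes; objective evaluates order
  statistics on the sorted candidate vector, so coordinate permutations are
  harmless; Nelder–Mead fallback if L-BFGS-B aborts; ≤ 25 restarts.
- Convergence: a reconstruction is accepted only when every active constraint
  is inside its tolerance; otherwise an error carries the best residual.
- Seeds: one master integer seed; sub-streams (per-category reconstruction,
  bootstrap, exposure) derive from it via a seeded integer draw, all below
  2³¹.
- Test problem sizes: moment-recovery checks use 10⁶ draws; the bootstrap
  variance law uses 10⁴ replicates of the 20-value biscuit dataset; Monte
  Carlo mean checks use 10⁵ iterations; full-pipeline tests run 2,000–10,000
  iterations. The complete suite runs in well under a minute.

## Known limitations

- Biscuits are the sole modelled intake source; no aggregate multi-food or
  lifetime-averaged exposure.
- One-dimensional Monte Carlo: sampling variability and bootstrap uncertainty
  are pooled, not separated.
- The censor-count allocation and the reconstructed datasets are feasible
  choices, not unique inversions of the published table.
- Log-normal consumption is an assumption, and a contested one for food
  consumption data; no truncation or alternative families are offered.
- BMDL₁₀ values are fixed inputs; the package does no dose–response
  modelling.
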