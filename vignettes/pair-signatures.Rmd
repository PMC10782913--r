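---
title: "Gene-pair prognostic signatures: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `pairsig`, every
tunable parameter and its default, the design and intended scope of the
synthetic-cohort generator, the numerical decisions that make the
pipeline reliable, and the package's limitations. All quantitative
statements here are recomputed by the test suite
(`tests/testthat/`) or the acceptance script
(`scripts/acceptance.R`); nothing is quoted that the package does not
itself compute.

## 1. The model

### Pair indicators

For an ordered gene pair (M, G) and a sample s with expression
E_s(·), the indicator is

$$
I_s(M, G) = \begin{cases} +1 & E_s(M) \ge E_s(G) \\ -1 & \text{otherwise.} \end{cases}
$$

Ties map to +1; the rule is deterministic so an encoding is a pure
function of the expression matrix. Because the comparison happens
within one sample, $I$ is invariant under any strictly increasing
transform applied per sample — log, rank, quantile normalization,
library-size scaling. This is the property that lets a fixed signature
cross platforms. The acceptance script verifies it empirically: 100
random per-sample compositions of affine, exponential, cubic,
logarithmic and rank transforms leave the encoding bit-identical
(`encoding_invariance_fraction`).

### Candidate pairing

Candidates are regulator–target pairs with Pearson correlation
|r| > `r_min` (default 0.5) and two-sided P < `p_max` (default 0.01),
both strict. The regulator set defaults to 25 m6A regulators (8
writers, 2 erasers, 15 readers) shipped in the package; any tibble
with `symbol` and `class` columns can replace or extend it. The
correlation p-value uses the exact t transform on n − 2 degrees of
freedom, vectorized over the full regulator × target grid.

### Reversal testing

For two outcome-separated groups (defaults `"LGG"` vs `"GBM"` in the
`grade` column), each pair yields a 2×2 table of indicator sign
against group. The point probability of a table under fixed margins is
the hypergeometric term; the two-sided p-value sums point
probabilities not exceeding the observed one. Pairs pass selection
when $\log_{10} p < -70$ (strict). Section 4 explains why this must
be computed in log space.

### Fitting and scoring

Selected indicators enter a LASSO Cox model
(`glmnet::cv.glmnet`, `family = "cox"`, 10-fold CV, `lambda.min`).
Standardization is off: the columns are ±1 indicators and already on a
common scale, so penalizing them equally is the intended behavior. The
CV fold assignment is drawn from the user-supplied seed, making
selection bit-reproducible. Pairs surviving the LASSO are refitted
without penalty (`survival::coxph`); a QR rank check first rejects
perfectly collinear indicator columns with an error naming the pairs.
The risk score is the linear combination
$\sum_i \beta_i I_s(M_i, G_i)$ and cohorts are split at the median
score (ties to the low group, "high" means strictly above the
median).

The package also carries the published five-pair glioma signature as a
fixed object, `published_mrgps()`, with coefficients
(EIF3A, AK2) −0.204, (EIF3A, EMP3) −0.266, (YTHDC1, IGFBP2) −0.439,
(YTHDC1, TUBA1C) −0.140, (IGF2BP3, CYP17A1) +0.647, for external
validation via `run_validate()`.

### Evaluation

* **Kaplan–Meier / log-rank** wrap `survival::survfit` and
  `survdiff`.
* **Time-dependent AUC** is the inverse-probability-of-censoring
  weighted (IPCW) cumulative/dynamic estimator: at horizon h, cases
  are events with $T \le h$, controls are samples with $T > h$; case
  weights are $1/\hat G(T_i^-)$ and control weights $1/\hat G(h)$,
  with $\hat G$ the Kaplan–Meier estimate of the censoring
  distribution. Implemented directly (no external dependency) and
  anchored by the tests: a perfect risk ranking gives AUC exactly 1,
  and independent scores sit at 0.5 within Monte-Carlo error.
* **Harrell's C** counts usable pairs (earlier time is an event, times
  distinct), scoring concordant 1 and score-ties 0.5. It is
  cross-checked in the tests against `survival::concordance`
  (`reverse = TRUE`) to 1e-10.
* **Calibration** compares predicted survival at a horizon — Breslow
  baseline hazard composed with the linear predictor — to observed
  Kaplan–Meier survival inside risk-score quantile bins.

## 2. Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `r_min` | 0.5 | correlation floor for biologically coupled pairs |
| `p_max` | 0.01 | correlation significance; strict inequality |
| `log10_fisher_threshold` | −70 | reversal selection; strict, in log10 space |
| `folds` | 10 | CV folds for LASSO Cox |
| lambda rule | `lambda.min` | minimizes CV partial-likelihood deviance |
| `standardize` | `FALSE` | ±1 indicators are already scale-matched |
| median split | ties → low | deterministic stratification |
| `horizons` | 12, 36, 60 months | 1/3/5-year survival, the usual clinical horizons |
| tie rule in encoding | → +1 | deterministic; measure-zero event for continuous data |
| `days_to_months` divisor | 30.44 | mean Gregorian month length |

`seed` has no default anywhere randomness occurs — `run_discovery()`
and `lasso_cox_select()` error without one, so no analysis silently
depends on the session's RNG state.

## 3. The synthetic generator and its scope

`generate_cohort(synthetic_config(...))` builds a cohort in which the
entire discovery pipeline has a known answer. Design:

* **Correlation structure.** Each regulator anchors a block of
  `targets_per_regulator` targets; block members share a latent factor
  so that within-block correlation is `rho` (default 0.8). Unrelated
  `NOISE` genes are independent.
* **Planted reversal.** `n_reversed_pairs` blocks receive a shared
  grade effect: all block members shift by 1.5·`delta` with the sign
  depending on group, while the designated reversed target sits
  `delta` *below* its regulator's level. The regulator–target gap is
  therefore +`delta` in one group and −`delta` in the other — the
  indicator reverses — while the shared shift keeps the *pooled*
  Pearson correlation high so the pair survives the |r| > 0.5 gate.
  This is the one subtle piece of the design: planting the reversal as
  opposite mean shifts alone would destroy the pooled correlation and
  the pair would never reach the Fisher stage.
* **Construction truth.** Because the grade effect is shared across
  shifted blocks, *every* shifted regulator reverses against *every*
  reversed target, not just the within-block seed. `truth$reversed_pairs`
  is that full cross — the set the generator genuinely plants — and
  `truth$seeded_pairs` records the within-block seeds separately.
  `recovery_report()` scores precision/recall against the full cross.
* **Survival.** Event times follow a Weibull (default exponential,
  `weibull_shape = 1`) proportional-hazards model with linear
  predictor $\sum_j \beta_j I_j + \beta_{age}(age - 50)$ over the
  `prognostic_pairs`. Censoring is uniform on (0, c); c is found by
  bisection so the realized censoring fraction matches
  `censoring_rate` in expectation (verified ±0.05 in the tests).
* **Determinism.** The whole cohort is a pure function of the config,
  including its `seed`; the tests assert bit-identical regeneration.

Default sizes (250 + 250 samples, 10 regulators × 4 targets, 10
reversed pairs, 2 prognostic) are this package's own choice: large
enough that the Fisher statistics reach the 1e−70 selection regime and
the Cox coefficients are identifiable, small enough that a full
discovery run takes seconds. The generator's scope is validation of
*this pipeline's* operating characteristics — it is not a general
transcriptome simulator: no batch effects, no heavy-tailed counts, no
gene-length or GC structure, Gaussian blocks only.

The recovery study in the acceptance script (50 replicates,
`delta = 0.8`, betas 0.8/−0.5) deliberately uses a *weaker* grade
effect than the default so that indicators are not grade-degenerate
(the within-group flip probability is about 0.10) and the planted
hazard coefficients are estimable; it reports 3·SE coverage of the
planted coefficients and LASSO recall of the prognostic pairs.

## 4. Numerical choices

* **Log-space Fisher.** At the selection regime the p-values are
  below 1e−70 — representable but the hypergeometric *terms* composing
  them involve binomial coefficients far beyond double range. All
  point probabilities are computed as
  $\log_{10} p = [\sum \ln\Gamma(\text{margins}+1) - \sum \ln\Gamma(\text{cells}+1) - \ln\Gamma(n+1)]/\ln 10$
  and summed with a log-sum-exp in base 10. The two-sided tail keeps
  tables with $\log_{10} p_i \le \log_{10} p_{obs} + 10^{-7}|\log_{10} p_{obs}|$ —
  a relative guard so that mathematically-equal terms computed through
  different `lgamma` routes are not dropped by the last-ulp
  difference. The implementation is validated against an independent
  exact oracle (prime factorization of the factorials with Legendre
  exponents, an exact rational evaluated in double) on *every* 2×2
  table with total count up to 20, to 1e−12 on the log10 scale, and
  against `stats::fisher.test` on random tables.
* **Deterministic ties.** Encoding ties go to +1; median-split ties go
  to "low". Both rules are asserted directly in the tests rather than
  via looser invariants.
* **Duplicate encodings.** Under a strong group effect distinct planted
  pairs can encode to *identical* ±1 vectors; `run_discovery()` keeps
  the lowest-p representative of each distinct encoding before the
  LASSO so the design matrix has full rank, and `cox_refit()`
  independently errors on perfect collinearity.
* **Censoring KM left-limit.** IPCW weights use $\hat G(t^-)$, the
  left-continuous version of the censoring survival curve, which is
  what makes AUC exactly 1 achievable for a perfect ranking.
* **Bit-stable I/O.** `write_expression()` prints with `%.17g`, so a
  write–read round trip is exact in double precision (asserted in the
  tests).
* **Seeded CV.** `lasso_cox_select()` derives the fold assignment from
  the seed with `sample(rep_len(1:folds, n))`, so the selected pair
  set is reproducible across sessions on the same data.

## 5. Limitations

* The Fisher selection threshold of 1e−70 presumes cohorts of several
  hundred samples per group; in small cohorts no pair can reach it and
  `run_discovery()` stops at the reversal stage with an explicit
  error.
* The indicator discards all magnitude information; pairs whose
  ordering never flips carry no signal regardless of how prognostic
  the underlying genes are. The single-gene LASSO baseline
  (`baseline_gene_signature()`) is provided for that comparison.
* IPCW AUC and the calibration curve assume censoring independent of
  the risk score; informative censoring biases both.
* The generator's Gaussian equicorrelated blocks are a deliberately
  clean stress-bed, not a portrait of real transcriptomes; pipeline
  performance numbers on synthetic cohorts are operating
  characteristics under the generator's assumptions, not clinical
  claims.
* The published five-pair signature is shipped as published; the
  package validates its *mechanics* (scoring, stratification,
  evaluation) on synthetic cohorts and makes no claim about its
  clinical performance on data it has not seen.
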