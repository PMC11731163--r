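---
title: "Models and methods behind bayescat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bayescat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayescat)
library(dplyr)
```

bayescat analyses perceptual decision-making in orientation categorization
when two Bayesian ingredients are manipulated independently: the *prior*
(category base rates varied across blocks) and the *likelihood* (sensory
uncertainty varied through stimulus contrast). This vignette describes the
observer models, the estimators, the synthetic-data generator used to
validate them, and the numerical and design choices a maintainer would want
spelled out.

## The two tasks

**Two-mean task.** Stimulus orientations are drawn from one of two Gaussian
categories with means 86° and 94° (tilts around vertical) and a shared sd of
5°. Internally the package works in signed degrees relative to the 90°
reference (positive = clockwise), so the categories sit at −4° and +4°.
Because the distributions overlap, even a noiseless observer with the
accuracy-maximizing midpoint criterion is capped at
`pnorm(4/5)` ≈ `r round(100 * max_accuracy(task_gaussian()), 1)`% correct —
the task's design ceiling of 80%.

**Embedded task.** Both categories share a 0° (horizontal) mean but differ
in dispersion: narrow (sd 3°) versus broad (sd 12°). The optimal rule
reports "narrow" when the measurement falls between symmetric boundaries
±k, and — the task's point — those boundaries must *widen* as the
observer's own sensory noise grows. The noiseless ceiling is
`r round(100 * max_accuracy(task_embedded()), 1)`%.

Sessions follow the standard designs: three 320-trial base-rate blocks
(category-B rate 75%, 50%, 25%; neutral block always second, biased order
counterbalanced) for the prior experiment, and two 960-trial sessions of
neutral blocks for the uncertainty experiment. Contrast is drawn uniformly
per trial from the seven-level ladder
(0.004, 0.016, 0.033, 0.093, 0.18, 0.36, 0.72).

## Estimation

### Sensitivity and criterion (two-mean task)

Per participant × block × contrast cell, with H = P(report B | B) and
F = P(report B | A) after an extreme-rate correction,

* d′ = z(H) − z(F)
* c = −(z(H) + z(F)) / 2.

Category B is treated as "signal"; positive c is a bias against reporting
B. Because no published convention is universal, every downstream metric is
defined so its magnitude is convention-invariant.

The default correction is log-linear (add 0.5 to each count, 1 to each
total); a hard clamp of raw rates to [1/(2n), 1 − 1/(2n)] is selectable via
`analysis_config(correction = "clamp")` for sensitivity analyses.

### The ideal observer and suboptimality

For a block with category-B base rate α, the accuracy-maximizing
likelihood-ratio criterion is β_opt = (1 − α)/α and its placement on the
criterion axis is c_opt = ln(β_opt)/d′, computed at the *participant's own*
d′ for that cell. Natural logarithms are used throughout, which makes the
identity c_opt · d′ = ln β_opt exact (tested to 1e−12). Two summary
metrics follow:

* **D_criterion** = c(75% block) − c(25% block) per contrast: the raw
  criterion shift; 0 for a prior-ignoring observer, growing in magnitude as
  d′ falls for a Bayesian one.
* **c_error** = sign(c_opt) · (c_opt − c) per biased block, averaged over
  the two biased blocks per contrast. The sign normalization makes
  "under-shift toward the prior" positive in both blocks so the average is
  meaningful; 0 is optimal. Published work does not state whether its
  criterion error was signed, absolute, or how the two biased blocks were
  combined for a 7 × 2 (contrast × group) analysis; the sign-normalized
  mean is this package's documented choice.

As d′ → 0, c_opt diverges; the pipeline returns an infinite c_error for a
degenerate cell rather than failing, and the c_error > 50 exclusion rule
(below) then removes such participants from optimality analyses — which is
precisely the role of that rule.

### Sensory noise and boundaries (embedded task)

The internal measurement of a category-s_cat stimulus under sensory noise
σ_sens is Gaussian with sd σ_cat = sqrt(s_cat² + σ_sens²), so the
probability of a narrow report is p = 2Φ(k/σ_cat) − 1, with exact inverse
k = σ_cat · z((1+p)/2). Per participant × contrast, the two-step estimator:

1. finds the σ_sens ≥ 0 minimizing the squared discrepancy between the
   boundaries implied by the two category-wise narrow-report proportions,
   and
2. sets k to the mean of the two implied boundaries at that optimum.

With two free parameters and two observed proportions, the two-step
solution coincides with the joint binomial maximum-likelihood fit whenever
the discrepancy can reach zero; the test suite verifies this equivalence
against an independent ML fit. When the proportions are ordered so that no
σ_sens ≥ 0 reconciles a single boundary (e.g. the narrow category produced
*fewer* narrow reports), the fit is returned with `converged = FALSE` and
its residual objective, never a silent `NaN`; non-converged fits are
excluded from group means with a reported count.

The optimal boundary lies at the crossing of the two measurement densities,

k_opt = sqrt( 2 σ_A² σ_B² ln(σ_B/σ_A) / (σ_B² − σ_A²) ),

the positive solution of N(0, σ_A)(k) = N(0, σ_B)(k). The radical spans the
whole expression — that, not a narrower reading, is the dimensionally
consistent crossing point — and the implementation is required by its tests
to agree with a brute-force accuracy-maximizing grid search (step 0.001°)
to within 0.01° across σ_sens ∈ {0, 1, 2, 5, 10, 20}. Boundary
suboptimality is k_error = k − k_opt(σ̂_sens), signed (negative = narrower
than optimal); the absolute value is trivially available, since whether the
field reports this quantity signed or absolute is not standardized.

### Numerical choices

* Optimizer: coarse scan of the squared-discrepancy objective on a
  log-spaced 400-point grid over [0, 100]° (dense near 0, where the
  objective can be flat), then `stats::optimize()` in the bracketing
  interval; convergence declared when the objective is below 1e−8
  squared degrees.
* The Eq.-4 forward/inverse pair round-trips to 1e−10 over (0, 1).
* Proportions of exactly 0 or 1 are rejected by the inversion; the pipeline
  applies the same count correction as the two-mean analysis before
  inverting.
* Degenerate inputs (equal category sds, α ∈ {0, 1}, d′ = 0, empty cells)
  are rejected with messages naming the offending field; the pipeline skips
  empty cells with a per-participant warning.

## Exclusion rules

Defaults in `analysis_config()`:

| rule | threshold | stage |
|---|---|---|
| accuracy over the three highest contrasts | < 0.6 | all analyses |
| fitted k (embedded) | > 100° | all analyses |
| fitted σ_sens (embedded) | > 100° | all analyses |
| criterion error (two-mean) | > 50 | optimality only |
| boundary error (embedded) | > 35° | optimality only |

Each excluded participant is tagged with exactly one rule (priority:
accuracy, k, σ, c_error/k_error) and the report reconciles retained +
excluded = input at every stage. On default-configured synthetic cohorts
these are outlier guards, not filters: fewer than 10% of simulated
participants are removed.

Psychometric tables bin orientations to the 15 centers −14°…+14° in 2°
steps (nearest center, ties to the more clockwise center, extremes
clamped). The protocol literature describes "16 binned orientation levels"
but enumerates these 15 centers; the enumerated list is the checkable
ground truth, so 15 bins are used. Group curves are means of
per-participant proportions with between-participant SEs.

## The synthetic-data generator

`simulate_cohort()` generates complete trial-level datasets plus a
ground-truth table, so every pipeline stage is testable by parameter
recovery. Each simulated observer has:

* a noise map σ(c) = σ_floor + a·c^(−b), defaults σ_floor = 2°, a = 0.08,
  b = 0.9. No psychometric contrast function is published for these tasks;
  this decreasing form spans d′ ≈ 0.55 → 1.5 across the ladder (roughly
  the observed dynamic range) and any decreasing map would serve the
  recovery tests equally.
* a prior weight w on the log prior odds: the two-mean criterion is placed
  at x* = w · ln((1−α)/α) · (sd² + σ²)/(mean_B − mean_A); w = 1 is
  Bayes-optimal for the observer's own noise, w = 0 prior-ignoring.
* boundary distortion γ and noise misestimation ρ in the embedded task:
  k_obs = γ · k_opt(ρ·σ). γ and ρ are *jointly unidentifiable* from choice
  data, since only k_obs is observable — the recovery tooling treats γ at
  ρ = 1 as the recoverable suboptimality axis and documents the confound
  rather than hiding it.
* a lapse rate λ (default 0.02) replacing the response with a fair coin —
  kept small but nonzero so extreme-rate correction paths are exercised.
* gamble calibration: check-question stakes follow
  clip(round(99·(w_g·α + (1−w_g)·0.5) + ε), 0, 99), ε ~ N(0, gamble_sd).
  The protocol does not state how often check questions occurred; one per
  80 trials is the configurable default — sparse, but enough for a stable
  per-block mean.

Group presets cover both hypotheses of interest: `"null"` (identical
parameter distributions, the empirically supported pattern) and
`"altered_integration"` (autistic-group prior weight centred on 0.6, the
pattern the altered-integration hypothesis predicts), enabling power-style
experiments.

What the generator deliberately does **not** emulate: reaction times,
confidence ratings (carried in the schema but never analyzed), learning or
drift within a block (priors are explicit and static), criterion jitter
across trials, and asymmetric boundaries. Passing recovery tests therefore
show that the estimators invert the stated observer models — not that real
observers obey those models.

## Validation summary

The test suite validates, among others:

* the closed-form optimal boundary against a brute-force grid oracle;
* the two-step fit against exact forward-model proportions (recovery to
  1e−6) and against an independent joint binomial ML fit;
* parameter recovery over a σ_sens ∈ {1,3,6,12} × k ∈ {3,6,9} factorial at
  10⁴ trials per contrast: median absolute error of both parameters below
  5% of truth (~200 binomial refits);
* an all-optimal simulated cohort (w = γ = ρ = 1, no lapses; 20
  participants, ~2000 trials per contrast cell — sizes chosen so estimator
  bias is negligible against the between-participant SE) shows group-mean
  c_error and k_error within 2 SE of zero at every contrast;
* the qualitative Bayesian signatures: |D_criterion| grows as contrast
  falls, fitted boundaries shift outward as contrast falls, and a 75%
  base-rate block shifts the psychometric curve upward at every bin.

```{r recovery-demo}
rec <- recovery_study(sigma_grid = c(3, 6), k_grid = c(6), n_per_category = 5000,
                      n_fits_per_cell = 4, seed = 1)
rec |>
  group_by(sigma_true, k_true) |>
  summarise(bias_sigma = mean(sigma_error), bias_k = mean(k_error),
            .groups = "drop")
```

## Known limitations

* Equal-variance SDT only for the two-mean task; no ROC/confidence
  modelling.
* The embedded fit assumes symmetric, trial-stable boundaries — the same
  assumption the estimator's target model makes.
* Inferential statistics (ANOVAs, Bayes factors, mixed models) are
  consumers of the exported tidy tables, not pipeline stages; any stats
  package can take them from there.
* Configs are plain R lists with a shipped JSON default
  (`load_config()`); YAML is intentionally not a second format.
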