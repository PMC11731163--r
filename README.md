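# bayescat

Signal-detection and ideal-observer analysis of orientation categorization
under manipulated priors and sensory uncertainty.

## What problem this addresses

In Bayesian accounts of perception, a decision combines *prior knowledge*
(how likely each category is) with the *likelihood* (how reliable the
sensory evidence is). Testing whether observers — for example autistic
versus non-autistic adults — integrate these two ingredients requires
manipulating them independently and benchmarking each observer against the
ideal observer *at that observer's own sensitivity*. bayescat implements
that analysis chain for two orientation categorization tasks:

* **Two-mean task** (prior manipulation): Gaussian categories at 86°/94°
  (sd 5°), with category base rates varied across blocks (25/50/75%).
  Standard equal-variance SDT gives, per block × contrast cell,

  d′ = z(H) − z(F),  c = −(z(H) + z(F))/2,

  and the ideal observer places its criterion at c_opt = ln(β_opt)/d′ with
  β_opt = (1 − α)/α for base rate α. Suboptimality is
  c_error = sign(c_opt)·(c_opt − c), and the prior-integration index is
  D_criterion = c(75%) − c(25%).

* **Embedded task** (uncertainty manipulation): same-mean categories with
  sd 3° (narrow) vs 12° (broad). With combined noise
  σ_cat = √(s_cat² + σ_sens²) and symmetric boundaries ±k, the narrow-report
  probability is 2Φ(k/σ_cat) − 1. A two-step estimator recovers σ_sens and
  k per contrast from the two category-wise report proportions; the optimal
  boundary is the density crossing
  k_opt = √(2σ_A²σ_B² ln(σ_B/σ_A)/(σ_B² − σ_A²)), and
  k_error = k − k_opt.

The package also ships a synthetic-cohort generator (tunable prior weight,
boundary distortion, lapses, gamble calibration) so the full pipeline —
psychometric binning, outlier-exclusion rules, group summaries — is
validated end-to-end by parameter recovery, and a `recovery_study()`
harness for that validation.

## Worked example

Simulate a 12-participant cohort of near-optimal observers and run the
base-rate analysis:

```r
library(bayescat)
library(dplyr)

cohort <- simulate_cohort(cohort_config(n_autistic = 6, n_non_autistic = 6,
                                        trials_per_block = 960, seed = 42))
res <- run_experiment1_analysis(cohort$trials)

res$group_d_criterion |>
  group_by(contrast) |>
  summarise(d_criterion = mean(d_criterion_mean))
#>   contrast d_criterion
#> 1    0.004       -3.61
#> 2    0.016       -1.96
#> 3    0.033       -1.54
#> 4    0.093       -1.58
#> 5    0.18        -1.49
#> 6    0.36        -1.40
#> 7    0.72        -1.49
```

The criterion shift between the 75% and 25% blocks is negative (criteria
move toward the likelier category) and largest in magnitude at the lowest
contrast — more reliance on the prior when the evidence is weak, the
Bayesian signature. The manipulation check behaves too: mean stakes of
24.4, 49.4 and 73.6 cents in the 25%, 50% and 75% blocks track the base
rates.

For the embedded task, fitting report proportions generated by an observer
with σ_sens = 4° and boundary k = 6°:

```r
fit <- fit_embedded_observer(
  p_narrow_given_A = prob_report_narrow(6, combined_sd(3, 4)),
  p_narrow_given_B = prob_report_narrow(6, combined_sd(12, 4)))
fit
#>   sigma_sens     k  objective converged
#> 1       4.00  6.00   1.48e-17      TRUE
optimal_boundary(fit$sigma_sens)$k_opt
#> [1] 7.42
```

The estimator recovers the generating parameters exactly, and
k − k_opt = 6 − 7.42 < 0 says this observer's boundaries are narrower than
optimal for its noise level.

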