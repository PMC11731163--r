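# Independent oracles used to check the analytic implementations.

# Brute-force accuracy-maximizing symmetric boundary for an embedded task:
# grid search over k, no use of the closed form.
brute_force_k_opt <- function(sigma_A, sigma_B, k_max = 6 * sigma_B,
                              step = 0.001) {
  ks <- seq(step, k_max, by = step)
  acc <- 0.5 * (2 * pnorm(ks / sigma_A) - 1) + 0.5 * (2 * pnorm(-ks / sigma_B))
  ks[which.max(acc)]
}

# Joint binomial maximum-likelihood fit of (sigma_sens, k) from narrow-report
# counts, as an independent cross-check of the two-step estimator.
ml_fit_embedded <- function(x_a, n_a, x_b, n_b, task = task_embedded()) {
  nll <- function(par) {
    sigma <- exp(par[1])
    k <- exp(par[2])
    p_a <- 2 * pnorm(k / sqrt(task$sd_narrow^2 + sigma^2)) - 1
    p_b <- 2 * pnorm(k / sqrt(task$sd_broad^2 + sigma^2)) - 1
    p_a <- min(max(p_a, 1e-12), 1 - 1e-12)
    p_b <- min(max(p_b, 1e-12), 1 - 1e-12)
    -(dbinom(x_a, n_a, p_a, log = TRUE) + dbinom(x_b, n_b, p_b, log = TRUE))
  }
  fit <- optim(c(log(3), log(5)), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(sigma_sens = exp(fit$par[1]), k = exp(fit$par[2]))
}

# A deterministic trial tibble with known counts, for tally/plumbing tests.
make_trials <- function(true_category, response, participant_id = "p1",
                        group = "non-autistic", experiment = 1,
                        block_alpha_B = 0.5, contrast = 0.72,
                        orientation_deg = 0) {
  tibble::tibble(
    participant_id = participant_id, group = group, experiment = experiment,
    block_alpha_B = block_alpha_B, contrast = contrast,
    orientation_deg = orientation_deg,
    true_category = true_category, response = response,
    confidence = NA_integer_, rt_s = NA_real_, gamble_stake_B = NA_real_
  )
}
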