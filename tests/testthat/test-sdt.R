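# Signal-detection estimation, ideal-observer criterion, suboptimality.

test_that("response tallies conserve trials and reject mixed input", {
  trials <- make_trials(
    true_category = c(rep("B", 6), rep("A", 4)),
    response = c(rep("B", 5), "A", "B", rep("A", 3))
  )
  counts <- count_responses(trials)
  expect_equal(counts$n_B_given_B, 5)
  expect_equal(counts$n_trials_B, 6)
  expect_equal(counts$n_B_given_A, 1)
  expect_equal(counts$n_trials_A, 4)

  mixed <- dplyr::bind_rows(trials, make_trials("A", "A", participant_id = "p2"))
  expect_error(count_responses(mixed), "single participant")
  exp2 <- make_trials("A", "A", experiment = 2)
  expect_error(count_responses(exp2), "experiment 1")

  # block totals are conserved over cells on simulated data
  sim <- simulate_participant_exp1(observer_params(), seed = 5)
  counts_sim <- count_responses(sim)
  totals <- counts_sim |>
    dplyr::group_by(block_alpha_B) |>
    dplyr::summarise(n = sum(n_trials_A + n_trials_B))
  expect_equal(totals$n, rep(320L, 3))
})

test_that("d-prime and criterion follow the normal-quantile definitions", {
  # H and F one z-unit either side of the mean: d' = 2, c = 0
  counts <- tibble::tibble(
    participant_id = "p1", block_alpha_B = 0.5, contrast = 0.72,
    n_B_given_B = 8413, n_trials_B = 10000,
    n_B_given_A = 1587, n_trials_A = 10000
  )
  est <- estimate_dprime_criterion(counts, "clamp")
  expect_equal(est$d_prime, 2, tolerance = 1e-3)
  expect_equal(est$criterion_c, 0, tolerance = 1e-3)

  # H = F gives no discrimination whatever the rate
  for (p in c(0.1, 0.5, 0.9)) {
    eq <- estimate_dprime_criterion(dplyr::mutate(
      counts, n_B_given_B = round(p * 1e4), n_B_given_A = round(p * 1e4)))
    expect_equal(eq$d_prime, 0, tolerance = 1e-3)
  }

  # perfect performance under the log-linear correction (frozen from qnorm)
  perfect <- dplyr::mutate(counts, n_B_given_B = 20, n_trials_B = 20,
                           n_B_given_A = 0, n_trials_A = 20)
  est_ll <- estimate_dprime_criterion(perfect, "loglinear")
  expect_equal(est_ll$hit_rate, 20.5 / 21)
  expect_equal(est_ll$fa_rate, 0.5 / 21)
  expect_equal(est_ll$d_prime, 3.961505, tolerance = 1e-6)

  # clamp correction truncates raw rates to [1/(2n), 1 - 1/(2n)]
  est_cl <- estimate_dprime_criterion(perfect, "clamp")
  expect_equal(est_cl$hit_rate, 1 - 1 / 40)
  expect_equal(est_cl$fa_rate, 1 / 40)

  zero <- dplyr::mutate(counts, n_trials_A = 0, n_B_given_A = 0)
  expect_error(estimate_dprime_criterion(zero), "zero trials")
})

test_that("relabeling the categories negates c and preserves d-prime", {
  set.seed(31)
  trials <- simulate_participant_exp1(observer_params(), seed = 31)
  est <- estimate_dprime_criterion(count_responses(trials))
  flip <- function(x) ifelse(x == "A", "B", "A")
  swapped <- dplyr::mutate(trials,
                           true_category = flip(true_category),
                           response = flip(response),
                           block_alpha_B = 1 - block_alpha_B)
  est_sw <- estimate_dprime_criterion(count_responses(swapped)) |>
    dplyr::mutate(block_alpha_B = 1 - block_alpha_B) |>
    dplyr::arrange(block_alpha_B, contrast)
  est <- dplyr::arrange(est, block_alpha_B, contrast)
  expect_equal(est_sw$d_prime, est$d_prime, tolerance = 1e-12)
  expect_equal(est_sw$criterion_c, -est$criterion_c, tolerance = 1e-12)
})

test_that("optimal criterion follows the prior odds and its identities", {
  expect_equal(optimal_beta(0.25), 3)
  expect_equal(optimal_beta(0.5), 1)
  expect_equal(optimal_beta(0.75), 1 / 3)
  expect_error(optimal_beta(0), "strictly")
  expect_error(optimal_beta(1), "strictly")

  expect_equal(optimal_criterion(1, 1.7), 0)
  expect_equal(optimal_criterion(3, 2), 0.5493061, tolerance = 1e-6)
  expect_equal(optimal_criterion(3, 0.05), 21.97225, tolerance = 1e-4)
  expect_error(optimal_criterion(3, 0), "unbounded")
  expect_error(optimal_criterion(-1, 1), "positive")

  set.seed(77)
  for (i in 1:50) {
    alpha <- runif(1, 0.05, 0.95)
    d <- runif(1, 0.1, 4) * sample(c(-1, 1), 1)
    beta <- optimal_beta(alpha)
    # exact identity c_opt * d' = ln(beta)
    expect_lt(abs(optimal_criterion(beta, d) * d - log(beta)), 1e-12)
    # antisymmetry between complementary base rates
    expect_lt(abs(optimal_criterion(beta, d) +
                    optimal_criterion(optimal_beta(1 - alpha), d)), 1e-12)
  }
})

test_that("criterion shift and criterion error behave as ideal-observer metrics", {
  d <- 1
  c75 <- optimal_criterion(optimal_beta(0.75), d)
  c25 <- optimal_criterion(optimal_beta(0.25), d)
  expect_equal(criterion_shift(c75, c25), -2.197225, tolerance = 1e-6)
  expect_equal(criterion_shift(0.3, 0.3), 0)

  expect_equal(criterion_error(c75, d, 0.75), 0, tolerance = 1e-12)
  expect_equal(criterion_error(0, 1, 0.25), log(3), tolerance = 1e-12)
  # sign-normalized symmetry between the two biased blocks
  expect_equal(criterion_error(0, 1, 0.75), log(3), tolerance = 1e-12)
  expect_error(criterion_error(0, 1, 0.5), "biased blocks")
})

test_that("criterion error vanishes for an ideal observer and hits |c_opt| for a prior-ignoring one", {
  # 1e4 trials per block x contrast cell: single contrast, large blocks
  ladder <- contrast_ladder(0.72)
  design <- session_design(c(0.75, 0.5, 0.25), trials_per_block = 1e4)
  ideal <- simulate_participant_exp1(
    observer_params(noise_floor = 4, noise_scale = 0, lapse = 0),
    design, contrasts = ladder, seed = 91)
  est <- estimate_dprime_criterion(count_responses(ideal)) |>
    dplyr::filter(block_alpha_B != 0.5)
  errs <- criterion_error(est$criterion_c, est$d_prime, est$block_alpha_B)
  expect_lt(abs(mean(errs)), 0.05)

  ignorer <- simulate_participant_exp1(
    observer_params(noise_floor = 4, noise_scale = 0, prior_weight = 0, lapse = 0),
    design, contrasts = ladder, seed = 92)
  est0 <- estimate_dprime_criterion(count_responses(ignorer)) |>
    dplyr::filter(block_alpha_B != 0.5)
  errs0 <- criterion_error(est0$criterion_c, est0$d_prime, est0$block_alpha_B)
  copt0 <- abs(optimal_criterion(optimal_beta(est0$block_alpha_B), est0$d_prime))
  expect_equal(mean(errs0), mean(copt0), tolerance = 0.05)
})

test_that("expected criterion shift shrinks with contrast for a prior-using observer", {
  # generative closed form: |D| = 2 ln 3 / d'(contrast), no noisy estimates
  params <- observer_params()
  ladder <- as.numeric(contrast_ladder())
  sigma <- sensory_noise(params, ladder)
  d_true <- 8 / sqrt(25 + sigma^2)
  d_mag <- abs(criterion_shift(
    optimal_criterion(optimal_beta(0.75), d_true),
    optimal_criterion(optimal_beta(0.25), d_true)
  ))
  expect_true(all(diff(d_mag) <= 0))
  expect_true(all(diff(d_true) > 0))
})
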