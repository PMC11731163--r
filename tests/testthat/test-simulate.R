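# Synthetic observers and cohorts.

test_that("observer parameters are validated and the noise map decreases", {
  expect_error(observer_params(noise_floor = 0), "noise map")
  expect_error(observer_params(prior_weight = 2), "prior_weight")
  expect_error(observer_params(lapse = 0.5), "lapse")
  p <- observer_params()
  sig <- sensory_noise(p, as.numeric(contrast_ladder()))
  expect_true(all(sig > 0))
  expect_true(all(diff(sig) < 0))
})

test_that("base-rate observer places its criterion at the Bayes point", {
  # fixed noise sigma = 5, biased block: theoretical rates from the
  # closed-form criterion x* = ln(1/3) * (25 + 25) / 8 = -6.8663 degrees
  params <- observer_params(noise_floor = 5, noise_scale = 0, lapse = 0)
  design <- session_design(0.75, trials_per_block = 2e4)
  trials <- simulate_participant_exp1(params, design,
                                      contrasts = contrast_ladder(0.72),
                                      seed = 41)
  xstar <- log(1 / 3) * 50 / 8
  expect_equal(xstar, -6.866327, tolerance = 1e-6)
  sigma_tot <- sqrt(25 + 25)
  h_theory <- pnorm((4 - xstar) / sigma_tot)
  f_theory <- pnorm((-4 - xstar) / sigma_tot)
  emp <- count_responses(trials)
  h_emp <- emp$n_B_given_B / emp$n_trials_B
  f_emp <- emp$n_B_given_A / emp$n_trials_A
  expect_lt(abs(h_emp - h_theory),
            3 * sqrt(h_theory * (1 - h_theory) / emp$n_trials_B))
  expect_lt(abs(f_emp - f_theory),
            3 * sqrt(f_theory * (1 - f_theory) / emp$n_trials_A))
  # neutral block: midpoint rule, so hit and correct-rejection rates match
  neutral <- simulate_participant_exp1(params, session_design(0.5, 2e4),
                                       contrasts = contrast_ladder(0.72),
                                       seed = 42)
  estn <- estimate_dprime_criterion(count_responses(neutral))
  expect_lt(abs(estn$criterion_c), 0.05)
})

test_that("simulated sensitivity rises and criterion shift falls with contrast", {
  params <- observer_params(lapse = 0)
  trials <- simulate_participant_exp1(params,
                                      session_design_exp1(trials_per_block = 2e4),
                                      seed = 43)
  est <- estimate_dprime_criterion(count_responses(trials))
  d_by_contrast <- est |>
    dplyr::group_by(contrast) |>
    dplyr::summarise(d = mean(d_prime)) |>
    dplyr::arrange(contrast)
  expect_gt(cor(d_by_contrast$contrast, d_by_contrast$d, method = "spearman"), 0.9)
  shifts <- est |>
    dplyr::filter(block_alpha_B != 0.5) |>
    dplyr::select(block_alpha_B, contrast, criterion_c) |>
    tidyr::pivot_wider(names_from = block_alpha_B, values_from = criterion_c) |>
    dplyr::mutate(mag = abs(criterion_shift(`0.75`, `0.25`)))
  expect_lt(shifts$mag[which.max(shifts$contrast)],
            shifts$mag[which.min(shifts$contrast)])
})

test_that("neutral-prior accuracy never beats the task ceiling", {
  params <- observer_params(noise_floor = 0.6, noise_scale = 0.001, lapse = 0)
  trials <- simulate_participant_exp1(params, session_design(0.5, 2e4), seed = 44)
  acc <- trials |>
    dplyr::group_by(contrast) |>
    dplyr::summarise(acc = mean(response == true_category), n = dplyr::n())
  ceiling <- max_accuracy(task_gaussian())
  expect_true(all(acc$acc <= ceiling + 3 * sqrt(ceiling * (1 - ceiling) / acc$n)))

  trials2 <- simulate_participant_exp2(params, session_design_exp2(4000), seed = 45)
  acc2 <- trials2 |>
    dplyr::group_by(contrast) |>
    dplyr::summarise(acc = mean(response == true_category), n = dplyr::n())
  ceiling2 <- max_accuracy(task_embedded())
  expect_true(all(acc2$acc <= ceiling2 + 3 * sqrt(ceiling2 * (1 - ceiling2) / acc2$n)))
})

test_that("embedded-task observer uses its distorted boundary", {
  # constant noise: the observer's boundary is constant across contrast
  params <- observer_params(noise_floor = 4, noise_scale = 0, lapse = 0)
  k_true <- optimal_boundary(4, task_embedded())$k_opt
  trials <- simulate_participant_exp2(params, session_design_exp2(2000), seed = 46)
  p_by_cat <- trials |>
    dplyr::group_by(true_category) |>
    dplyr::summarise(p = mean(response == "A"), n = dplyr::n())
  p_a_theory <- prob_report_narrow(k_true, combined_sd(3, 4))
  p_b_theory <- prob_report_narrow(k_true, combined_sd(12, 4))
  expect_lt(abs(p_by_cat$p[p_by_cat$true_category == "A"] - p_a_theory), 0.02)
  expect_lt(abs(p_by_cat$p[p_by_cat$true_category == "B"] - p_b_theory), 0.02)

  # a conservative boundary (gamma < 1) yields negative fitted k_error
  narrow <- observer_params(boundary_scale = 0.7, lapse = 0)
  tr <- simulate_participant_exp2(narrow, session_design_exp2(3000), seed = 47)
  fits <- run_experiment2_analysis(tr)$fits
  expect_true(all(fits$k_error < 0))
})

test_that("gamble stakes follow the calibration model", {
  p1 <- observer_params(gamble_weight = 1, gamble_sd = 0)
  expect_equal(simulate_gamble_responses(p1, 0.75, 5), rep(74, 5))
  expect_equal(simulate_gamble_responses(p1, 0.25, 3), rep(25, 3))
  p0 <- observer_params(gamble_weight = 0, gamble_sd = 0)
  expect_equal(simulate_gamble_responses(p0, 0.75, 4), rep(50, 4))
  set.seed(48)
  pn <- observer_params(gamble_weight = 1, gamble_sd = 5)
  means <- vapply(c(0.25, 0.5, 0.75),
                  function(a) mean(simulate_gamble_responses(pn, a, 500)),
                  numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means >= 0 & means <= 99))
})

test_that("cohort simulation is deterministic and matches requested sizes", {
  cfg <- cohort_config(n_autistic = 3, n_non_autistic = 4,
                       trials_per_block = 96, seed = 49)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(dplyr::n_distinct(a$trials$participant_id), 7)
  sizes <- dplyr::count(dplyr::distinct(a$trials, participant_id, group), group)
  expect_equal(sizes$n[sizes$group == "autistic"], 3)
  expect_equal(sizes$n[sizes$group == "non-autistic"], 4)
  expect_equal(nrow(a$trials), 7 * 3 * 96)
  # ground truth joins 1:1
  expect_setequal(unique(a$ground_truth$participant_id),
                  unique(a$trials$participant_id))
  expect_equal(nrow(a$ground_truth), 7 * 7)  # participants x ladder levels
  # byte-identical CSV round trip
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(a$trials, p1)
  write_trials(simulate_cohort(cfg)$trials, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("group presets separate or coincide as configured", {
  null_cfg <- cohort_config(n_autistic = 8, n_non_autistic = 8,
                            trials_per_block = 700, seed = 50)
  alt_cfg <- cohort_config(n_autistic = 8, n_non_autistic = 8,
                           preset = "altered_integration",
                           trials_per_block = 700, seed = 50)
  expect_equal(alt_cfg$means$autistic$prior_weight, 0.6)
  expect_equal(alt_cfg$means$`non-autistic`$prior_weight, 1)
  alt <- simulate_cohort(alt_cfg)
  res <- run_experiment1_analysis(alt$trials)
  shift <- res$d_criterion |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(abs(d_criterion)))
  # reduced prior weight means a smaller criterion shift
  expect_lt(shift$m[shift$group == "autistic"],
            shift$m[shift$group == "non-autistic"])
})
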