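# Synthetic observers and cohorts: trial-level response generation for both
# tasks from explicit observer models with tunable suboptimality, plus
# ground-truth emission for parameter-recovery studies.

#' Generative parameters of a simulated observer
#'
#' The observer's sensory noise at contrast c follows
#' sigma(c) = noise_floor + noise_scale * c^(-noise_exponent), a decreasing
#' map chosen so that sensitivity spans the realistic range across the
#' default contrast ladder. Decision suboptimality is controlled by:
#'
#' * `prior_weight` (w): weight on the log prior odds when placing the
#'   criterion in the base-rate task; 1 = optimal, 0 = prior-ignoring.
#' * `boundary_scale` (gamma): multiplicative distortion of the embedded-task
#'   boundary, k_obs = gamma * k_opt(sigma_assumed); 1 = optimal.
#' * `noise_misestimate` (rho): distortion of the observer's belief about its
#'   own noise, sigma_assumed = rho * sigma(c); 1 = accurate. gamma and rho
#'   are jointly unidentifiable from the boundary alone (only k_obs is
#'   observable), which the recovery tooling documents rather than hides.
#' * `lapse` (lambda): probability of replacing the response with a fair coin.
#' * `gamble_weight`, `gamble_sd`: calibration and noise of check-question
#'   stakes.
#'
#' @param noise_floor,noise_scale,noise_exponent Noise-map parameters
#'   (degrees, degrees, unitless).
#' @param prior_weight Weight in `[0, 1.5]` on the log prior odds.
#' @param boundary_scale,noise_misestimate Positive distortion factors.
#' @param lapse Lapse probability in `[0, 0.1]`.
#' @param gamble_weight Stake calibration (1 = stakes track the base rate).
#' @param gamble_sd Stake noise in cents.
#' @return An `observer_params` list.
#' @export
observer_params <- function(noise_floor = 2, noise_scale = 0.08,
                            noise_exponent = 0.9,
                            prior_weight = 1, boundary_scale = 1,
                            noise_misestimate = 1, lapse = 0.02,
                            gamble_weight = 1, gamble_sd = 5) {
  p <- list(
    noise_floor = noise_floor, noise_scale = noise_scale,
    noise_exponent = noise_exponent, prior_weight = prior_weight,
    boundary_scale = boundary_scale, noise_misestimate = noise_misestimate,
    lapse = lapse, gamble_weight = gamble_weight, gamble_sd = gamble_sd
  )
  if (p$noise_floor <= 0 || p$noise_scale < 0 || p$noise_exponent <= 0) {
    stop("noise map must be positive and decreasing in contrast", call. = FALSE)
  }
  if (p$prior_weight < 0 || p$prior_weight > 1.5) {
    stop("`prior_weight` must lie in [0, 1.5]", call. = FALSE)
  }
  if (p$lapse < 0 || p$lapse > 0.1) stop("`lapse` must lie in [0, 0.1]", call. = FALSE)
  if (p$boundary_scale <= 0 || p$noise_misestimate <= 0) {
    stop("`boundary_scale` and `noise_misestimate` must be positive", call. = FALSE)
  }
  structure(p, class = "observer_params")
}

#' Sensory noise implied by an observer's noise map
#'
#' @param params An [observer_params()] object.
#' @param contrast Michelson contrast(s) in (0, 1].
#' @return sigma_sens in degrees (vectorized over `contrast`).
#' @export
sensory_noise <- function(params, contrast) {
  stopifnot(inherits(params, "observer_params"))
  params$noise_floor + params$noise_scale * contrast^(-params$noise_exponent)
}

new_trial_tibble <- function(n, participant_id, group, experiment) {
  tibble::tibble(
    participant_id = participant_id,
    group = group,
    experiment = experiment,
    block_alpha_B = NA_real_,
    contrast = NA_real_,
    orientation_deg = NA_real_,
    true_category = NA_character_,
    response = NA_character_,
    confidence = NA_integer_,
    rt_s = NA_real_,
    gamble_stake_B = NA_real_,
    .rows = n
  )
}

apply_lapse <- function(response, lapse) {
  n <- length(response)
  lapsed <- stats::runif(n) < lapse
  coin <- ifelse(stats::runif(n) < 0.5, "A", "B")
  ifelse(lapsed, coin, response)
}

#' Simulate a participant in the base-rate (prior) experiment
#'
#' On each trial the observer receives a noisy measurement
#' x ~ N(orientation, sigma(contrast)) and reports B when x exceeds the
#' criterion
#' x* = w * ln((1 - alpha_B)/alpha_B) * (sd^2 + sigma^2) / (mean_B - mean_A)
#' (degrees relative to the task reference): the Bayes-optimal placement for
#' its own noise when w = 1, scaled by the prior weight w otherwise. With
#' probability `lapse` the response is replaced by a fair coin. Contrast is
#' drawn uniformly from the ladder on each trial. Every `check_every` trials
#' the row also carries a gamble stake from [simulate_gamble_responses()].
#'
#' @param params An [observer_params()] object.
#' @param design A [session_design()] (default the standard three-block
#'   base-rate session).
#' @param task A [task_gaussian()] object.
#' @param contrasts A [contrast_ladder()].
#' @param participant_id,group Identifiers carried into the trial records.
#' @param check_every Trial spacing of check questions (one per
#'   `check_every` trials).
#' @param seed Optional integer seed for this participant's stream.
#' @return A trial tibble in the standard schema.
#' @export
simulate_participant_exp1 <- function(params, design = session_design_exp1(),
                                      task = task_gaussian(),
                                      contrasts = contrast_ladder(),
                                      participant_id = "sim",
                                      group = "non-autistic",
                                      check_every = 80, seed = NULL) {
  stopifnot(inherits(params, "observer_params"), inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  sep <- task$mean_B - task$mean_A
  blocks <- lapply(design$alpha_B, function(alpha) {
    n <- design$trials_per_block
    stim <- sample_trial_stimulus(task, alpha, n)
    contrast <- sample(as.numeric(contrasts), n, replace = TRUE)
    sigma <- sensory_noise(params, contrast)
    x <- stim$orientation + stats::rnorm(n, 0, sigma)
    xstar <- params$prior_weight * log((1 - alpha) / alpha) *
      (task$sd^2 + sigma^2) / sep
    response <- apply_lapse(ifelse(x > xstar, "B", "A"), params$lapse)
    out <- new_trial_tibble(n, participant_id, group, 1L)
    out$block_alpha_B <- alpha
    out$contrast <- contrast
    out$orientation_deg <- stim$orientation
    out$true_category <- stim$true_category
    out$response <- response
    check_idx <- seq_len(n)[seq_len(n) %% check_every == 0]
    if (length(check_idx) > 0) {
      out$gamble_stake_B[check_idx] <-
        simulate_gamble_responses(params, alpha, length(check_idx))
    }
    out
  })
  dplyr::bind_rows(blocks)
}

#' Simulate a participant in the sensory-uncertainty experiment
#'
#' The observer reports the narrow category when |x| < k_obs(contrast), with
#' k_obs = boundary_scale * k_opt(noise_misestimate * sigma(contrast)): the
#' ideal-observer boundary for the noise level the observer believes it has,
#' optionally distorted multiplicatively. Lapses as in
#' [simulate_participant_exp1()].
#'
#' @inheritParams simulate_participant_exp1
#' @param design A [session_design()] (default two 960-trial sessions of
#'   neutral blocks).
#' @param task A [task_embedded()] object.
#' @return A trial tibble in the standard schema.
#' @export
simulate_participant_exp2 <- function(params, design = session_design_exp2(),
                                      task = task_embedded(),
                                      contrasts = contrast_ladder(),
                                      participant_id = "sim",
                                      group = "non-autistic",
                                      check_every = 80, seed = NULL) {
  stopifnot(inherits(params, "observer_params"), inherits(design, "session_design"))
  if (!is.null(seed)) set.seed(seed)
  ladder <- as.numeric(contrasts)
  k_obs_map <- params$boundary_scale *
    optimal_boundary(params$noise_misestimate * sensory_noise(params, ladder),
                     task)$k_opt
  alphas <- rep(design$alpha_B, times = design$n_sessions)
  blocks <- lapply(alphas, function(alpha) {
    n <- design$trials_per_block
    stim <- sample_trial_stimulus(task, alpha, n)
    ci <- sample.int(length(ladder), n, replace = TRUE)
    sigma <- sensory_noise(params, ladder[ci])
    x <- stim$orientation + stats::rnorm(n, 0, sigma)
    response <- apply_lapse(ifelse(abs(x) < k_obs_map[ci], "A", "B"), params$lapse)
    out <- new_trial_tibble(n, participant_id, group, 2L)
    out$block_alpha_B <- alpha
    out$contrast <- ladder[ci]
    out$orientation_deg <- stim$orientation
    out$true_category <- stim$true_category
    out$response <- response
    check_idx <- seq_len(n)[seq_len(n) %% check_every == 0]
    if (length(check_idx) > 0) {
      out$gamble_stake_B[check_idx] <-
        simulate_gamble_responses(params, alpha, length(check_idx))
    }
    out
  })
  dplyr::bind_rows(blocks)
}

#' Simulate check-question gamble stakes
#'
#' A calibrated gambler (gamble_weight = 1) stakes, on average, 99 times the
#' block base rate on category B; a knowledge-free gambler
#' (gamble_weight = 0) stakes about half regardless of block. Stakes are
#' Gaussian-perturbed, rounded, and clipped to the 0-99 cent scale:
#' stake = clip(round(99 * (w_g * alpha_B + (1 - w_g) * 0.5) + e), 0, 99),
#' e ~ N(0, gamble_sd).
#'
#' @param params An [observer_params()] object.
#' @param alpha_B Block base rate of category B.
#' @param n_checks Number of check questions.
#' @return Integer stakes in cents.
#' @export
simulate_gamble_responses <- function(params, alpha_B, n_checks) {
  stopifnot(inherits(params, "observer_params"), n_checks >= 1)
  target <- 99 * (params$gamble_weight * alpha_B +
                    (1 - params$gamble_weight) * 0.5)
  stake <- round(target + stats::rnorm(n_checks, 0, params$gamble_sd))
  pmin(pmax(stake, 0), 99)
}

#' Cohort configuration for synthetic experiments
#'
#' Describes two groups of simulated observers. Each observer's parameters
#' are drawn from group-level Gaussian distributions (truncated to the valid
#' ranges of [observer_params()]). Two named presets cover the contrast of
#' hypotheses the design addresses: `"null"` gives both groups identical
#' parameter distributions; `"altered_integration"` shifts the autistic
#' group's prior weight down (mean 0.6), the pattern the altered-integration
#' hypothesis predicts.
#'
#' @param n_autistic,n_non_autistic Group sizes.
#' @param experiment 1 (base-rate task) or 2 (embedded task).
#' @param preset `"null"` or `"altered_integration"`.
#' @param trials_per_block Trials per block in the session design.
#' @param means Named list overriding group-shared parameter means (any of
#'   the [observer_params()] fields).
#' @param sds Named list of between-participant standard deviations; defaults
#'   are small but nonzero for `noise_floor`, `prior_weight`,
#'   `boundary_scale` and `gamble_weight`.
#' @param autistic_means Named list overriding means for the autistic group
#'   only (applied after `preset`).
#' @param seed Master seed fixing the full cohort bit-for-bit.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_autistic = 10, n_non_autistic = 10,
                          experiment = 1, preset = c("null", "altered_integration"),
                          trials_per_block = 320,
                          means = list(), sds = list(),
                          autistic_means = list(), seed = 1) {
  preset <- match.arg(preset)
  stopifnot(experiment %in% c(1, 2), n_autistic >= 1, n_non_autistic >= 1)
  base_means <- utils::modifyList(list(
    noise_floor = 2, noise_scale = 0.08, noise_exponent = 0.9,
    prior_weight = 1, boundary_scale = 1, noise_misestimate = 1,
    lapse = 0.02, gamble_weight = 1, gamble_sd = 5
  ), means)
  base_sds <- utils::modifyList(list(
    noise_floor = 0.3, noise_scale = 0, noise_exponent = 0,
    prior_weight = 0.1, boundary_scale = 0.1, noise_misestimate = 0,
    lapse = 0, gamble_weight = 0.05, gamble_sd = 0
  ), sds)
  aut_means <- base_means
  if (preset == "altered_integration") aut_means$prior_weight <- 0.6
  aut_means <- utils::modifyList(aut_means, autistic_means)
  structure(
    list(
      n_autistic = n_autistic, n_non_autistic = n_non_autistic,
      experiment = experiment, preset = preset,
      trials_per_block = trials_per_block,
      means = list(autistic = aut_means, `non-autistic` = base_means),
      sds = base_sds, seed = seed
    ),
    class = "cohort_config"
  )
}

draw_observer <- function(means, sds) {
  draw <- function(field, lower, upper) {
    v <- stats::rnorm(1, means[[field]], sds[[field]])
    min(max(v, lower), upper)
  }
  observer_params(
    noise_floor = draw("noise_floor", 0.5, Inf),
    noise_scale = draw("noise_scale", 0, Inf),
    noise_exponent = draw("noise_exponent", 0.1, Inf),
    prior_weight = draw("prior_weight", 0, 1.5),
    boundary_scale = draw("boundary_scale", 0.2, 5),
    noise_misestimate = draw("noise_misestimate", 0.2, 5),
    lapse = draw("lapse", 0, 0.1),
    gamble_weight = draw("gamble_weight", 0, 1),
    gamble_sd = draw("gamble_sd", 0, Inf)
  )
}

#' Simulate a full cohort with ground truth
#'
#' Generates trial-level data for every participant under the configured
#' session design and emits a ground-truth table joinable 1:1 on
#' `participant_id`, carrying each observer's generative parameters and the
#' derived per-contrast true sensory noise plus, per experiment, the true
#' sensitivity (d') or the true boundary (k_obs). The master seed fixes both
#' tables bit-for-bit.
#'
#' @param config A [cohort_config()] object.
#' @return A list with tibbles `trials` and `ground_truth`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_autistic = 2, n_non_autistic = 2,
#'                                         trials_per_block = 64, seed = 7))
#' dplyr::count(cohort$trials, participant_id)
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c(rep("autistic", config$n_autistic),
              rep("non-autistic", config$n_non_autistic))
  ids <- sprintf("%s%02d",
                 ifelse(groups == "autistic", "aut", "non"),
                 c(seq_len(config$n_autistic), seq_len(config$n_non_autistic)))
  part_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  ladder <- contrast_ladder()
  gtask <- task_gaussian()
  etask <- task_embedded()
  trials <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    params <- draw_observer(config$means[[groups[i]]], config$sds)
    if (config$experiment == 1) {
      design <- session_design_exp1(config$trials_per_block,
                                    b_first = i %% 2 == 0)
      trials[[i]] <- simulate_participant_exp1(
        params, design, gtask, ladder, ids[i], groups[i], seed = part_seeds[i])
      sigma <- sensory_noise(params, as.numeric(ladder))
      extra <- tibble::tibble(
        contrast = as.numeric(ladder),
        true_sigma_sens = sigma,
        true_d_prime = (gtask$mean_B - gtask$mean_A) / sqrt(gtask$sd^2 + sigma^2)
      )
    } else {
      design <- session_design_exp2(config$trials_per_block)
      trials[[i]] <- simulate_participant_exp2(
        params, design, etask, ladder, ids[i], groups[i], seed = part_seeds[i])
      sigma <- sensory_noise(params, as.numeric(ladder))
      extra <- tibble::tibble(
        contrast = as.numeric(ladder),
        true_sigma_sens = sigma,
        true_k_obs = params$boundary_scale *
          optimal_boundary(params$noise_misestimate * sigma, etask)$k_opt
      )
    }
    truth[[i]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = ids[i], group = groups[i],
                     experiment = config$experiment),
      tibble::as_tibble(unclass(params)),
      tidyr::nest(extra, per_contrast = dplyr::everything())
    )
  }
  truth_tbl <- dplyr::bind_rows(truth) |> tidyr::unnest("per_contrast")
  list(trials = dplyr::bind_rows(trials), ground_truth = truth_tbl)
}
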