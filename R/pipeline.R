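# End-to-end orchestration: psychometric binning, outlier-exclusion rules,
# per-participant estimation, and group summary tables.

#' Analysis configuration
#'
#' Bundles the tunable choices of the analysis chain: the extreme-rate
#' correction, the outlier-exclusion thresholds, and the psychometric bin
#' centers. Defaults follow the standard protocol: participants with mean
#' accuracy below 0.6 over the three highest contrasts are excluded from all
#' analyses; embedded-task fits with k > 100 or sigma_sens > 100 degrees are
#' excluded from all analyses; criterion error above 50 (base-rate task) or
#' boundary error above 35 degrees (embedded task) excludes a participant
#' from the optimality analyses only.
#'
#' @param correction `"loglinear"` or `"clamp"` extreme-rate correction.
#' @param accuracy_min Minimum mean accuracy over the top contrasts.
#' @param n_top_contrasts How many of the highest contrasts enter the
#'   accuracy screen.
#' @param c_error_max,k_error_max Optimality-stage thresholds (absolute).
#' @param k_max,sigma_max Embedded-fit sanity thresholds in degrees.
#' @param bin_centers Psychometric bin centers in degrees, sorted.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(correction = c("loglinear", "clamp"),
                            accuracy_min = 0.6, n_top_contrasts = 3,
                            c_error_max = 50, k_error_max = 35,
                            k_max = 100, sigma_max = 100,
                            bin_centers = seq(-14, 14, by = 2)) {
  correction <- match.arg(correction)
  stopifnot(accuracy_min > 0, c_error_max > 0, k_error_max > 0,
            k_max > 0, sigma_max > 0)
  if (is.unsorted(bin_centers, strictly = TRUE)) {
    stop("`bin_centers` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(correction = correction, accuracy_min = accuracy_min,
         n_top_contrasts = n_top_contrasts, c_error_max = c_error_max,
         k_error_max = k_error_max, k_max = k_max, sigma_max = sigma_max,
         bin_centers = bin_centers),
    class = "analysis_config"
  )
}

#' Assign orientations to psychometric bins
#'
#' Each trial goes to the nearest listed bin center (ties to the more
#' clockwise, i.e. larger, center); orientations beyond the extreme centers
#' clamp to the extreme bins. Report proportions are computed per
#' participant, then averaged with a between-participant standard error per
#' (group x condition x bin).
#'
#' @param trials Trial tibble (one experiment).
#' @param bin_centers Sorted bin centers in degrees.
#' @param condition Name of the trial column defining the condition
#'   (`"block_alpha_B"` for the base-rate task, `"contrast"` for the
#'   embedded task).
#' @return A tibble with one row per (group, condition, bin):
#'   `orientation_bin_center`, `p_report_B`, `se`, `n` (pooled trials),
#'   `n_participants`.
#' @export
bin_orientations <- function(trials, bin_centers = seq(-14, 14, by = 2),
                             condition = "block_alpha_B") {
  if (nrow(trials) == 0) {
    return(tibble::tibble(group = character(), condition = numeric(),
                          orientation_bin_center = numeric(),
                          p_report_B = numeric(), se = numeric(),
                          n = integer(), n_participants = integer()))
  }
  boundaries <- utils::head(bin_centers, -1) + diff(bin_centers) / 2
  idx <- findInterval(trials$orientation_deg, boundaries) + 1L
  per_part <- trials |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::mutate(
      orientation_bin_center = bin_centers[idx],
      condition = .data[[condition]]
    ) |>
    dplyr::group_by(.data$group, .data$participant_id, .data$condition,
                    .data$orientation_bin_center) |>
    dplyr::summarise(p = mean(.data$response == "B"), n = dplyr::n(),
                     .groups = "drop")
  per_part |>
    dplyr::group_by(.data$group, .data$condition, .data$orientation_bin_center) |>
    dplyr::summarise(
      p_report_B = mean(.data$p),
      se = stats::sd(.data$p) / sqrt(dplyr::n()),
      n = sum(.data$n),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

#' Apply outlier-exclusion rules to participant-level metrics
#'
#' Screens a participant-metrics table against the configured thresholds.
#' Stage `"all"` applies the screens that remove a participant from every
#' analysis (accuracy on the highest contrasts; for the embedded task also
#' extreme fitted k or sigma_sens). Stage `"optimality"` additionally applies
#' the optimality-analysis screens (extreme criterion error or boundary
#' error). Every exclusion names exactly one rule, the first that fires in
#' the order accuracy, k, sigma, c_error/k_error.
#'
#' @param metrics Per-participant tibble with `participant_id`,
#'   `accuracy_top`, and (by experiment) `max_abs_c_error` or `max_k`,
#'   `max_sigma`, `max_abs_k_error`.
#' @param config An [analysis_config()].
#' @param stage `"all"` or `"optimality"`.
#' @param experiment 1 or 2.
#' @return A list: `retained` (filtered metrics) and `report` (tibble of
#'   `participant_id`, `retained`, `rule`, `value`).
#' @export
apply_exclusions <- function(metrics, config = analysis_config(),
                             stage = c("all", "optimality"), experiment = 1) {
  stage <- match.arg(stage)
  stopifnot(experiment %in% c(1, 2))
  rules <- list(list(
    name = "accuracy",
    value = metrics$accuracy_top,
    hit = metrics$accuracy_top < config$accuracy_min
  ))
  if (experiment == 2) {
    rules <- c(rules, list(
      list(name = "k", value = metrics$max_k, hit = metrics$max_k > config$k_max),
      list(name = "sigma", value = metrics$max_sigma,
           hit = metrics$max_sigma > config$sigma_max)
    ))
  }
  if (stage == "optimality") {
    rules <- c(rules, if (experiment == 1) {
      list(list(name = "c_error", value = metrics$max_abs_c_error,
                hit = metrics$max_abs_c_error > config$c_error_max))
    } else {
      list(list(name = "k_error", value = metrics$max_abs_k_error,
                hit = metrics$max_abs_k_error > config$k_error_max))
    })
  }
  rule_name <- rep(NA_character_, nrow(metrics))
  rule_value <- rep(NA_real_, nrow(metrics))
  for (r in rev(rules)) {     # earlier rules overwrite later ones: priority order
    hit <- r$hit & !is.na(r$hit)
    rule_name[hit] <- r$name
    rule_value[hit] <- r$value[hit]
  }
  report <- tibble::tibble(
    participant_id = metrics$participant_id,
    stage = stage,
    retained = is.na(rule_name),
    rule = rule_name,
    value = rule_value
  )
  list(retained = metrics[report$retained, , drop = FALSE], report = report)
}

group_mean_se <- function(df, value_cols, ...) {
  df |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(value_cols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         se = ~stats::sd(.x, na.rm = TRUE) /
                           sqrt(sum(!is.na(.x))))),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}

accuracy_top_contrasts <- function(trials, n_top) {
  ladder <- sort(unique(trials$contrast))
  top <- utils::tail(ladder, n_top)
  trials |>
    dplyr::filter(.data$contrast %in% top, !is.na(.data$response)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(accuracy_top = mean(.data$response == .data$true_category),
                     .groups = "drop")
}

#' Full analysis chain for the base-rate (prior) experiment
#'
#' Per participant: response counts and signal-detection estimates per block
#' x contrast; criterion shift D_criterion = c_75% - c_25% per contrast;
#' sign-normalized criterion error per contrast (mean over the two biased
#' blocks, each against the ideal observer at that cell's own d'); mean
#' gamble stake per block. Accuracy-screened participants are dropped from
#' everything; extreme criterion error additionally drops a participant from
#' the optimality tables. Group summaries are
#' mean +/- between-participant SE.
#'
#' @param trials Trial tibble containing experiment-1 trials.
#' @param config An [analysis_config()].
#' @return A list of tibbles: `sdt` (participant x block x contrast),
#'   `d_criterion` (participant x contrast), `c_error` (participant x
#'   contrast, optimality-screened), `psychometric`, `gamble`,
#'   `group_sdt`, `group_d_criterion`, `group_c_error`, `exclusions`.
#' @export
run_experiment1_analysis <- function(trials, config = analysis_config()) {
  trials <- dplyr::filter(trials, .data$experiment == 1)
  if (nrow(trials) == 0) stop("no experiment-1 trials in `trials`", call. = FALSE)

  sdt <- trials |>
    dplyr::group_split(.data$participant_id) |>
    lapply(function(tr) {
      counts <- count_responses(tr)
      sparse <- counts$n_trials_A == 0 | counts$n_trials_B == 0
      if (any(sparse)) {
        warning(sprintf("participant %s: skipping %d cell(s) with no trials in one category",
                        tr$participant_id[1], sum(sparse)), call. = FALSE)
        counts <- counts[!sparse, , drop = FALSE]
      }
      estimate_dprime_criterion(counts, config$correction) |>
        dplyr::mutate(group = tr$group[1])
    }) |>
    dplyr::bind_rows()

  biased <- sdt |>
    dplyr::filter(.data$block_alpha_B != 0.5) |>
    dplyr::mutate(
      # same formulas as optimal_criterion()/criterion_error(), but a cell
      # with d' = 0 yields an infinite error (caught by the c_error screen)
      # instead of aborting the whole analysis
      c_opt = log(optimal_beta(.data$block_alpha_B)) / .data$d_prime,
      c_error = sign(.data$c_opt) * (.data$c_opt - .data$criterion_c)
    )
  wide <- biased |>
    dplyr::select("participant_id", "group", "contrast", "block_alpha_B",
                  "criterion_c") |>
    tidyr::pivot_wider(names_from = "block_alpha_B",
                       values_from = "criterion_c", names_prefix = "c_")
  d_criterion <- wide |>
    dplyr::mutate(d_criterion = criterion_shift(.data$c_0.75, .data$c_0.25)) |>
    dplyr::select("participant_id", "group", "contrast", "d_criterion")
  c_error <- biased |>
    dplyr::group_by(.data$participant_id, .data$group, .data$contrast) |>
    dplyr::summarise(c_error = mean(.data$c_error), .groups = "drop")

  metrics <- accuracy_top_contrasts(trials, config$n_top_contrasts) |>
    dplyr::left_join(
      c_error |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(max_abs_c_error = max(abs(.data$c_error)),
                         .groups = "drop"),
      by = "participant_id"
    )
  excl_all <- apply_exclusions(metrics, config, "all", experiment = 1)
  excl_opt <- apply_exclusions(metrics, config, "optimality", experiment = 1)
  keep_all <- excl_all$retained$participant_id
  keep_opt <- excl_opt$retained$participant_id

  sdt <- dplyr::filter(sdt, .data$participant_id %in% keep_all)
  d_criterion <- dplyr::filter(d_criterion, .data$participant_id %in% keep_all)
  c_error <- dplyr::filter(c_error, .data$participant_id %in% keep_opt)
  psychometric <- bin_orientations(
    dplyr::filter(trials, .data$participant_id %in% keep_all),
    config$bin_centers, condition = "block_alpha_B")
  gamble <- summarize_gamble(
    dplyr::filter(trials, .data$participant_id %in% keep_all))

  list(
    sdt = sdt,
    d_criterion = d_criterion,
    c_error = c_error,
    psychometric = psychometric,
    gamble = gamble$participant,
    group_sdt = group_mean_se(sdt, c("d_prime", "criterion_c"),
                              .data$group, .data$block_alpha_B, .data$contrast),
    group_d_criterion = group_mean_se(d_criterion, "d_criterion",
                                      .data$group, .data$contrast),
    group_c_error = group_mean_se(c_error, "c_error",
                                  .data$group, .data$contrast),
    group_gamble = gamble$group,
    exclusions = dplyr::bind_rows(excl_all$report, excl_opt$report)
  )
}

#' Full analysis chain for the sensory-uncertainty experiment
#'
#' Per participant and contrast: category-wise narrow-report proportions
#' (count-corrected), the two-step fit of sigma_sens and k, the optimal
#' boundary at the fitted sigma_sens, and the boundary error k - k_opt.
#' Accuracy- and sanity-screened (k, sigma_sens) participants are dropped
#' from everything; extreme boundary error additionally drops a participant
#' from the optimality tables. Non-converged fits are flagged and excluded
#' from group means, with the count reported.
#'
#' @param trials Trial tibble containing experiment-2 trials.
#' @param config An [analysis_config()].
#' @param task The [task_embedded()] the data come from.
#' @return A list of tibbles: `fits` (participant x contrast, with
#'   `sigma_sens`, `k`, `k_opt`, `k_error`, `converged`, `objective`),
#'   `k_error` (optimality-screened), `psychometric`, `group_fits`,
#'   `group_k_error`, `exclusions`, and `n_nonconverged`.
#' @export
run_experiment2_analysis <- function(trials, config = analysis_config(),
                                     task = task_embedded()) {
  trials <- dplyr::filter(trials, .data$experiment == 2)
  if (nrow(trials) == 0) stop("no experiment-2 trials in `trials`", call. = FALSE)

  props <- trials |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$contrast,
                    .data$true_category) |>
    dplyr::summarise(n_narrow = sum(.data$response == "A"), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(p_narrow = correct_rate(.data$n_narrow, .data$n,
                                          config$correction)) |>
    dplyr::select("participant_id", "group", "contrast", "true_category",
                  "p_narrow") |>
    tidyr::pivot_wider(names_from = "true_category", values_from = "p_narrow",
                       names_prefix = "p_")

  fits <- props |>
    dplyr::rowwise() |>
    dplyr::mutate(fit_embedded_observer(.data$p_A, .data$p_B, task,
                                        sigma_max = config$sigma_max * 10)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      k_opt = optimal_boundary(.data$sigma_sens, task)$k_opt,
      k_error = .data$k - .data$k_opt
    )

  metrics <- accuracy_top_contrasts(trials, config$n_top_contrasts) |>
    dplyr::left_join(
      fits |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(max_k = max(.data$k), max_sigma = max(.data$sigma_sens),
                         max_abs_k_error = max(abs(.data$k_error)),
                         .groups = "drop"),
      by = "participant_id"
    )
  excl_all <- apply_exclusions(metrics, config, "all", experiment = 2)
  excl_opt <- apply_exclusions(metrics, config, "optimality", experiment = 2)
  keep_all <- excl_all$retained$participant_id
  keep_opt <- excl_opt$retained$participant_id

  fits <- dplyr::filter(fits, .data$participant_id %in% keep_all)
  n_nonconverged <- sum(!fits$converged)
  fits_ok <- dplyr::filter(fits, .data$converged)
  k_error <- fits_ok |>
    dplyr::filter(.data$participant_id %in% keep_opt) |>
    dplyr::select("participant_id", "group", "contrast", "k_error")
  psychometric <- bin_orientations(
    dplyr::filter(trials, .data$participant_id %in% keep_all),
    config$bin_centers, condition = "contrast")

  list(
    fits = fits,
    k_error = k_error,
    psychometric = psychometric,
    group_fits = group_mean_se(fits_ok, c("sigma_sens", "k", "k_opt"),
                               .data$group, .data$contrast),
    group_k_error = group_mean_se(k_error, "k_error",
                                  .data$group, .data$contrast),
    exclusions = dplyr::bind_rows(excl_all$report, excl_opt$report),
    n_nonconverged = n_nonconverged
  )
}

#' Summarize check-question gamble stakes
#'
#' Mean stake on category B per participant and base-rate block, plus the
#' group mean +/- between-participant SE per block: the manipulation check
#' that base-rate knowledge was acquired.
#'
#' @param trials Trial tibble; rows with a non-missing `gamble_stake_B` are
#'   the check questions.
#' @return A list of tibbles `participant` and `group`; both empty (with a
#'   warning) when no check trials are present.
#' @export
summarize_gamble <- function(trials) {
  checks <- dplyr::filter(trials, !is.na(.data$gamble_stake_B))
  if (nrow(checks) == 0) {
    warning("no check-question trials found; gamble summary is empty",
            call. = FALSE)
    empty <- tibble::tibble(participant_id = character(), group = character(),
                            block_alpha_B = numeric(), mean_stake_B = numeric())
    return(list(participant = empty, group = empty[0, ]))
  }
  participant <- checks |>
    dplyr::group_by(.data$participant_id, .data$group, .data$block_alpha_B) |>
    dplyr::summarise(mean_stake_B = mean(.data$gamble_stake_B),
                     n_checks = dplyr::n(), .groups = "drop")
  group <- group_mean_se(participant, "mean_stake_B",
                         .data$group, .data$block_alpha_B)
  list(participant = participant, group = group)
}
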