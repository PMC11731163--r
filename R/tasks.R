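# Task definitions, session designs, stimulus sampling and the shared
# trial-record schema.

#' Two-mean Gaussian orientation categorization task
#'
#' Defines a categorization task in which stimulus orientations are drawn from
#' one of two Gaussian distributions that share a standard deviation but differ
#' in mean (tilts around a vertical reference). Category A is the
#' counter-clockwise category, B the clockwise one.
#'
#' Orientations are handled internally as signed degrees relative to the
#' reference (the midpoint of the two means), positive = clockwise.
#'
#' @param mean_A,mean_B Category means in degrees; `mean_A < mean_B`.
#' @param sd Shared category standard deviation in degrees; must be positive.
#' @return An object of class `gaussian_task` with fields `mean_A`, `mean_B`,
#'   `sd` and `reference` (midpoint of the means).
#' @examples
#' task_gaussian()           # the default 86/94, sd 5 task
#' max_accuracy(task_gaussian())
#' @export
task_gaussian <- function(mean_A = 86, mean_B = 94, sd = 5) {
  stopifnot(is.numeric(mean_A), is.numeric(mean_B), is.numeric(sd))
  if (!(sd > 0)) stop("`sd` must be positive", call. = FALSE)
  if (!(mean_A < mean_B)) stop("`mean_A` must be less than `mean_B`", call. = FALSE)
  structure(
    list(
      mean_A = mean_A, mean_B = mean_B, sd = sd,
      reference = (mean_A + mean_B) / 2
    ),
    class = c("gaussian_task", "categorization_task")
  )
}

#' Embedded (same-mean, different-variance) categorization task
#'
#' Both categories share a mean orientation (horizontal, 0 degrees) but differ
#' in dispersion: a narrow category A and a broad category B. The
#' accuracy-maximizing decision rule reports the narrow category when the
#' measurement falls between symmetric boundaries around the mean, and those
#' boundaries must widen as sensory noise grows.
#'
#' @param mean Shared category mean in degrees (relative reference).
#' @param sd_narrow,sd_broad Standard deviations of the narrow (A) and broad
#'   (B) categories in degrees; `0 < sd_narrow < sd_broad`.
#' @return An object of class `embedded_task` with fields `mean`, `sd_narrow`,
#'   `sd_broad`.
#' @examples
#' task_embedded()          # the default sd 3 vs sd 12 task
#' optimal_boundary(0, task_embedded())
#' @export
task_embedded <- function(mean = 0, sd_narrow = 3, sd_broad = 12) {
  stopifnot(is.numeric(mean), is.numeric(sd_narrow), is.numeric(sd_broad))
  if (!(sd_narrow > 0 && sd_broad > sd_narrow)) {
    stop("need 0 < `sd_narrow` < `sd_broad`", call. = FALSE)
  }
  structure(
    list(mean = mean, sd_narrow = sd_narrow, sd_broad = sd_broad),
    class = c("embedded_task", "categorization_task")
  )
}

#' Contrast ladder
#'
#' The fixed set of Michelson contrasts used to manipulate sensory
#' uncertainty, randomly interleaved across trials.
#'
#' @param levels Strictly increasing contrasts in (0, 1].
#' @return Numeric vector of class `contrast_ladder`.
#' @export
contrast_ladder <- function(levels = c(0.004, 0.016, 0.033, 0.093, 0.18, 0.36, 0.72)) {
  stopifnot(is.numeric(levels), length(levels) >= 1)
  if (any(levels <= 0 | levels > 1)) {
    stop("contrast `levels` must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("contrast `levels` must be strictly increasing", call. = FALSE)
  }
  structure(levels, class = "contrast_ladder")
}

#' Session designs for the two experiments
#'
#' `session_design()` builds a block structure; the two convenience
#' constructors encode the standard designs: the prior-manipulation session
#' (three base-rate blocks of 320 trials, neutral block second, biased block
#' order counterbalanced by flag) and the sensory-uncertainty sessions (two
#' sessions of three neutral 320-trial blocks each).
#'
#' @param alpha_B Per-block probability of category B, in block order.
#' @param trials_per_block Trials per block (default 320).
#' @param n_sessions Number of sessions of this block structure.
#' @return A `session_design` list with fields `alpha_B`, `trials_per_block`,
#'   `n_sessions` and `n_trials` (the per-participant total).
#' @examples
#' session_design_exp1()$n_trials   # 960
#' session_design_exp2()$n_trials   # 1920
#' @export
session_design <- function(alpha_B, trials_per_block = 320, n_sessions = 1) {
  stopifnot(is.numeric(alpha_B), length(alpha_B) >= 1)
  if (any(alpha_B <= 0 | alpha_B >= 1)) {
    stop("`alpha_B` values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(trials_per_block > 0)) stop("`trials_per_block` must be positive", call. = FALSE)
  structure(
    list(
      alpha_B = alpha_B,
      trials_per_block = as.integer(trials_per_block),
      n_sessions = as.integer(n_sessions),
      n_trials = as.integer(length(alpha_B) * trials_per_block * n_sessions)
    ),
    class = "session_design"
  )
}

#' @rdname session_design
#' @param b_first If `TRUE` the block with the high category-B base rate is
#'   run first (the neutral block is always second).
#' @export
session_design_exp1 <- function(trials_per_block = 320, b_first = TRUE) {
  biased <- if (b_first) c(0.75, 0.25) else c(0.25, 0.75)
  session_design(c(biased[1], 0.5, biased[2]), trials_per_block, n_sessions = 1)
}

#' @rdname session_design
#' @export
session_design_exp2 <- function(trials_per_block = 320) {
  session_design(c(0.5, 0.5, 0.5), trials_per_block, n_sessions = 2)
}

#' Draw trial stimuli from a task's category mixture
#'
#' Samples true categories (B with probability `alpha_B`) and orientations
#' from the corresponding category distribution. Orientations are returned as
#' signed degrees relative to the task reference (positive = clockwise).
#'
#' @param task A `gaussian_task` or `embedded_task`.
#' @param alpha_B Probability that a trial belongs to category B; in (0, 1).
#' @param n Number of trials to draw.
#' @return A tibble with columns `true_category` ("A"/"B") and
#'   `orientation` (degrees).
#' @examples
#' set.seed(1)
#' sample_trial_stimulus(task_gaussian(), alpha_B = 0.75, n = 5)
#' @export
sample_trial_stimulus <- function(task, alpha_B, n = 1) {
  if (!is.numeric(alpha_B) || length(alpha_B) != 1 || alpha_B <= 0 || alpha_B >= 1) {
    stop("`alpha_B` must be a single probability strictly in (0, 1)", call. = FALSE)
  }
  is_b <- stats::runif(n) < alpha_B
  ori <- category_orientation_draw(task, is_b)
  tibble::tibble(
    true_category = ifelse(is_b, "B", "A"),
    orientation = ori
  )
}

category_orientation_draw <- function(task, is_b) {
  UseMethod("category_orientation_draw")
}

#' @export
category_orientation_draw.gaussian_task <- function(task, is_b) {
  mu <- ifelse(is_b, task$mean_B, task$mean_A) - task$reference
  stats::rnorm(length(is_b), mean = mu, sd = task$sd)
}

#' @export
category_orientation_draw.embedded_task <- function(task, is_b) {
  stats::rnorm(length(is_b), mean = task$mean,
               sd = ifelse(is_b, task$sd_broad, task$sd_narrow))
}

#' Accuracy ceiling of a zero-noise ideal observer
#'
#' Expected proportion correct, under equal priors, of an observer with no
#' sensory noise who uses the accuracy-maximizing decision rule: the midpoint
#' criterion for the two-mean task, or the symmetric density-crossing
#' boundaries for the embedded task. Because the category distributions
#' overlap, this ceiling is below 1 even for a perfect observer; for the
#' default tasks it is just under 0.80.
#'
#' @param task A `gaussian_task` or `embedded_task`.
#' @return Expected accuracy as a proportion in (0.5, 1).
#' @examples
#' max_accuracy(task_gaussian())   # ~0.788
#' max_accuracy(task_embedded())   # ~0.791
#' @export
max_accuracy <- function(task) UseMethod("max_accuracy")

#' @export
max_accuracy.gaussian_task <- function(task) {
  # midpoint rule: each category errs with mass beyond half the separation
  stats::pnorm((task$mean_B - task$mean_A) / (2 * task$sd))
}

#' @export
max_accuracy.embedded_task <- function(task) {
  k <- optimal_boundary(0, task)$k_opt
  embedded_accuracy(k, task$sd_narrow, task$sd_broad)
}

#' Expected accuracy of symmetric boundaries in an embedded task
#'
#' For measurement distributions N(0, `sigma_A`) (narrow) and N(0, `sigma_B`)
#' (broad) with equal priors and the rule "report narrow iff |x| < k".
#'
#' @param k Positive half-boundary in degrees.
#' @param sigma_A,sigma_B Measurement standard deviations for the narrow and
#'   broad categories.
#' @return Expected proportion correct.
#' @export
embedded_accuracy <- function(k, sigma_A, sigma_B) {
  0.5 * prob_report_narrow(k, sigma_A) + 0.5 * (1 - prob_report_narrow(k, sigma_B))
}

#' Load the default task and design configuration
#'
#' Reads the JSON configuration shipped with the package (or a user-supplied
#' file in the same format), holding the standard task geometries, contrast
#' ladder, session designs, observer defaults and analysis thresholds.
#'
#' @param path Path to a JSON config; defaults to the packaged file.
#' @return A named list.
#' @export
load_config <- function(path = system.file("extdata", "default_config.json",
                                           package = "bayescat")) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading JSON configs requires the 'jsonlite' package", call. = FALSE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# -- trial-record schema ------------------------------------------------------

trial_columns <- c(
  "participant_id", "group", "experiment", "block_alpha_B", "contrast",
  "orientation_deg", "true_category", "response", "confidence", "rt_s",
  "gamble_stake_B"
)

#' Read and write trial-level data
#'
#' Trial data travel as UTF-8 CSV with one row per trial and the fixed header
#' `participant_id, group, experiment, block_alpha_B, contrast,
#' orientation_deg, true_category, response, confidence, rt_s,
#' gamble_stake_B`. Optional fields (`confidence`, `rt_s`, `gamble_stake_B`)
#' are empty strings when absent; categories are encoded "A"/"B".
#'
#' @param path File path.
#' @param trials A trial tibble with the schema columns.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(participant_id = "character"))
  missing <- setdiff(trial_columns, names(df))
  if (length(missing) > 0) {
    stop("trial file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df[trial_columns])
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(trials[trial_columns]), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
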