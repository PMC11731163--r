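# Standard signal-detection estimation for the two-mean task, the
# ideal-observer criterion, and the criterion-shift / suboptimality metrics.
#
# Sign convention: category B ("signal") is the clockwise category; the
# criterion c is positive when the observer is conservative about reporting B.
# Downstream suboptimality metrics are defined to be convention-invariant.

#' Tally category responses per block x contrast cell
#'
#' Aggregates one participant's two-mean-task trials into the per-cell counts
#' that signal-detection estimation needs: how often category B was reported
#' when the stimulus truly was B (hits) and when it was A (false alarms).
#'
#' @param trials Trial tibble for a single participant from the
#'   prior-manipulation experiment (experiment 1).
#' @return A tibble with one row per non-empty `(block_alpha_B, contrast)`
#'   cell: `participant_id`, `block_alpha_B`, `contrast`, `n_B_given_B`,
#'   `n_trials_B`, `n_B_given_A`, `n_trials_A`.
#' @export
count_responses <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (length(unique(trials$participant_id)) > 1) {
    stop("`trials` must come from a single participant", call. = FALSE)
  }
  if (length(unique(trials$experiment)) > 1 || !all(trials$experiment == 1)) {
    stop("`trials` must all come from experiment 1", call. = FALSE)
  }
  trials |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::group_by(.data$participant_id, .data$block_alpha_B, .data$contrast) |>
    dplyr::summarise(
      n_B_given_B = sum(.data$true_category == "B" & .data$response == "B"),
      n_trials_B = sum(.data$true_category == "B"),
      n_B_given_A = sum(.data$true_category == "A" & .data$response == "B"),
      n_trials_A = sum(.data$true_category == "A"),
      .groups = "drop"
    )
}

correct_rate <- function(x, n, correction) {
  switch(correction,
    loglinear = (x + 0.5) / (n + 1),
    clamp = pmin(pmax(x / n, 1 / (2 * n)), 1 - 1 / (2 * n)),
    stop("unknown `correction`: ", correction, call. = FALSE)
  )
}

#' Estimate sensitivity and decision criterion from response counts
#'
#' Equal-variance Gaussian signal detection: with H the (corrected) hit rate
#' P(report B | category B) and F the false-alarm rate
#' P(report B | category A),
#' d' = z(H) - z(F) and c = -(z(H) + z(F))/2, z the standard normal quantile.
#' Positive c means a bias against reporting B. Extreme rates are corrected
#' before the quantile transform: the log-linear rule adds 0.5 to each count
#' and 1 to each total; the clamp rule truncates raw rates to
#' [1/(2n), 1 - 1/(2n)].
#'
#' @param counts Output of [count_responses()] (any number of rows).
#' @param correction `"loglinear"` (default) or `"clamp"`.
#' @return `counts` with columns `hit_rate`, `fa_rate`, `d_prime`,
#'   `criterion_c`, `correction` appended.
#' @examples
#' counts <- tibble::tibble(
#'   participant_id = "p1", block_alpha_B = 0.5, contrast = 0.72,
#'   n_B_given_B = 42, n_trials_B = 50, n_B_given_A = 8, n_trials_A = 50
#' )
#' estimate_dprime_criterion(counts)
#' @export
estimate_dprime_criterion <- function(counts, correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  bad <- counts$n_trials_A == 0 | counts$n_trials_B == 0
  if (any(bad)) {
    stop("zero trials in one category for cell(s): ",
         paste(sprintf("(alpha_B=%s, contrast=%s)",
                       counts$block_alpha_B[bad], counts$contrast[bad]),
               collapse = ", "),
         call. = FALSE)
  }
  h <- correct_rate(counts$n_B_given_B, counts$n_trials_B, correction)
  f <- correct_rate(counts$n_B_given_A, counts$n_trials_A, correction)
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  dplyr::mutate(counts,
    hit_rate = h, fa_rate = f,
    d_prime = zh - zf,
    criterion_c = -(zh + zf) / 2,
    correction = correction
  )
}

#' Optimal likelihood-ratio criterion from a block base rate
#'
#' The accuracy-maximizing observer responds at the likelihood ratio equal to
#' the prior odds against the signal category: beta_opt = (1 - alpha)/alpha,
#' where alpha is the base rate of category B in the block.
#'
#' @param alpha_B Base rate of category B; strictly in (0, 1).
#' @return beta_opt (vectorized).
#' @examples
#' optimal_beta(c(0.25, 0.5, 0.75))   # 3, 1, 1/3
#' @export
optimal_beta <- function(alpha_B) {
  if (any(!is.finite(alpha_B)) || any(alpha_B <= 0 | alpha_B >= 1)) {
    stop("`alpha_B` must lie strictly in (0, 1): prior odds are undefined at 0 or 1",
         call. = FALSE)
  }
  (1 - alpha_B) / alpha_B
}

#' Optimal criterion placement for a given sensitivity
#'
#' c_opt = ln(beta_opt) / d'. As sensitivity shrinks the optimal criterion
#' diverges, which is why downstream analyses guard against extreme
#' criterion-error values.
#'
#' @param beta_opt Positive likelihood-ratio criterion, e.g. from
#'   [optimal_beta()].
#' @param d_prime Nonzero sensitivity.
#' @return c_opt on the same scale and sign convention as `criterion_c`.
#' @examples
#' optimal_criterion(optimal_beta(0.25), d_prime = 2)   # log(3)/2
#' @export
optimal_criterion <- function(beta_opt, d_prime) {
  if (any(beta_opt <= 0)) stop("`beta_opt` must be positive", call. = FALSE)
  if (any(d_prime == 0)) {
    stop("`d_prime` is 0: the optimal criterion is unbounded", call. = FALSE)
  }
  log(beta_opt) / d_prime
}

#' Criterion shift between biased base-rate blocks
#'
#' D_criterion = c at the 75% block minus c at the 25% block, for the same
#' participant and contrast. An observer who integrates the prior shifts the
#' criterion toward the likelier category in each block, so D_criterion is
#' negative under this sign convention and its magnitude grows as sensitivity
#' falls; a prior-ignoring observer gives 0.
#'
#' @param c_at_alpha75,c_at_alpha25 Criterion estimates from the two biased
#'   blocks.
#' @return Signed criterion shift (vectorized).
#' @export
criterion_shift <- function(c_at_alpha75, c_at_alpha25) {
  c_at_alpha75 - c_at_alpha25
}

#' Deviation of the decision criterion from the ideal observer
#'
#' Sign-normalized criterion error for one biased block:
#' sign(c_opt) * (c_opt - c), where c_opt is computed at the participant's
#' own sensitivity. Positive values mean the criterion was shifted less than
#' the ideal observer would shift it (under-use of the prior); 0 is optimal.
#' The sign normalization makes the two biased blocks comparable so their
#' errors can be averaged per contrast.
#'
#' @param c Estimated criterion.
#' @param d_prime Nonzero sensitivity for the same cell.
#' @param alpha_B Block base rate; must be a biased block (0.25 or 0.75 by
#'   default designs), not the neutral one.
#' @return Signed criterion error (vectorized).
#' @examples
#' criterion_error(c = 0, d_prime = 1, alpha_B = 0.25)   # log(3)
#' @export
criterion_error <- function(c, d_prime, alpha_B) {
  if (any(alpha_B == 0.5)) {
    stop("criterion error is defined for biased blocks only (`alpha_B` != 0.5)",
         call. = FALSE)
  }
  c_opt <- optimal_criterion(optimal_beta(alpha_B), d_prime)
  sign(c_opt) * (c_opt - c)
}
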