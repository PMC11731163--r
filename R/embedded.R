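# Observer model for the embedded category task: combined internal/external
# noise, the report-probability model and its analytic inverse, the two-step
# estimator of sensory noise and decision boundary, and the optimal boundary.

#' Combined external and internal orientation noise
#'
#' The internal measurement of a stimulus drawn from a category with external
#' (stimulus) standard deviation `s_cat` and corrupted by sensory noise
#' `sigma_sens` is, across trials, Gaussian with standard deviation
#' sqrt(s_cat^2 + sigma_sens^2).
#'
#' @param s_cat Category (stimulus) standard deviation in degrees; positive.
#' @param sigma_sens Sensory noise standard deviation in degrees;
#'   non-negative.
#' @return sigma_cat in degrees (vectorized).
#' @examples
#' combined_sd(3, 4)   # 5
#' @export
combined_sd <- function(s_cat, sigma_sens) {
  if (any(s_cat <= 0)) stop("`s_cat` must be positive", call. = FALSE)
  if (any(sigma_sens < 0)) stop("`sigma_sens` must be non-negative", call. = FALSE)
  sqrt(s_cat^2 + sigma_sens^2)
}

#' Probability of reporting the narrow category
#'
#' With symmetric decision boundaries at +/- k and a zero-mean Gaussian
#' measurement distribution with standard deviation `sigma_cat`, the
#' probability of reporting the narrow category is the Gaussian mass between
#' the boundaries: 2 * pnorm(k / sigma_cat) - 1. Reporting the broad category
#' has the complementary probability.
#'
#' @param k Non-negative half-boundary in degrees.
#' @param sigma_cat Positive measurement standard deviation in degrees.
#' @return Probability (vectorized).
#' @export
prob_report_narrow <- function(k, sigma_cat) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  if (any(sigma_cat <= 0)) stop("`sigma_cat` must be positive", call. = FALSE)
  2 * stats::pnorm(k / sigma_cat) - 1
}

#' Boundary implied by a narrow-report proportion
#'
#' Exact inverse of [prob_report_narrow()]:
#' k = sigma_cat * qnorm((1 + p_narrow)/2). Proportions of exactly 0 or 1 are
#' rejected; apply a count correction upstream.
#'
#' @param p_narrow Proportion of narrow-category reports, strictly in (0, 1).
#' @param sigma_cat Positive measurement standard deviation in degrees.
#' @return Half-boundary k in degrees (vectorized).
#' @export
invert_boundary <- function(p_narrow, sigma_cat) {
  if (any(p_narrow <= 0 | p_narrow >= 1)) {
    stop("`p_narrow` must lie strictly in (0, 1); correct extreme counts upstream",
         call. = FALSE)
  }
  if (any(sigma_cat <= 0)) stop("`sigma_cat` must be positive", call. = FALSE)
  sigma_cat * stats::qnorm((1 + p_narrow) / 2)
}

#' Two-step fit of sensory noise and decision boundary
#'
#' Estimates, for one participant at one contrast level, the sensory noise
#' sigma_sens and the symmetric half-boundary k from the two category-wise
#' proportions of narrow-category reports. Step one finds the sigma_sens most
#' consistent with a single boundary across both categories: it minimizes the
#' squared discrepancy between the boundaries implied by each category's
#' proportion, k_cat(sigma) = invert_boundary(p_cat, combined_sd(s_cat,
#' sigma)). Step two sets k to the mean of the two implied boundaries at the
#' optimum.
#'
#' The objective is minimized over sigma_sens in [0, `sigma_max`] by a coarse
#' grid scan followed by golden-section refinement in the bracketing
#' interval; `converged` reports whether the residual discrepancy reached
#' `tol`. When the proportions are ordered so that no non-negative sigma
#' equates the two implied boundaries (e.g. the narrow category yields the
#' smaller narrow-report proportion), the fit is returned with
#' `converged = FALSE` rather than failing.
#'
#' @param p_narrow_given_A Proportion of narrow reports on narrow-category
#'   trials, strictly in (0, 1) (count-corrected upstream).
#' @param p_narrow_given_B Proportion of narrow reports on broad-category
#'   trials, strictly in (0, 1).
#' @param task An [task_embedded()] object supplying the category standard
#'   deviations.
#' @param sigma_max Upper search bound for sigma_sens in degrees.
#' @param tol Convergence tolerance on the squared-discrepancy objective
#'   (squared degrees).
#' @return A one-row tibble: `sigma_sens`, `k`, `k_A`, `k_B`, `objective`,
#'   `converged`.
#' @examples
#' task <- task_embedded()
#' p_A <- prob_report_narrow(6, combined_sd(3, 4))
#' p_B <- prob_report_narrow(6, combined_sd(12, 4))
#' fit_embedded_observer(p_A, p_B, task)   # recovers sigma_sens 4, k 6
#' @export
fit_embedded_observer <- function(p_narrow_given_A, p_narrow_given_B,
                                  task = task_embedded(),
                                  sigma_max = 100, tol = 1e-8) {
  stopifnot(inherits(task, "embedded_task"))
  for (p in c(p_narrow_given_A, p_narrow_given_B)) {
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop("report proportions must lie strictly in (0, 1); apply a count correction",
           call. = FALSE)
    }
  }
  z_a <- stats::qnorm((1 + p_narrow_given_A) / 2)
  z_b <- stats::qnorm((1 + p_narrow_given_B) / 2)
  objective <- function(sigma) {
    (sqrt(task$sd_narrow^2 + sigma^2) * z_a -
       sqrt(task$sd_broad^2 + sigma^2) * z_b)^2
  }
  # coarse scan (dense near 0 where the objective can be flat), then refine
  grid <- c(0, exp(seq(log(1e-3), log(sigma_max), length.out = 400)))
  vals <- objective(grid)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  sigma_hat <- grid[i]
  obj_hat <- vals[i]
  if (hi > lo) {
    opt <- stats::optimize(objective, c(lo, hi), tol = 1e-12)
    if (opt$objective < obj_hat) {
      sigma_hat <- opt$minimum
      obj_hat <- opt$objective
    }
  }
  k_a <- sqrt(task$sd_narrow^2 + sigma_hat^2) * z_a
  k_b <- sqrt(task$sd_broad^2 + sigma_hat^2) * z_b
  tibble::tibble(
    sigma_sens = sigma_hat,
    k = (k_a + k_b) / 2,
    k_A = k_a,
    k_B = k_b,
    objective = obj_hat,
    converged = obj_hat < tol
  )
}

#' Optimal symmetric boundary for an embedded task
#'
#' The accuracy-maximizing half-boundary lies where the two internal
#' measurement densities cross. With sigma_A and sigma_B the combined
#' (external + internal) standard deviations of the narrow and broad
#' categories, the positive crossing point is
#' k_opt = sqrt(2 sigma_A^2 sigma_B^2 log(sigma_B / sigma_A) /
#' (sigma_B^2 - sigma_A^2)). Boundaries widen as sensory noise grows.
#'
#' @param sigma_sens Non-negative sensory noise in degrees.
#' @param task An [task_embedded()] object.
#' @return A one-row tibble: `sigma_sens`, `sigma_A`, `sigma_B`, `k_opt`.
#' @examples
#' optimal_boundary(0, task_embedded())$k_opt   # ~5.159
#' @export
optimal_boundary <- function(sigma_sens, task = task_embedded()) {
  stopifnot(inherits(task, "embedded_task"))
  sigma_a <- combined_sd(task$sd_narrow, sigma_sens)
  sigma_b <- combined_sd(task$sd_broad, sigma_sens)
  if (any(sigma_a >= sigma_b)) {
    stop("degenerate task: combined noise must differ between categories",
         call. = FALSE)
  }
  k_opt <- sqrt(2 * sigma_a^2 * sigma_b^2 * log(sigma_b / sigma_a) /
                  (sigma_b^2 - sigma_a^2))
  tibble::tibble(sigma_sens = sigma_sens, sigma_A = sigma_a,
                 sigma_B = sigma_b, k_opt = k_opt)
}

#' Boundary suboptimality
#'
#' Signed deviation of a fitted half-boundary from the ideal-observer
#' boundary computed at the same sensory noise: k - k_opt. Positive values
#' mean boundaries wider than optimal; 0 is optimal.
#'
#' @param k Fitted positive half-boundary in degrees.
#' @param k_opt Optimal half-boundary in degrees.
#' @return Signed boundary error in degrees (vectorized).
#' @export
boundary_error <- function(k, k_opt) {
  if (any(k <= 0) || any(k_opt <= 0)) {
    stop("`k` and `k_opt` must be positive", call. = FALSE)
  }
  k - k_opt
}
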