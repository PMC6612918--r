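#' Run a simulated staircase session for one condition
#'
#' Reproduces the threshold-measurement protocol: one practice run followed
#' by two test runs, each run consisting of two interleaved psi staircases of
#' `trials_per_staircase` stimulus pairs presented in strict alternation.
#' The practice run is simulated and discarded; each test staircase yields
#' one threshold estimate (posterior mean of the 80%-correct point) with its
#' SE (posterior SD), for a total of four estimates per condition.
#'
#' Trial responses are Bernoulli draws from the observer's psychometric
#' function, seeded per trial from `(seed, run, staircase, trial)` so
#' sessions are exactly reproducible.
#'
#' @param observer A [psychometric_model()].
#' @param condition Condition label attached to the estimates (e.g.
#'   `"CD_ach"`, `"CD_s"`, `"IOVD_ach"`, `"IOVD_s"`).
#' @param seed Integer seed.
#' @param trials_per_staircase Trials per staircase (default 30).
#' @param n_test_runs Number of scoring runs (default 2).
#' @param practice Whether to simulate (and discard) a practice run.
#' @return A data.frame with one row per test staircase: `condition`, `run`,
#'   `staircase`, `threshold`, `se`, `slope`, `n_trials`, and the trial-level
#'   history as attribute `"trials"`.
#' @export
run_session <- function(observer, condition = "CD_ach", seed = 1,
                        trials_per_staircase = 30, n_test_runs = 2,
                        practice = TRUE) {
  stopifnot(inherits(observer, "psychometric_model"))
  runs <- if (practice) 0:n_test_runs else seq_len(n_test_runs)
  est <- list()
  trials <- list()
  for (run in runs) {
    states <- list(psi_init(), psi_init())
    for (trial in seq_len(2 * trials_per_staircase)) {
      sc <- ((trial - 1L) %% 2L) + 1L       # strict alternation
      x <- psi_next_intensity(states[[sc]])
      u <- with_seed(mix_seed(seed, run, sc, trial), stats::runif(1))
      correct <- u < p_correct(observer, x)
      states[[sc]] <- psi_update(states[[sc]], x, correct)
      trials[[length(trials) + 1L]] <- data.frame(
        condition = condition, run = run, staircase = sc,
        trial = ceiling(trial / 2), intensity = x, correct = correct
      )
    }
    if (run == 0) next # practice run discarded
    for (sc in 1:2) {
      e <- psi_estimate(states[[sc]])
      est[[length(est) + 1L]] <- data.frame(
        condition = condition, run = run, staircase = sc,
        threshold = e$threshold, se = e$se, slope = e$slope,
        n_trials = e$n_trials
      )
    }
  }
  out <- do.call(rbind, est)
  attr(out, "trials") <- do.call(rbind, trials)
  out
}

#' Variance-weighted threshold aggregation
#'
#' Combines several threshold estimates into a subject-level threshold by
#' weighting each estimate by the inverse of its standard error:
#' `sum(t_i / se_i) / sum(1 / se_i)`. The literal 1/SE weighting is the
#' default; inverse-variance weighting (1/SE^2) is available via `weights`.
#'
#' @param threshold Thresholds (% coherence), or a data.frame with columns
#'   `threshold` and `se` (as returned by [run_session()]).
#' @param se Standard errors (ignored when `threshold` is a data.frame).
#' @param weights `"inverse_se"` (default) or `"inverse_variance"`.
#' @return The weighted mean threshold (% coherence).
#' @export
#' @examples
#' variance_weighted_threshold(c(40, 60), c(1, 2)) # 46.67
variance_weighted_threshold <- function(threshold, se = NULL,
                                        weights = c("inverse_se",
                                                    "inverse_variance")) {
  weights <- match.arg(weights)
  if (is.data.frame(threshold)) {
    se <- threshold$se
    threshold <- threshold$threshold
  }
  if (length(threshold) < 1) stop("need at least one estimate", call. = FALSE)
  if (length(se) != length(threshold)) stop("threshold/se length mismatch", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  w <- if (weights == "inverse_se") 1 / se else 1 / se^2
  sum(threshold * w) / sum(w)
}

#' S-cone performance decrement
#'
#' Achromatic threshold minus S-cone threshold for the same cue type. Zero
#' means chromaticity-independent performance; negative values mean more
#' signal was needed when the stimulus was S-cone isolating.
#'
#' @param ach Achromatic variance-weighted threshold (% coherence).
#' @param scone S-cone variance-weighted threshold (% coherence).
#' @return `ach - scone` (% coherence).
#' @export
scone_decrement <- function(ach, scone) {
  if (any(ach <= 0 | ach > 100) || any(scone <= 0 | scone > 100)) {
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  }
  ach - scone
}
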