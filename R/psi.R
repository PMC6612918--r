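#' Weibull 2AFC psychometric model
#'
#' A simulated observer for the two-interval MID-versus-control
#' discrimination task. The psychometric function is a Weibull parameterized
#' directly in its 80%-correct point:
#' `P(x) = guess + (1 - guess - lapse) * (1 - exp(-k * (x / threshold80)^slope))`
#' with `k` chosen so that `P(threshold80) = 0.80` exactly for the given
#' guess and lapse rates.
#'
#' @param threshold80 Coherence (% signal dots) at which the observer is 80%
#'   correct; in `(0, 100]`.
#' @param slope Weibull slope (dimensionless), > 0.
#' @param guess Guess rate; 0.5 for 2AFC.
#' @param lapse Lapse rate in `[0, 0.5)`.
#' @return An object of class `psychometric_model`.
#' @export
psychometric_model <- function(threshold80 = 40, slope = 3.5,
                               guess = 0.5, lapse = 0.02) {
  if (threshold80 <= 0 || threshold80 > 100) {
    stop("threshold80 must be in (0, 100]", call. = FALSE)
  }
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)", call. = FALSE)
  if (0.80 >= 1 - lapse) stop("lapse too large for an 80% criterion", call. = FALSE)
  structure(list(threshold80 = threshold80, slope = slope,
                 guess = guess, lapse = lapse),
            class = "psychometric_model")
}

## Weibull scale constant pinning P(threshold80) = 0.80.
weibull_k <- function(guess, lapse, criterion = 0.80) {
  -log(1 - (criterion - guess) / (1 - guess - lapse))
}

#' Probability correct of the simulated observer
#'
#' @param model A [psychometric_model()].
#' @param x Stimulus coherence(s), % in `[0, 100]`.
#' @return Probability correct, monotone nondecreasing in `x`.
#' @export
#' @examples
#' m <- psychometric_model(threshold80 = 40)
#' p_correct(m, c(0, 40, 100))
p_correct <- function(model, x) {
  if (any(x < 0 | x > 100)) stop("x must be in [0, 100]", call. = FALSE)
  k <- weibull_k(model$guess, model$lapse)
  model$guess + (1 - model$guess - model$lapse) *
    (1 - exp(-k * (x / model$threshold80)^model$slope))
}

#' Initialize a Bayesian psi staircase state
#'
#' The psi method keeps a posterior over a grid of psychometric-function
#' hypotheses and places each trial at the stimulus intensity minimizing the
#' expected posterior entropy. The grid is parameterized directly in the
#' 80%-correct threshold, so posterior summaries are in threshold units.
#'
#' @param intensities Allowed stimulus intensities (% coherence; integers
#'   1--100 by default).
#' @param grid_threshold Threshold hypotheses (default 41 log-spaced values
#'   over 1--100%).
#' @param grid_slope Slope hypotheses (default 25 log-spaced values over
#'   0.5--10).
#' @param guess,lapse Fixed guess and lapse rates of the assumed observer.
#' @param prior Optional prior probability matrix/vector over the grid
#'   (uniform by default).
#' @return An object of class `psi_state`.
#' @export
psi_init <- function(intensities = 1:100,
                     grid_threshold = exp(seq(log(1), log(100), length.out = 41)),
                     grid_slope = exp(seq(log(0.5), log(10), length.out = 25)),
                     guess = 0.5, lapse = 0.02, prior = NULL) {
  grid <- expand.grid(threshold = grid_threshold, slope = grid_slope,
                      KEEP.OUT.ATTRS = FALSE)
  k <- weibull_k(guess, lapse)
  ## likelihood table: P(correct | hypothesis, intensity)
  P <- vapply(intensities, function(x) {
    guess + (1 - guess - lapse) * (1 - exp(-k * (x / grid$threshold)^grid$slope))
  }, numeric(nrow(grid)))
  posterior <- if (is.null(prior)) {
    rep(1 / nrow(grid), nrow(grid))
  } else {
    pr <- as.numeric(prior)
    stopifnot(length(pr) == nrow(grid), all(pr >= 0), sum(pr) > 0)
    pr / sum(pr)
  }
  structure(list(
    intensities = intensities, grid = grid, P = P,
    posterior = posterior,
    history = data.frame(intensity = numeric(0), correct = logical(0))
  ), class = "psi_state")
}

#' Bayesian update of a psi state
#'
#' Multiplies the posterior by the likelihood of the observed response under
#' every grid hypothesis and renormalizes; the trial is appended to the
#' history.
#'
#' @param state A [psi_init()] state.
#' @param x The presented intensity (must be one of `state$intensities`).
#' @param correct Logical response.
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, x, correct) {
  i <- match(x, state$intensities)
  if (is.na(i)) stop("x is not in the allowed intensity set", call. = FALSE)
  like <- if (correct) state$P[, i] else 1 - state$P[, i]
  post <- state$posterior * like
  z <- sum(post)
  if (z <= 0 || !is.finite(z)) {
    stop("posterior underflow: response sequence inconsistent with the grid",
         call. = FALSE)
  }
  state$posterior <- post / z
  state$history <- rbind(state$history,
                         data.frame(intensity = x, correct = correct))
  state
}

#' Next intensity by expected-entropy minimization
#'
#' Returns the allowed intensity that minimizes the posterior entropy over
#' (threshold, slope) expected after observing the next response.
#'
#' @param state A [psi_init()] state.
#' @return A single intensity from `state$intensities`.
#' @export
psi_next_intensity <- function(state) {
  post <- state$posterior
  P <- state$P
  ## joint "masses" for a correct / incorrect response at each intensity
  A <- P * post        # recycles post down each column
  B <- (1 - P) * post
  pc <- colSums(A)     # predictive P(correct | x)
  ## H(posterior | outcome) computed from unnormalized masses:
  ## H = -sum(q log q) with q = A[,x]/pc[x]
  hA <- -colSums(ifelse(A > 0, A * log(A), 0)) / pc + log(pc)
  hB <- -colSums(ifelse(B > 0, B * log(B), 0)) / (1 - pc) + log(1 - pc)
  eh <- pc * hA + (1 - pc) * hB
  state$intensities[which.min(eh)]
}

#' Posterior threshold estimate of a psi state
#'
#' Posterior mean and SD of the 80%-correct threshold (the grid is
#' parameterized in threshold units, so no transformation is involved), plus
#' the posterior mean slope.
#'
#' @param state A [psi_init()] state.
#' @return A list with `threshold`, `se`, `slope`, `n_trials`.
#' @export
psi_estimate <- function(state) {
  post <- state$posterior
  thr <- sum(post * state$grid$threshold)
  v <- sum(post * (state$grid$threshold - thr)^2)
  list(threshold = thr, se = sqrt(max(v, 0)),
       slope = sum(post * state$grid$slope),
       n_trials = nrow(state$history))
}
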