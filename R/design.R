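#' Stimulus conditions of the event-related MID experiment
#'
#' Eight stimulus conditions (2 cues x 2 chromaticities x stimulus/control)
#' plus a blank fixation-only condition.
#'
#' @return Character vector of the 9 condition labels.
#' @export
mid_conditions <- function() {
  c("CD_ach", "CD_ach_control", "CD_s", "CD_s_control",
    "IOVD_ach", "IOVD_ach_control", "IOVD_s", "IOVD_s_control", "blank")
}

#' Event-related run design with jittered ISIs
#'
#' Schedules `repeats_per_condition` events of every condition (including
#' blank) in seeded random order within one fMRI run. Inter-stimulus
#' intervals are multiples of `isi_step` within `isi_range`; the jitter
#' allocation distributes the available run time (after the 4 dummy volumes
#' are discarded) over the gaps at random, subject to the per-gap bounds, so
#' every sampled schedule fits the run exactly. Onsets are expressed
#' relative to the first retained volume.
#'
#' @param config Optional named list overriding any of: `conditions` (9
#'   labels), `repeats_per_condition` (5), `duration` (3 s), `tr` (3 s),
#'   `n_volumes` (114), `dummy_volumes` (4), `isi_range` (`c(3, 12)` s),
#'   `isi_step` (1.5 s).
#' @param seed Integer seed.
#' @return An object of class `event_design`: a list with `events` (data
#'   frame: onset, duration, condition) and the scheduling metadata.
#' @export
#' @examples
#' d <- generate_run_design(seed = 1)
#' range(diff(d$events$onset) - d$duration) # ISIs within [3, 12] - 3
generate_run_design <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    conditions = mid_conditions(), repeats_per_condition = 5,
    duration = 3, tr = 3, n_volumes = 114, dummy_volumes = 4,
    isi_range = c(3, 12), isi_step = 1.5
  ), config)
  run_time <- (cfg$n_volumes - cfg$dummy_volumes) * cfg$tr
  n_ev <- length(cfg$conditions) * cfg$repeats_per_condition
  if (n_ev == 0) {
    return(structure(c(cfg, list(
      events = data.frame(onset = numeric(0), duration = numeric(0),
                          condition = character(0)),
      run_time = run_time, seed = as.integer(seed))),
      class = "event_design"))
  }
  n_gap <- n_ev - 1L
  slack <- run_time - n_ev * cfg$duration - n_gap * cfg$isi_range[1]
  if (slack < 0) {
    stop("the requested events cannot fit the run even at the minimum ISI",
         call. = FALSE)
  }
  units_total <- floor(slack / cfg$isi_step)
  cap <- floor((cfg$isi_range[2] - cfg$isi_range[1]) / cfg$isi_step)
  units_total <- min(units_total, n_gap * cap)

  sched <- with_seed(mix_seed(seed, 53L), {
    order <- sample(rep(cfg$conditions, cfg$repeats_per_condition))
    ## distribute jitter units over gaps uniformly at random, respecting the
    ## per-gap cap; bounded retries, then a deterministic fill
    units <- NULL
    for (try in 1:100) {
      u <- tabulate(sample.int(n_gap, units_total, replace = TRUE), n_gap)
      if (all(u <= cap)) { units <- u; break }
    }
    if (is.null(units)) {
      units <- rep(floor(units_total / n_gap), n_gap)
      rem <- units_total - sum(units)
      if (rem > 0) units[seq_len(rem)] <- units[seq_len(rem)] + 1L
    }
    list(order = order, units = units)
  })
  isi <- cfg$isi_range[1] + sched$units * cfg$isi_step
  onsets <- cumsum(c(0, cfg$duration + isi))
  stopifnot(onsets[n_ev] + cfg$duration <= run_time + 1e-9)
  structure(c(cfg, list(
    events = data.frame(onset = onsets, duration = cfg$duration,
                        condition = sched$order, stringsAsFactors = FALSE),
    run_time = run_time, seed = as.integer(seed))),
    class = "event_design")
}

#' @export
print.event_design <- function(x, ...) {
  cat(sprintf("<event_design> %d events, %d conditions, run time %gs (TR %gs, %d+%d volumes)\n",
              nrow(x$events), length(x$conditions), x$run_time, x$tr,
              x$n_volumes - x$dummy_volumes, x$dummy_volumes))
  invisible(x)
}

#' Hemodynamic response model
#'
#' A gamma-density HRF parameterized by its mean lag and standard deviation
#' (shape `(lag/sd)^2`, scale `sd^2/lag`), normalized to unit peak; the
#' difference-of-gammas variant subtracts a delayed undershoot gamma scaled
#' by `undershoot_ratio`.
#'
#' @param kind `"gamma"` or `"difference_of_gammas"`.
#' @param lag Mean of the response gamma, s.
#' @param sd Standard deviation of the response gamma, s.
#' @param undershoot_ratio Amplitude of the undershoot relative to the
#'   (pre-normalization) response peak.
#' @param undershoot_lag,undershoot_sd Mean/SD of the undershoot gamma, s.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(kind = c("gamma", "difference_of_gammas"),
                      lag = 6, sd = 3, undershoot_ratio = 1 / 6,
                      undershoot_lag = 16, undershoot_sd = 4) {
  kind <- match.arg(kind)
  stopifnot_scalar(lag, "lag"); stopifnot_scalar(sd, "sd")
  structure(list(kind = kind, lag = lag, sd = sd,
                 undershoot_ratio = undershoot_ratio,
                 undershoot_lag = undershoot_lag, undershoot_sd = undershoot_sd),
            class = "hrf_model")
}

#' Sampled HRF kernel
#'
#' @param model An [hrf_model()].
#' @param dt Sampling interval, s.
#' @param span Kernel support, s.
#' @return A list with `t` (times) and `k` (kernel values, unit peak).
#' @export
#' @examples
#' k <- hrf_kernel(hrf_model(), dt = 0.1)
#' sum(k$t * k$k) / sum(k$k) # ~6 s mean lag
hrf_kernel <- function(model, dt = 0.1, span = 32) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  t <- seq(0, span, by = dt)
  g <- function(lag, sd) {
    shape <- (lag / sd)^2
    stats::dgamma(t, shape = shape, scale = sd^2 / lag)
  }
  k <- g(model$lag, model$sd)
  if (model$kind == "difference_of_gammas") {
    k <- k - model$undershoot_ratio * max(k) /
      max(g(model$undershoot_lag, model$undershoot_sd)) *
      g(model$undershoot_lag, model$undershoot_sd)
  }
  k <- k / max(k)
  list(t = t, k = k)
}

#' HRF-convolved design matrix
#'
#' One regressor per non-blank condition: the event boxcars (full stimulus
#' duration) convolved with the HRF on a fine time grid and sampled at the
#' volume acquisition times after dummy discard, plus an intercept column.
#' Blank events are carried by the baseline. Conditions without events
#' produce an all-zero regressor which is dropped and recorded in the
#' `"excluded"` attribute.
#'
#' @param design An [generate_run_design()] event design.
#' @param hrf An [hrf_model()].
#' @param dt Convolution grid step, s.
#' @return Numeric matrix (volumes x regressors) with attribute
#'   `"excluded"`.
#' @export
build_design_matrix <- function(design, hrf, dt = 0.1) {
  n_vol <- design$n_volumes - design$dummy_volumes
  vol_t <- (seq_len(n_vol) - 1) * design$tr
  conds <- setdiff(design$conditions, "blank")
  kern <- hrf_kernel(hrf, dt = dt)
  grid_t <- seq(0, design$run_time + 1e-9, by = dt)
  X <- matrix(0, n_vol, length(conds) + 1L,
              dimnames = list(NULL, c("(Intercept)", conds)))
  X[, 1] <- 1
  for (j in seq_along(conds)) {
    ev <- design$events[design$events$condition == conds[j], ]
    box <- numeric(length(grid_t))
    for (i in seq_len(nrow(ev))) {
      box[grid_t >= ev$onset[i] - 1e-9 &
            grid_t < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
    }
    reg <- stats::convolve(box, rev(kern$k), type = "open")[seq_along(grid_t)] * dt
    X[, j + 1L] <- stats::approx(grid_t, reg, xout = vol_t, rule = 2)$y
  }
  zero <- colnames(X)[-1][apply(X[, -1, drop = FALSE], 2, function(c) all(c == 0))]
  if (length(zero)) X <- X[, setdiff(colnames(X), zero), drop = FALSE]
  attr(X, "excluded") <- zero
  X
}

#' Ordinary least-squares GLM fit
#'
#' @param timeseries Numeric vector, one value per retained volume.
#' @param X Design matrix from [build_design_matrix()] (or any full-rank
#'   matrix with matching rows).
#' @return A list with `betas` (named), `r_squared` (fraction of variance
#'   explained), `fitted`, `residuals`.
#' @export
fit_glm <- function(timeseries, X) {
  if (length(timeseries) != nrow(X)) {
    stop("timeseries length must match the design matrix rows", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  fit <- stats::lm.fit(X, timeseries)
  fitted <- timeseries - fit$residuals
  tss <- sum((timeseries - mean(timeseries))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  list(betas = fit$coefficients, r_squared = r2, fitted = fitted,
       residuals = fit$residuals)
}

#' Subject-level quality-control filter
#'
#' Drops subjects whose mean GLM variance explained across ROIs falls below
#' the threshold (default 5%).
#'
#' @param beta_table A data.frame with columns `subject`, `roi`,
#'   `r_squared` (and typically `condition`, `beta`).
#' @param min_r_squared Threshold in `(0, 1)`; 0 disables filtering.
#' @return The rows of `beta_table` belonging to retained subjects; the
#'   dropped subject ids are in attribute `"dropped"`.
#' @export
qc_filter <- function(beta_table, min_r_squared = 0.05) {
  stopifnot(all(c("subject", "r_squared") %in% names(beta_table)))
  if (min_r_squared < 0 || min_r_squared >= 1) {
    stop("min_r_squared must be in [0, 1)", call. = FALSE)
  }
  mean_r2 <- tapply(beta_table$r_squared, beta_table$subject, mean)
  dropped <- names(mean_r2)[mean_r2 < min_r_squared]
  out <- beta_table[!(beta_table$subject %in% dropped), , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
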