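#' Specification of a simulated psychophysical cohort
#'
#' Describes a group of simulated Weibull 2AFC observers whose true
#' 80%-correct coherence thresholds differ between the four
#' cue-by-chromaticity conditions. Each subject's threshold in a condition
#' is the condition mean plus a subject-level offset shared across
#' conditions (a generally good observer is good everywhere) plus
#' independent condition-level jitter.
#'
#' The default condition means place the CD S-cone threshold about 35
#' percentage points above the achromatic CD threshold and the IOVD S-cone
#' threshold about 10 points above its achromatic counterpart -- the pattern
#' of a strong cue-by-chromaticity interaction in which S-cone input
#' supports IOVD far better than CD.
#'
#' @param n_subjects Number of simulated observers (default 7).
#' @param condition_means Named true thresholds (% coherence) for
#'   `CD_ach`, `CD_s`, `IOVD_ach`, `IOVD_s`.
#' @param between_subject_sd SD of the shared subject offset (% coherence).
#' @param within_subject_sd SD of the independent condition jitter.
#' @param slope,lapse Weibull slope and lapse rate of every observer.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 7,
                        condition_means = c(CD_ach = 25, CD_s = 60,
                                            IOVD_ach = 35, IOVD_s = 45),
                        between_subject_sd = 8, within_subject_sd = 4,
                        slope = 3.5, lapse = 0.02, seed = 1) {
  stopifnot(n_subjects >= 1, all(condition_means > 0 & condition_means < 100),
            between_subject_sd >= 0, within_subject_sd >= 0)
  structure(list(n_subjects = n_subjects, condition_means = condition_means,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 slope = slope, lapse = lapse, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of psychophysical observers
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per subject per condition: `subject`,
#'   `condition`, `threshold80`, `slope`, `lapse`. True thresholds are
#'   clamped to (1, 99)% coherence.
#' @export
simulate_psychophysics_cohort <- function(spec) {
  conds <- names(spec$condition_means)
  with_seed(mix_seed(spec$seed, 211L), {
    offsets <- stats::rnorm(spec$n_subjects, 0, spec$between_subject_sd)
    out <- expand.grid(subject = seq_len(spec$n_subjects), condition = conds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    jitter <- stats::rnorm(nrow(out), 0, spec$within_subject_sd)
    out$threshold80 <- pmin(pmax(
      spec$condition_means[out$condition] + offsets[out$subject] + jitter,
      1), 99)
    out$slope <- spec$slope
    out$lapse <- spec$lapse
    out[order(out$subject, out$condition), ]
  })
}

#' Staircase thresholds for a whole cohort
#'
#' Runs the full session protocol ([run_session()]) for every subject and
#' condition of a simulated cohort, aggregates each subject's four estimates
#' by variance weighting, and computes the per-subject S-cone performance
#' decrement for each cue.
#'
#' @param cohort Output of [simulate_psychophysics_cohort()].
#' @param seed Integer seed for the sessions.
#' @return A list with `thresholds` (subject, condition, true threshold,
#'   recovered variance-weighted threshold) and `decrements` (subject, cue,
#'   decrement).
#' @export
cohort_thresholds <- function(cohort, seed = 1) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    obs <- psychometric_model(cohort$threshold80[i], cohort$slope[i],
                              lapse = cohort$lapse[i])
    est <- run_session(obs, condition = cohort$condition[i],
                       seed = mix_seed(seed, cohort$subject[i],
                                       match(cohort$condition[i],
                                             unique(cohort$condition))))
    data.frame(subject = cohort$subject[i], condition = cohort$condition[i],
               true_threshold = cohort$threshold80[i],
               threshold = variance_weighted_threshold(est))
  })
  thr <- do.call(rbind, rows)
  wide <- stats::reshape(thr[, c("subject", "condition", "threshold")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  ## S-cone decrements for every cue with both an _ach and an _s condition
  cues <- unique(sub("_(ach|s)$", "",
                     grep("_(ach|s)$", unique(thr$condition), value = TRUE)))
  cues <- cues[paste0(cues, "_ach") %in% thr$condition &
                 paste0(cues, "_s") %in% thr$condition]
  dec <- if (length(cues)) {
    do.call(rbind, lapply(cues, function(cue) {
      data.frame(subject = wide$subject, cue = cue,
                 decrement = scone_decrement(
                   wide[[paste0("threshold.", cue, "_ach")]],
                   wide[[paste0("threshold.", cue, "_s")]]))
    }))
  } else {
    data.frame(subject = integer(0), cue = character(0),
               decrement = numeric(0))
  }
  list(thresholds = thr, decrements = dec)
}

#' Specification of synthetic BOLD data
#'
#' Describes synthetic voxel time series for a set of ROIs: every voxel's
#' series is the HRF-convolved design matrix times the ROI's true condition
#' betas plus AR(1) Gaussian noise (innovations scaled so the marginal noise
#' SD equals `noise_sd`).
#'
#' @param roi_condition_betas A data.frame with columns `roi`, `condition`,
#'   `beta` giving the true response amplitude of every ROI to every
#'   non-blank condition; [default_beta_pattern()] supplies a 10-ROI pattern
#'   embedding a cue-by-chromaticity interaction.
#' @param noise_sd Marginal SD of the voxel noise.
#' @param ar1_coefficient AR(1) coefficient in `(-1, 1)`.
#' @param n_voxels_per_roi Voxels per ROI.
#' @param seed Integer seed.
#' @return An object of class `bold_spec`.
#' @export
bold_spec <- function(roi_condition_betas = default_beta_pattern(),
                      noise_sd = 1, ar1_coefficient = 0.3,
                      n_voxels_per_roi = 20, seed = 1) {
  stopifnot(abs(ar1_coefficient) < 1, noise_sd >= 0, n_voxels_per_roi >= 1)
  structure(list(roi_condition_betas = roi_condition_betas,
                 noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
                 n_voxels_per_roi = n_voxels_per_roi, seed = as.integer(seed)),
            class = "bold_spec")
}

#' @rdname bold_spec
#' @param rois ROI labels.
#' @param base Response common to all conditions.
#' @param delta Named MID-minus-control differentials for `CD_ach`, `CD_s`,
#'   `IOVD_ach`, `IOVD_s`. The default embeds the interaction
#'   (CD larger achromatic, IOVD larger S-cone).
#' @export
default_beta_pattern <- function(rois = unlist(roi_groups()), base = 1,
                                 delta = c(CD_ach = 0.5, CD_s = 0.2,
                                           IOVD_ach = 0.2, IOVD_s = 0.5)) {
  conds <- setdiff(mid_conditions(), "blank")
  out <- expand.grid(roi = unname(rois), condition = conds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  is_ctl <- grepl("_control$", out$condition)
  mid <- sub("_control$", "", out$condition)
  out$beta <- base + ifelse(is_ctl, 0, delta[mid])
  out
}

#' Simulate ROI voxel time series
#'
#' @param spec A [bold_spec()].
#' @param designs A list of [generate_run_design()] objects (one per run).
#' @param hrf An [hrf_model()].
#' @return Nested list: `result[[roi]][[run]]` is an
#'   `n_voxels x n_volumes` matrix of simulated BOLD values.
#' @export
simulate_bold <- function(spec, designs, hrf) {
  rois <- unique(spec$roi_condition_betas$roi)
  out <- list()
  for (r in seq_along(rois)) {
    roi <- rois[r]
    bt <- spec$roi_condition_betas[spec$roi_condition_betas$roi == roi, ]
    runs <- list()
    for (d in seq_along(designs)) {
      X <- build_design_matrix(designs[[d]], hrf)
      beta <- c(0, bt$beta[match(colnames(X)[-1], bt$condition)])
      if (anyNA(beta)) {
        stop("roi_condition_betas lacks a condition present in the design",
             call. = FALSE)
      }
      mu <- as.numeric(X %*% beta)
      noise <- with_seed(mix_seed(spec$seed, r, d, 307L), {
        innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1_coefficient^2)
        t(vapply(seq_len(spec$n_voxels_per_roi), function(v) {
          as.numeric(stats::filter(stats::rnorm(length(mu), 0, innov_sd),
                                   spec$ar1_coefficient,
                                   method = "recursive"))
        }, numeric(length(mu))))
      })
      runs[[d]] <- sweep(noise, 2, mu, "+")
    }
    out[[roi]] <- runs
  }
  out
}

#' Fit the GLM to simulated ROI data
#'
#' Averages voxels within each ROI, fits the per-run GLM, and averages betas
#' and variance explained across runs, yielding one beta per (roi,
#' condition) -- the input expected by [delta_beta_table()].
#'
#' @param bold Output of [simulate_bold()].
#' @param designs The design list used to simulate.
#' @param hrf The [hrf_model()] used to simulate.
#' @param subject Subject id attached to the output.
#' @return A data.frame: `subject`, `roi`, `condition`, `beta`, `r_squared`.
#' @export
glm_beta_table <- function(bold, designs, hrf, subject = 1) {
  out <- list()
  for (roi in names(bold)) {
    acc <- NULL
    r2 <- 0
    for (d in seq_along(designs)) {
      X <- build_design_matrix(designs[[d]], hrf)
      y <- colMeans(bold[[roi]][[d]])
      fit <- fit_glm(y, X)
      b <- fit$betas[-1]
      acc <- if (is.null(acc)) b else acc + b
      r2 <- r2 + fit$r_squared
    }
    acc <- acc / length(designs)
    r2 <- r2 / length(designs)
    out[[roi]] <- data.frame(subject = subject, roi = roi,
                             condition = names(acc), beta = unname(acc),
                             r_squared = r2)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
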