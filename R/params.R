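#' Stimulus parameters for dynamic random-dot stereogram sequences
#'
#' Collects every geometric and temporal parameter of the CD (changing
#' disparity) and IOVD (interocular velocity difference) stimulus families.
#' Defaults reproduce the scanning configuration: 0.5 deg antialiased dots at
#' one dot per square degree inside a 0.5--5 deg annular aperture, a 120 Hz
#' frame rate, 3 s presentations, CD oscillation at 1.4 Hz with 24 arcmin
#' peak-to-trough interocular disparity (+/-12 arcmin per eye), IOVD
#' oscillation at 1.1 Hz, and a 50 ms dot lifetime for moving dots.
#'
#' In `mode = "behavioral"` the dot diameter is doubled (unless explicitly
#' supplied) and CD dot positions are held for `behavioral_hold_frames`
#' consecutive video frames while the disparity signal keeps evolving at its
#' usual rate, mirroring the slower position refresh used for threshold
#' measurement.
#'
#' @param dot_diameter Dot diameter, degrees of visual angle. Default 0.5
#'   (1.0 in behavioral mode).
#' @param cosine_edge Width of the raised-cosine edge of each dot, degrees.
#' @param min_separation Minimum distance between dot centers, degrees.
#' @param density Dots per square degree, per eye.
#' @param aperture_inner,aperture_outer Inner/outer radius of the annular
#'   aperture, degrees.
#' @param aperture_edge_fwhm FWHM of the Gaussian aperture edge smoothing,
#'   degrees (rendering only).
#' @param frame_rate Video frame rate, Hz.
#' @param duration Presentation duration, seconds.
#' @param ramp_time Duration of each raised-cosine contrast ramp, seconds.
#' @param cd_frequency CD depth-oscillation frequency, Hz.
#' @param cd_disparity_amplitude Peak interocular disparity of the CD
#'   stimulus, arcmin (applied as -/+ half per eye).
#' @param iovd_frequency IOVD depth-oscillation frequency, Hz.
#' @param iovd_displacement_amplitude Monocular displacement amplitude used by
#'   the displacement-matched IOVD profile, arcmin.
#' @param iovd_peak_speed Peak monocular dot speed used by the
#'   velocity-matched IOVD profile, degrees/s.
#' @param iovd_profile_mode `"velocity_matched"` (default) or
#'   `"displacement_matched"`; see the package vignette for why both exist.
#' @param dot_lifetime Maximum dot lifetime for moving (IOVD-family) dots,
#'   seconds. Must be an integer number of frames.
#' @param stripe_height Height of the horizontal eye-alternation stripes used
#'   by the IOVD stimulus, degrees.
#' @param anticorr_radius Interocular center distance below which dot pairs
#'   near a stripe border are forced to opposite contrast polarity, degrees.
#'   Defaults to the dot diameter.
#' @param behavioral_hold_frames Number of consecutive frames CD dot
#'   positions are held in behavioral mode.
#' @param mode `"fmri"` or `"behavioral"`.
#' @return An object of class `stimulus_params` (a validated named list).
#' @export
#' @examples
#' p <- stimulus_params()
#' dot_budget(p) # 78 dots for the default annulus at 1 dot/deg^2
stimulus_params <- function(dot_diameter = NULL,
                            cosine_edge = 0.15,
                            min_separation = 0.5,
                            density = 1.0,
                            aperture_inner = 0.5,
                            aperture_outer = 5.0,
                            aperture_edge_fwhm = 0.5,
                            frame_rate = 120,
                            duration = 3.0,
                            ramp_time = 0.75,
                            cd_frequency = 1.4,
                            cd_disparity_amplitude = 24,
                            iovd_frequency = 1.1,
                            iovd_displacement_amplitude = 100,
                            iovd_peak_speed = 1.7,
                            iovd_profile_mode = c("velocity_matched",
                                                  "displacement_matched"),
                            dot_lifetime = 0.050,
                            stripe_height = 1.0,
                            anticorr_radius = NULL,
                            behavioral_hold_frames = 4,
                            mode = c("fmri", "behavioral")) {
  mode <- match.arg(mode)
  iovd_profile_mode <- match.arg(iovd_profile_mode)
  if (is.null(dot_diameter)) {
    dot_diameter <- if (mode == "behavioral") 1.0 else 0.5
  }
  if (is.null(anticorr_radius)) anticorr_radius <- dot_diameter

  p <- list(
    dot_diameter = dot_diameter, cosine_edge = cosine_edge,
    min_separation = min_separation, density = density,
    aperture_inner = aperture_inner, aperture_outer = aperture_outer,
    aperture_edge_fwhm = aperture_edge_fwhm, frame_rate = frame_rate,
    duration = duration, ramp_time = ramp_time,
    cd_frequency = cd_frequency,
    cd_disparity_amplitude = cd_disparity_amplitude,
    iovd_frequency = iovd_frequency,
    iovd_displacement_amplitude = iovd_displacement_amplitude,
    iovd_peak_speed = iovd_peak_speed,
    iovd_profile_mode = iovd_profile_mode,
    dot_lifetime = dot_lifetime, stripe_height = stripe_height,
    anticorr_radius = anticorr_radius,
    behavioral_hold_frames = behavioral_hold_frames, mode = mode
  )
  class(p) <- "stimulus_params"
  validate_stimulus_params(p)
  p
}

validate_stimulus_params <- function(p) {
  for (f in c("dot_diameter", "cosine_edge", "min_separation",
              "aperture_inner", "aperture_outer", "aperture_edge_fwhm",
              "frame_rate", "duration", "cd_frequency", "iovd_frequency",
              "dot_lifetime", "stripe_height")) {
    stopifnot_scalar(p[[f]], f)
  }
  stopifnot_scalar(p$density, "density", positive = FALSE)
  if (p$density < 0) stop("'density' must be >= 0", call. = FALSE)
  if (p$anticorr_radius < 0) stop("'anticorr_radius' must be >= 0", call. = FALSE)
  if (p$aperture_inner >= p$aperture_outer) {
    stop("aperture_inner must be smaller than aperture_outer", call. = FALSE)
  }
  lf <- p$frame_rate * p$dot_lifetime
  if (abs(lf - round(lf)) > 1e-9 || round(lf) < 1) {
    stop("frame_rate * dot_lifetime must be a positive integer number of frames",
         call. = FALSE)
  }
  if (p$behavioral_hold_frames < 1) {
    stop("behavioral_hold_frames must be >= 1", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.stimulus_params <- function(x, ...) {
  cat(sprintf(
    "<stimulus_params> %s mode: %g deg dots, %g/deg^2, annulus %g-%g deg\n",
    x$mode, x$dot_diameter, x$density, x$aperture_inner, x$aperture_outer))
  cat(sprintf("  CD: %g Hz, %g arcmin; IOVD: %g Hz, %s, lifetime %g ms\n",
              x$cd_frequency, x$cd_disparity_amplitude, x$iovd_frequency,
              x$iovd_profile_mode, 1000 * x$dot_lifetime))
  invisible(x)
}

## Number of video frames in a sequence and their onset times (s).
n_frames <- function(params) as.integer(round(params$frame_rate * params$duration))
frame_times <- function(params) (seq_len(n_frames(params)) - 1) / params$frame_rate

lifetime_frames <- function(params) {
  as.integer(round(params$frame_rate * params$dot_lifetime))
}

#' Aperture area and per-eye dot budget
#'
#' @param params A [stimulus_params()] object.
#' @return `annulus_area()`: the aperture area in square degrees;
#'   `dot_budget()`: the per-eye dot count `round(density * area)`.
#' @export
annulus_area <- function(params) {
  pi * (params$aperture_outer^2 - params$aperture_inner^2)
}

#' @rdname annulus_area
#' @export
dot_budget <- function(params) {
  as.integer(round(params$density * annulus_area(params)))
}

#' Raised-cosine contrast envelope
#'
#' The presentation contrast ramps up with a raised cosine over `ramp_time`
#' seconds, sits at 1 for `duration - 2 * ramp_time` seconds, and ramps back
#' down. With the 3 s default presentation and 0.75 s ramps the stimulus is
#' at peak contrast for 1.5 s.
#'
#' @param t Time(s) within the presentation, seconds, in `[0, duration]`.
#' @param params A [stimulus_params()] object.
#' @return Envelope value(s) in `[0, 1]`.
#' @export
#' @examples
#' p <- stimulus_params()
#' contrast_envelope(c(0, 0.75, 1.5, 3), p)
contrast_envelope <- function(t, params) {
  d <- params$duration
  r <- params$ramp_time
  if (2 * r > d) stop("2 * ramp_time exceeds the stimulus duration", call. = FALSE)
  if (any(t < -1e-12 | t > d + 1e-12)) {
    stop("t must lie within [0, duration]", call. = FALSE)
  }
  t <- pmin(pmax(t, 0), d)
  up <- t < r
  down <- t > d - r
  e <- rep(1, length(t))
  e[up] <- 0.5 - 0.5 * cos(pi * t[up] / r)
  e[down] <- 0.5 - 0.5 * cos(pi * (d - t[down]) / r)
  e
}

## ---- annulus / stripe geometry helpers ------------------------------------

## Area of the disk of radius r lying below the horizontal line y.
disk_area_below <- function(r, y) {
  y <- pmax(-r, pmin(r, y))
  y * sqrt(pmax(r^2 - y^2, 0)) + r^2 * asin(y / r) + pi * r^2 / 2
}

## Area of the annulus within the horizontal band [a, b].
annulus_band_area <- function(params, a, b) {
  (disk_area_below(params$aperture_outer, b) -
     disk_area_below(params$aperture_outer, a)) -
    (disk_area_below(params$aperture_inner, b) -
       disk_area_below(params$aperture_inner, a))
}

## Horizontal stripe decomposition of the aperture for the IOVD stimulus:
## stripes of height `stripe_height` stacked from the bottom of the aperture,
## assigned alternately to the left and right eye (left owns the lowest).
stripe_bands <- function(params) {
  lo <- -params$aperture_outer
  hi <- params$aperture_outer
  edges <- seq(lo, hi, by = params$stripe_height)
  if (edges[length(edges)] < hi - 1e-9) edges <- c(edges, hi)
  n <- length(edges) - 1L
  eye <- rep(c("left", "right"), length.out = n)
  data.frame(
    index = seq_len(n), lo = edges[-length(edges)], hi = edges[-1],
    eye = eye,
    area = mapply(function(a, b) annulus_band_area(params, a, b),
                  edges[-length(edges)], edges[-1])
  )
}

## Uniform samples in the annulus (optionally restricted to a set of bands).
sample_annulus <- function(n, params, bands = NULL) {
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    r <- sqrt(stats::runif(m, params$aperture_inner^2, params$aperture_outer^2))
    th <- stats::runif(m, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    keep <- rep(TRUE, m)
    if (!is.null(bands)) {
      keep <- rep(FALSE, m)
      for (i in seq_len(nrow(bands))) {
        keep <- keep | (y >= bands$lo[i] & y < bands$hi[i])
      }
    }
    out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
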