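#' Display colorimetry model
#'
#' Characterizes a three-primary display by the 3x3 matrix mapping linear RGB
#' drive to L, M, S cone excitations, the per-channel gamma exponents, and
#' the background (mean) point in linear RGB. The packaged default,
#' [default_display()], is a synthetic model representative of an LCD whose
#' gamut limits the S-cone-isolating Michelson contrast to about 45% around
#' its background -- the regime the stimulus design assumes. It is not a
#' measurement of any physical display.
#'
#' @param rgb_to_lms 3x3 matrix; rows L, M, S; columns the cone excitations
#'   of the R, G, B primaries at full drive.
#' @param gamma Length-3 positive exponents mapping device drive to linear
#'   output (`linear = device^gamma`).
#' @param background_rgb Background point in linear RGB, strictly inside the
#'   gamut.
#' @return An object of class `display_model`.
#' @export
display_model <- function(rgb_to_lms, gamma = c(2.2, 2.2, 2.2),
                          background_rgb = c(0.5, 0.5, 0.5)) {
  rgb_to_lms <- as.matrix(rgb_to_lms)
  stopifnot(all(dim(rgb_to_lms) == c(3, 3)), length(gamma) == 3,
            length(background_rgb) == 3)
  if (abs(det(rgb_to_lms)) < 1e-12) {
    stop("rgb_to_lms must be invertible", call. = FALSE)
  }
  if (any(gamma <= 0)) stop("gamma exponents must be > 0", call. = FALSE)
  if (any(background_rgb <= 0) || any(background_rgb >= 1)) {
    stop("background_rgb must be strictly inside the gamut", call. = FALSE)
  }
  structure(list(rgb_to_lms = rgb_to_lms, gamma = as.numeric(gamma),
                 background_rgb = as.numeric(background_rgb)),
            class = "display_model")
}

#' @rdname display_model
#' @export
default_display <- function() {
  display_model(
    rgb_to_lms = matrix(c(0.3139, 0.6395, 0.0466,
                          0.1516, 0.7482, 0.1001,
                          0.0178, 0.0865, 0.8957), 3, 3, byrow = TRUE,
                        dimnames = list(c("L", "M", "S"), c("R", "G", "B"))),
    gamma = c(2.2, 2.2, 2.2),
    background_rgb = c(0.5, 0.5, 0.669)
  )
}

#' @export
print.display_model <- function(x, ...) {
  cat("<display_model>\n")
  print(round(x$rgb_to_lms, 4))
  cat("gamma:", x$gamma, " background (linear RGB):", x$background_rgb, "\n")
  invisible(x)
}

#' Convert between device RGB and cone excitations
#'
#' `lms_of_rgb()` gamma-linearizes device RGB drive values and applies the
#' display's RGB-to-LMS matrix; `rgb_of_lms()` is the exact inverse and
#' raises an error naming the offending channel when the requested excitation
#' falls outside the display gamut.
#'
#' @param display A [display_model()].
#' @param rgb Device RGB triplet in `[0, 1]^3`.
#' @param lms Cone excitation triplet.
#' @return The converted triplet.
#' @export
lms_of_rgb <- function(display, rgb) {
  stopifnot(length(rgb) == 3)
  if (any(rgb < -1e-12) || any(rgb > 1 + 1e-12)) {
    stop("rgb values must lie in [0, 1]", call. = FALSE)
  }
  lin <- pmin(pmax(rgb, 0), 1)^display$gamma
  as.numeric(display$rgb_to_lms %*% lin)
}

#' @rdname lms_of_rgb
#' @export
rgb_of_lms <- function(display, lms) {
  stopifnot(length(lms) == 3)
  lin <- as.numeric(solve(display$rgb_to_lms, lms))
  bad <- which(lin < -1e-9 | lin > 1 + 1e-9)
  if (length(bad)) {
    stop(sprintf("requested excitation is outside the display gamut (channel %s)",
                 paste(c("R", "G", "B")[bad], collapse = ", ")), call. = FALSE)
  }
  pmin(pmax(lin, 0), 1)^(1 / display$gamma)
}

## Background cone excitations and device drive of a display.
background_lms <- function(display) {
  as.numeric(display$rgb_to_lms %*% display$background_rgb)
}

background_device <- function(display) {
  display$background_rgb^(1 / display$gamma)
}

#' Maximum attainable contrast on a modulation axis
#'
#' Largest Michelson cone contrast whose positive and negative poles both
#' stay inside the display gamut, for the achromatic (L, M and S modulated
#' equally) or S-cone-isolating axis around the display background.
#'
#' @param display A [display_model()].
#' @param axis `"achromatic"` or `"s_isolating"`.
#' @return The maximum contrast (scalar in `(0, 1]`).
#' @export
#' @examples
#' max_axis_contrast(default_display(), "s_isolating") # ~0.45
max_axis_contrast <- function(display, axis = c("achromatic", "s_isolating")) {
  axis <- match.arg(axis)
  bg <- background_lms(display)
  dir_lms <- if (axis == "achromatic") bg else c(0, 0, bg[3])
  u <- as.numeric(solve(display$rgb_to_lms, dir_lms)) # linear RGB per unit contrast
  b <- display$background_rgb
  lims <- pmin(b, 1 - b) / abs(u)
  min(lims[is.finite(lims)])
}

#' Dot colors for an achromatic or S-cone-isolating modulation
#'
#' Returns the device RGB values of the positive- and negative-polarity dot
#' colors: cone excitations displaced symmetrically about the background
#' along the requested axis. The achromatic axis modulates L, M and S with
#' equal Michelson contrast; the S-isolating axis modulates S only
#' (`cL = cM = 0`).
#'
#' @param display A [display_model()].
#' @param axis `"achromatic"` or `"s_isolating"`.
#' @param contrast Michelson cone contrast in `[0, 1]`.
#' @return A list with device RGB triplets `positive` and `negative`, plus
#'   `lms_positive`, `lms_negative`.
#' @export
dot_colors <- function(display, axis = c("achromatic", "s_isolating"),
                       contrast) {
  axis <- match.arg(axis)
  stopifnot_scalar(contrast, "contrast", positive = FALSE)
  if (contrast < 0) stop("contrast must be >= 0", call. = FALSE)
  cmax <- max_axis_contrast(display, axis)
  if (contrast > cmax + 1e-12) {
    stop(sprintf("contrast %.4f exceeds the display gamut on the %s axis (max %.4f)",
                 contrast, axis, cmax), call. = FALSE)
  }
  bg <- background_lms(display)
  delta <- if (axis == "achromatic") contrast * bg else c(0, 0, contrast * bg[3])
  list(
    positive = rgb_of_lms(display, bg + delta),
    negative = rgb_of_lms(display, bg - delta),
    lms_positive = bg + delta,
    lms_negative = bg - delta
  )
}

#' Cone contrasts of a polarity pair
#'
#' Michelson contrast per cone class, `(E_max - E_min) / (E_max + E_min)`,
#' computed across the positive/negative pair and signed by the direction of
#' the positive pole.
#'
#' @param display A [display_model()].
#' @param pair A list with `lms_positive` and `lms_negative` (as returned by
#'   [dot_colors()]), or two device RGB triplets `positive` / `negative`.
#' @return Named numeric vector `c(cL, cM, cS)`.
#' @export
cone_contrast <- function(display, pair) {
  lp <- pair$lms_positive %||% lms_of_rgb(display, pair$positive)
  lm <- pair$lms_negative %||% lms_of_rgb(display, pair$negative)
  c(cL = (lp[1] - lm[1]) / (lp[1] + lm[1]),
    cM = (lp[2] - lm[2]) / (lp[2] + lm[2]),
    cS = (lp[3] - lm[3]) / (lp[3] + lm[3]))
}

#' Achromatic contrast scaling rule
#'
#' The achromatic dot contrast is set to a fixed fraction (default 10%) of
#' the S-cone contrast, balancing the salience and early-cortical drive of
#' the two chromaticities. With the ~45% S-cone gamut limit this yields the
#' 4.5% Michelson achromatic contrast used for the dot stimuli.
#'
#' @param s_cone_contrast S-cone Michelson contrast in `(0, 1]`.
#' @param policy_ratio Scaling fraction in `(0, 1]`.
#' @return The achromatic Michelson contrast.
#' @export
#' @examples
#' scale_achromatic_contrast(0.45) # 0.045
scale_achromatic_contrast <- function(s_cone_contrast, policy_ratio = 0.10) {
  stopifnot_scalar(s_cone_contrast, "s_cone_contrast")
  stopifnot_scalar(policy_ratio, "policy_ratio")
  if (s_cone_contrast > 1 || policy_ratio > 1) {
    stop("inputs must lie in (0, 1]", call. = FALSE)
  }
  s_cone_contrast * policy_ratio
}

#' Flicker-photometry observer
#'
#' An observer for the heterochromatic flicker photometry task: luminance is
#' a weighted sum of cone excitations (`wS` is ~0 since S cones contribute
#' negligibly to luminance), and each isoluminance setting is corrupted by
#' Gaussian adjustment noise.
#'
#' @param lum_weights Length-3 weights `(wL, wM, wS)`; `wL + wM` must be
#'   positive.
#' @param setting_noise_sd SD of a single setting, in contamination
#'   (Michelson) units.
#' @return An object of class `flicker_observer`.
#' @export
flicker_observer <- function(lum_weights = c(0.68, 0.32, 0),
                             setting_noise_sd = 0.005) {
  stopifnot(length(lum_weights) == 3)
  if (lum_weights[1] + lum_weights[2] <= 0) {
    stop("wL + wM must be > 0", call. = FALSE)
  }
  if (setting_noise_sd < 0) stop("setting_noise_sd must be >= 0", call. = FALSE)
  structure(list(lum_weights = as.numeric(lum_weights),
                 setting_noise_sd = setting_noise_sd),
            class = "flicker_observer")
}

## Luminance modulation of the lime/violet alternation at contamination k:
## the nominal S-axis modulation (possibly carrying L/M residuals when the
## display used to compute it differs from the true one) plus k times a unit
## (L+M) modulation scaled by the background excitations.
flicker_residual <- function(display, observer, k, base_modulation) {
  bg <- background_lms(display)
  contam <- c(bg[1], bg[2], 0)
  w <- observer$lum_weights
  abs(sum(w * (base_modulation + k * contam)))
}

#' Analytic isoluminance point of the flicker task
#'
#' The lime/violet S-cone alternation is perceptually isoluminant when the
#' luminance modulation `wL * dL(k) + wM * dM(k) + wS * dS` vanishes, where
#' `k` parameterizes the amount of (L+M) contamination added to the nominal
#' S-isolating modulation. Because the contamination enters linearly, the
#' zero is unique and available in closed form.
#'
#' When `nominal_display` differs from `display` (miscalibration, individual
#' cone fundamentals), the nominally S-isolating modulation carries L/M
#' residuals on the true display and the solved `k*` is nonzero.
#'
#' @param display The true [display_model()] seen by the observer.
#' @param observer A [flicker_observer()].
#' @param contrast S-cone contrast of the alternation.
#' @param nominal_display Display model used to construct the nominally
#'   S-isolating modulation (defaults to `display`).
#' @return The contamination `k*` in Michelson units.
#' @export
solve_isoluminance <- function(display, observer, contrast = 0.30,
                               nominal_display = display) {
  ## nominal S-isolating modulation, expressed in linear RGB on the nominal
  ## display, then evaluated in cone space on the true display
  bg_nom <- background_lms(nominal_display)
  rgb_mod <- as.numeric(solve(nominal_display$rgb_to_lms,
                              c(0, 0, contrast * bg_nom[3])))
  base_mod <- as.numeric(display$rgb_to_lms %*% rgb_mod)
  bg <- background_lms(display)
  w <- observer$lum_weights
  denom <- w[1] * bg[1] + w[2] * bg[2]
  if (abs(denom) < 1e-15) {
    stop("degenerate observer: luminance is insensitive to (L+M) contamination",
         call. = FALSE)
  }
  -sum(w * base_mod) / denom
}

#' Simulate the heterochromatic flicker photometry session
#'
#' Each eye contributes `settings_per_eye` independent isoluminance settings,
#' modeled as the analytic isoluminance point plus Gaussian adjustment noise;
#' the per-eye mean is the observer's isoluminance estimate, as in the in
#' situ procedure run before scanning and behavioral testing.
#'
#' @inheritParams solve_isoluminance
#' @param settings_per_eye Number of settings per eye (default 3).
#' @param seed Integer seed.
#' @return A list with `settings` (data frame: eye, setting) and `mean`
#'   (named per-eye means).
#' @export
simulate_flicker_task <- function(display, observer, settings_per_eye = 3,
                                  seed = 1, contrast = 0.30,
                                  nominal_display = display) {
  if (settings_per_eye < 1) stop("settings_per_eye must be >= 1", call. = FALSE)
  k_star <- solve_isoluminance(display, observer, contrast, nominal_display)
  eyes <- c("left", "right")
  settings <- with_seed(mix_seed(seed, 31L), {
    data.frame(
      eye = rep(eyes, each = settings_per_eye),
      setting = k_star + stats::rnorm(2 * settings_per_eye,
                                      sd = observer$setting_noise_sd)
    )
  })
  means <- vapply(eyes, function(e) mean(settings$setting[settings$eye == e]),
                  numeric(1))
  list(settings = settings, mean = means)
}
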