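#' Changing-disparity (CD) stimulus sequence
#'
#' Builds a dynamic random-dot stereogram in which signal dots appear as
#' interocular pairs whose horizontal offset follows the disparity signal
#' `d(t) = A * sin(2 * pi * f_CD * t)` (arcmin), applied symmetrically as
#' -/+ `d(t)/2` to the left/right eye. The disparity-defined plane therefore
#' oscillates in depth at `cd_frequency` Hz with peak interocular disparity
#' `cd_disparity_amplitude` arcmin.
#'
#' At coherence `c`, `round(c * N)` of the `N` per-eye dots are binocularly
#' paired signal dots; the remainder are noise dots positioned independently
#' in the two eyes so they carry no systematic disparity signal (random
#' binocular matches are allowed). In `"fmri"` mode all dot positions
#' regenerate on every video frame, eliminating coherent monocular motion; in
#' `"behavioral"` mode positions are held for `behavioral_hold_frames`
#' consecutive frames while `d(t)` keeps evolving at its usual rate.
#'
#' @param params A [stimulus_params()] object.
#' @param coherence Fraction of dots carrying the MID signal, in `[0, 1]`.
#' @param seed Integer seed; the sequence is deterministic given
#'   `(params, coherence, seed)`.
#' @return A `stereo_sequence` with `cue = "CD"`.
#' @export
#' @examples
#' p <- stimulus_params(duration = 0.5)
#' s <- cd_sequence(p, coherence = 1, seed = 1)
#' fit_sinusoid(disparity_trace(s))$amplitude # ~24 arcmin
cd_sequence <- function(params, coherence = 1, seed = 1) {
  validate_stimulus_params(params)
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0, 1]", call. = FALSE)

  nF <- n_frames(params)
  times <- frame_times(params)
  N <- dot_budget(params)
  n_sig <- as.integer(round(coherence * N))
  n_noise <- N - n_sig
  hold <- if (params$mode == "behavioral") params$behavioral_hold_frames else 1L
  A <- params$cd_disparity_amplitude            # arcmin, peak interocular
  half_deg <- A / 120                           # per-eye shift amplitude, deg
  d_arcmin <- A * sin(2 * pi * params$cd_frequency * times)
  half_shift <- d_arcmin / 120                  # per-eye shift, deg

  ## worst-case change of the per-eye shift within one hold block: signal
  ## dots drift by at most this much relative to static noise dots, so noise
  ## placement uses it as an extra separation margin
  block_margin <- half_deg * 2 * pi * params$cd_frequency *
    (hold - 1L) / params$frame_rate

  blocks <- split(seq_len(nF), ceiling(seq_len(nF) / hold))
  rows <- vector("list", 2L * length(blocks))
  pair_l <- vector("list", length(blocks))
  id0 <- 0L
  for (b in seq_along(blocks)) {
    fr <- blocks[[b]]
    out <- with_seed(mix_seed(seed, b), {
      sig <- place_dots(n_sig, params, group = rep("sig", n_sig),
                        future_dx = list(sig = c(-half_deg, 0, half_deg)))
      sig_pol <- sample(c(-1L, 1L), n_sig, replace = TRUE)
      eye_frames <- list()
      noise <- list()
      for (e in c("left", "right")) {
        s <- if (e == "left") -1 else 1
        ex <- if (n_sig) cbind(sig$x + s * half_shift[fr[1]], sig$y) else NULL
        nz <- place_dots(n_noise, params, group = rep("noise", n_noise),
                         existing_xy = ex,
                         existing_group = rep("sig", n_sig),
                         closure = block_margin)
        nz$polarity <- sample(c(-1L, 1L), n_noise, replace = TRUE)
        noise[[e]] <- nz
      }
      list(sig = sig, sig_pol = sig_pol, noise = noise)
    })

    ids_sig_l <- id0 + seq_len(n_sig)
    ids_sig_r <- id0 + n_sig + seq_len(n_sig)
    ids_nz_l <- id0 + 2L * n_sig + seq_len(n_noise)
    ids_nz_r <- id0 + 2L * n_sig + n_noise + seq_len(n_noise)
    id0 <- id0 + 2L * (n_sig + n_noise)
    if (n_sig) {
      pair_l[[b]] <- data.frame(left_id = ids_sig_l, right_id = ids_sig_r)
    }

    for (e in c("left", "right")) {
      s <- if (e == "left") -1 else 1
      nz <- out$noise[[e]]
      nfr <- length(fr)
      x_sig <- if (n_sig) {
        rep(out$sig$x, times = nfr) + s * rep(half_shift[fr], each = n_sig)
      } else numeric(0)
      rows[[2L * (b - 1L) + match(e, c("left", "right"))]] <- data.frame(
        frame = c(rep(fr, each = n_sig), rep(fr, each = n_noise)),
        time = c(rep(times[fr], each = n_sig), rep(times[fr], each = n_noise)),
        eye = e,
        id = c(rep(if (e == "left") ids_sig_l else ids_sig_r, times = nfr),
               rep(if (e == "left") ids_nz_l else ids_nz_r, times = nfr)),
        x = c(x_sig, rep(nz$x, times = nfr)),
        y = c(rep(out$sig$y, times = nfr), rep(nz$y, times = nfr)),
        polarity = c(rep(out$sig_pol, times = nfr), rep(nz$polarity, times = nfr)),
        role = c(rep("signal", n_sig * nfr), rep("noise", n_noise * nfr)),
        age = c(rep(seq_len(nfr), each = n_sig), rep(seq_len(nfr), each = n_noise)),
        stripe = NA_integer_,
        vx = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  frames <- do.call(rbind, rows)
  frames <- frames[order(frames$frame, frames$eye, frames$id), ]
  rownames(frames) <- NULL
  pairing <- if (n_sig) do.call(rbind, pair_l) else
    data.frame(left_id = integer(0), right_id = integer(0))
  new_stereo_sequence(params, "CD", coherence, frames, pairing, as.integer(seed))
}

#' CD control sequence (temporally shuffled CD frames)
#'
#' Applies a seeded uniform random permutation to the frames of a fully
#' coherent CD sequence. Each individual frame keeps its binocular disparity,
#' so the control contains the same multiset of disparities as its source,
#' but the smooth temporal disparity change that conveys motion in depth is
#' destroyed.
#'
#' @param source A `stereo_sequence` with `cue = "CD"` and coherence 1.
#' @param seed Integer seed for the permutation.
#' @return A `stereo_sequence` with `cue = "CD_control"`.
#' @export
cd_control_sequence <- function(source, seed = 1) {
  if (!inherits(source, "stereo_sequence") || source$cue != "CD") {
    stop("source must be a CD stereo_sequence", call. = FALSE)
  }
  if (source$coherence != 1) {
    stop("the CD control is defined for a fully coherent source", call. = FALSE)
  }
  if (nrow(source$frames) == 0) stop("source sequence is empty", call. = FALSE)

  fr <- sort(unique(source$frames$frame))
  times <- sort(unique(source$frames$time))
  perm <- with_seed(mix_seed(seed, 23L), sample(length(fr)))
  ## frame i of the control displays source frame perm[i]
  map <- match(source$frames$frame, fr)
  new_frame <- match(map, perm) # position where each source frame lands
  frames <- source$frames
  frames$frame <- fr[new_frame]
  frames$time <- times[new_frame]
  frames <- frames[order(frames$frame, frames$eye, frames$id), ]
  rownames(frames) <- NULL
  new_stereo_sequence(source$params, "CD_control", source$coherence,
                      frames, source$pairing, as.integer(seed))
}

#' Interocular disparity trace of a CD-family sequence
#'
#' Per-frame mean horizontal offset (right-eye x minus left-eye x) over all
#' paired signal dots, converted to arcmin.
#'
#' @param seq A `stereo_sequence` with cue `"CD"` or `"CD_control"`.
#' @return A `ts_trace` (times in s, values in arcmin).
#' @export
disparity_trace <- function(seq) {
  if (!seq$cue %in% c("CD", "CD_control")) {
    stop("disparity_trace requires a CD or CD_control sequence", call. = FALSE)
  }
  if (nrow(seq$pairing) == 0) {
    stop("no signal-dot pairs: disparity trace undefined", call. = FALSE)
  }
  lf <- seq$frames[seq$frames$eye == "left" &
                     seq$frames$id %in% seq$pairing$left_id, ]
  rf <- seq$frames[seq$frames$eye == "right" &
                     seq$frames$id %in% seq$pairing$right_id, ]
  lf$pair <- match(lf$id, seq$pairing$left_id)
  rf$pair <- match(rf$id, seq$pairing$right_id)
  lf <- lf[order(lf$frame, lf$pair), ]
  rf <- rf[order(rf$frame, rf$pair), ]
  stopifnot(nrow(lf) == nrow(rf), all(lf$frame == rf$frame))
  disp <- (rf$x - lf$x) * 60
  vals <- as.numeric(tapply(disp, lf$frame, mean))
  fr <- sort(unique(lf$frame))
  tms <- as.numeric(tapply(lf$time, lf$frame, function(t) t[1]))[order(fr)]
  ts_trace(tms, vals, label = "disparity (arcmin)")
}
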