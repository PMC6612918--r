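## Shared constructor for the central stimulus artifact: a timestamped
## sequence of per-eye dot frames plus metadata.
new_stereo_sequence <- function(params, cue, coherence, frames, pairing, seed) {
  structure(
    list(params = params, cue = cue, coherence = coherence,
         frames = frames, pairing = pairing, seed = seed),
    class = "stereo_sequence"
  )
}

#' @export
print.stereo_sequence <- function(x, ...) {
  nf <- length(unique(x$frames$frame))
  cat(sprintf("<stereo_sequence> cue=%s coherence=%g: %d frames, %d dot records, seed=%d\n",
              x$cue, x$coherence, nf, nrow(x$frames), x$seed))
  invisible(x)
}

## Per-eye dot counts for every frame (matrix frames x eyes).
sequence_dot_counts <- function(seq) {
  table(seq$frames$frame, seq$frames$eye)
}

#' Run lengths of held dot positions
#'
#' Measures, for each eye, how many consecutive frames share an identical set
#' of dots (same ids). In fmri mode every CD frame is regenerated, so all run
#' lengths are 1; in behavioral mode positions are held for
#' `behavioral_hold_frames` frames while the disparity signal keeps moving.
#'
#' @param seq A `stereo_sequence`.
#' @return Integer vector of run lengths (both eyes pooled).
#' @export
hold_run_lengths <- function(seq) {
  out <- integer(0)
  fr <- sort(unique(seq$frames$frame))
  for (e in unique(seq$frames$eye)) {
    sub <- seq$frames[seq$frames$eye == e, ]
    ids <- lapply(fr, function(f) sort(sub$id[sub$frame == f]))
    run <- 1L
    runs <- integer(0)
    for (i in seq_along(ids)[-1]) {
      if (identical(ids[[i]], ids[[i - 1L]])) {
        run <- run + 1L
      } else {
        runs <- c(runs, run); run <- 1L
      }
    }
    runs <- c(runs, run)
    out <- c(out, runs)
  }
  out
}

#' Per-frame dot regeneration counts
#'
#' Number of dot ids appearing in each frame that were absent from the
#' previous frame of the same eye. For IOVD-family sequences this is constant
#' across frames by construction (transient balancing).
#'
#' @param seq A `stereo_sequence`.
#' @return Integer vector, one entry per frame after the first (both eyes
#'   summed).
#' @export
regeneration_counts <- function(seq) {
  fr <- sort(unique(seq$frames$frame))
  if (length(fr) < 2) return(integer(0))
  counts <- integer(length(fr) - 1L)
  for (e in unique(seq$frames$eye)) {
    sub <- split(seq$frames$id[seq$frames$eye == e],
                 factor(seq$frames$frame[seq$frames$eye == e], levels = fr))
    for (i in seq_along(fr)[-1]) {
      counts[i - 1L] <- counts[i - 1L] + sum(!(sub[[i]] %in% sub[[i - 1L]]))
    }
  }
  counts
}

#' Maximum dot persistence in frames
#'
#' Longest number of consecutive frames any single dot id is present.
#'
#' @param seq A `stereo_sequence`.
#' @return Integer, maximum persistence in frames.
#' @export
max_dot_persistence <- function(seq) {
  per_eye <- vapply(unique(seq$frames$eye), function(e) {
    sub <- seq$frames[seq$frames$eye == e, ]
    max(table(sub$id))
  }, numeric(1))
  as.integer(max(per_eye))
}
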