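# Short-duration parameter sets keep the suite fast; all geometric and
# oscillation parameters stay at their experiment defaults.
short_params <- function(duration = 0.5, ...) {
  stimulus_params(duration = duration, ramp_time = min(0.2, duration / 3), ...)
}

# Per-frame mean signed horizontal velocity of a subset of dots, by eye.
# Returns a matrix (frames-1) x 2 [left, right]; NA where no dot persists.
mean_signed_velocity <- function(seq, roles = c("signal", "noise")) {
  fr <- sort(unique(seq$frames$frame))
  out <- matrix(NA_real_, length(fr) - 1L, 2,
                dimnames = list(NULL, c("left", "right")))
  for (e in c("left", "right")) {
    sub <- seq$frames[seq$frames$eye == e & seq$frames$role %in% roles, ]
    byf <- split(sub[, c("id", "x")], factor(sub$frame, levels = fr))
    for (i in seq_along(fr)[-1]) {
      m <- match(byf[[i]]$id, byf[[i - 1L]]$id)
      ok <- !is.na(m)
      if (any(ok)) {
        out[i - 1L, e] <- mean((byf[[i]]$x[ok] - byf[[i - 1L]]$x[m[ok]])) *
          seq$params$frame_rate
      }
    }
  }
  out
}

# Smallest pairwise center distance over every frame/eye of a sequence.
sequence_min_separation <- function(seq) {
  mins <- c()
  for (f in unique(seq$frames$frame)) {
    for (e in c("left", "right")) {
      sub <- seq$frames[seq$frames$frame == f & seq$frames$eye == e, ]
      if (nrow(sub) >= 2) mins <- c(mins, min(dist(cbind(sub$x, sub$y))))
    }
  }
  min(mins)
}

# All dots inside the annular aperture?
all_in_annulus <- function(seq) {
  r <- sqrt(seq$frames$x^2 + seq$frames$y^2)
  all(r >= seq$params$aperture_inner - 1e-9 &
        r <= seq$params$aperture_outer + 1e-9)
}
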