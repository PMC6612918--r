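test_that("coherent IOVD has antisymmetric eye velocities at 1.1 Hz", {
  p <- short_params(duration = 1.0)
  s <- iovd_sequence(p, coherence = 1, seed = 1)
  v <- mean_signed_velocity(s, roles = "signal")
  # v_L(t) = -v_R(t) exactly, every frame
  expect_true(all(abs(v[, "left"] + v[, "right"]) < 1e-9))
  fit <- fit_sinusoid(iovd_trace(s))
  expect_equal(fit$frequency, 1.1, tolerance = 1e-3)
  # trace = v_L - v_R = 2 v(t), so its amplitude is twice the peak speed
  expect_equal(fit$amplitude, 2 * p$iovd_peak_speed, tolerance = 0.01)
})

test_that("IOVD dots live at most 50 ms and regeneration is transient-balanced", {
  p <- short_params(duration = 1.0)
  s <- iovd_sequence(p, coherence = 1, seed = 2)
  L <- round(p$dot_lifetime * p$frame_rate)
  expect_equal(max_dot_persistence(s), L)      # 6 frames = 50 ms at 120 Hz
  expect_true(all(s$frames$age <= L))
  regen <- regeneration_counts(s)
  expect_equal(length(unique(regen)), 1L)      # same number every frame
})

test_that("near-border interocular pairs are anticorrelated", {
  p <- short_params(duration = 0.5)
  s <- iovd_sequence(p, coherence = 1, seed = 3)
  for (f in unique(s$frames$frame)) {
    lf <- s$frames[s$frames$frame == f & s$frames$eye == "left", ]
    rf <- s$frames[s$frames$frame == f & s$frames$eye == "right", ]
    d2 <- outer(lf$x, rf$x, "-")^2 + outer(lf$y, rf$y, "-")^2
    hit <- which(d2 <= p$anticorr_radius^2, arr.ind = TRUE)
    if (nrow(hit)) {
      prods <- lf$polarity[hit[, 1]] * rf$polarity[hit[, 2]]
      expect_true(all(prods == -1L))
    }
  }
})

test_that("stripes are monocular and per-eye density matches the budget", {
  p <- short_params(duration = 0.25)
  s <- iovd_sequence(p, coherence = 1, seed = 4)
  bands <- stereomid:::stripe_bands(p)
  f1 <- s$frames[s$frames$frame == 1, ]
  # each stripe's dots belong to exactly one eye
  for (b in seq_len(nrow(bands))) {
    dots <- f1[f1$y >= bands$lo[b] & f1$y < bands$hi[b], ]
    if (nrow(dots)) expect_equal(unique(dots$eye), bands$eye[b])
  }
  counts <- sequence_dot_counts(s)
  for (e in c("left", "right")) {
    budget <- p$density * sum(bands$area[bands$eye == e])
    expect_true(all(abs(counts[, e] - budget) <= 1))
    expect_equal(length(unique(counts[, e])), 1L) # conserved across frames
  }
})

test_that("IOVD trace amplitude is linear in coherence", {
  p <- short_params(duration = 1.0)
  a1 <- fit_sinusoid(iovd_trace(iovd_sequence(p, 1, seed = 5)))$amplitude
  a05 <- fit_sinusoid(iovd_trace(iovd_sequence(p, 0.5, seed = 5)))$amplitude
  expect_equal(a05 / a1, 0.5, tolerance = 0.05)
})

test_that("IOVD respects separation and containment over seeds", {
  for (seed in 1:3) {
    p <- short_params(duration = 0.2)
    s <- iovd_sequence(p, coherence = 0.5, seed = seed)
    expect_true(all_in_annulus(s))
    expect_gte(sequence_min_separation(s), p$min_separation - 1e-9)
  }
})

test_that("the displacement-matched profile hits the 100 arcmin amplitude", {
  p <- short_params(duration = 1.0, density = 0.3,
                    iovd_profile_mode = "displacement_matched")
  s <- iovd_sequence(p, coherence = 1, seed = 6)
  fit <- fit_sinusoid(iovd_trace(s))
  expect_equal(fit$frequency, 1.1, tolerance = 1e-2)
  # peak speed 2 pi f A on each eye; trace amplitude is twice that
  expect_equal(fit$amplitude, 2 * 2 * pi * 1.1 * 100 / 60, tolerance = 0.02)
})

test_that("IOVD control nulls the interocular velocity difference", {
  p <- short_params(duration = 1.0)
  s <- iovd_control_sequence(p, seed = 7)
  expect_equal(s$cue, "IOVD_control")
  tr <- iovd_trace(s)
  peak <- 2 * p$iovd_peak_speed
  expect_lt(mean(abs(tr$values)), 0.01 * peak)
  expect_lt(max(abs(tr$values)), 0.05 * peak)
})

test_that("IOVD control balances directions within each eye exactly", {
  p <- short_params(duration = 0.25)
  s <- iovd_control_sequence(p, seed = 8)
  # equal numbers of leftward and rightward movers at every frame: the mean
  # signed per-eye velocity over all dots vanishes identically
  bal <- aggregate(vx ~ frame + eye, data = s$frames, FUN = mean)
  expect_true(all(abs(bal$vx) < 1e-12))
  # and the split is exactly even
  cnt <- aggregate(vx ~ frame + eye, data = s$frames,
                   FUN = function(v) sum(v > 0) - sum(v < 0))
  expect_true(all(cnt$vx == 0))
})

test_that("IOVD control has the same monocular speed distribution as IOVD", {
  p <- short_params(duration = 0.5)
  spd <- function(s) {
    v <- c()
    fr <- sort(unique(s$frames$frame))
    for (e in c("left", "right")) {
      sub <- s$frames[s$frames$eye == e, ]
      byf <- split(sub[, c("id", "x")], factor(sub$frame, levels = fr))
      for (i in seq_along(fr)[-1]) {
        m <- match(byf[[i]]$id, byf[[i - 1]]$id)
        ok <- !is.na(m)
        v <- c(v, abs(byf[[i]]$x[ok] - byf[[i - 1]]$x[m[ok]]) * 120)
      }
    }
    v
  }
  s1 <- spd(iovd_sequence(p, 1, seed = 9))
  s0 <- spd(iovd_control_sequence(p, seed = 10))
  q <- seq(0.05, 0.95, by = 0.05)
  expect_equal(quantile(s0, q), quantile(s1, q), tolerance = 0.02)
})

test_that("IOVD validates stripe and anticorrelation parameters", {
  expect_error(stimulus_params(stripe_height = -1), "stripe_height")
  expect_error(iovd_sequence(short_params(), coherence = 2), "coherence")
})
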