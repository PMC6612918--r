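test_that("identity display maps rgb to lms unchanged", {
  d <- display_model(diag(3), gamma = c(1, 1, 1))
  expect_equal(lms_of_rgb(d, c(0.2, 0.5, 0.9)), c(0.2, 0.5, 0.9))
  expect_equal(lms_of_rgb(d, stereomid:::background_device(d)),
               stereomid:::background_lms(d))
})

test_that("rgb/lms conversions round-trip to 1e-9 on random displays", {
  set.seed(21)
  for (i in 1:20) {
    M <- diag(3) + matrix(runif(9, -0.2, 0.2), 3)
    d <- display_model(M, gamma = runif(3, 1.8, 2.6))
    lms <- lms_of_rgb(d, runif(3, 0.05, 0.95))
    expect_equal(lms_of_rgb(d, rgb_of_lms(d, lms)), lms, tolerance = 1e-9)
  }
})

test_that("out-of-gamut requests raise and name the channel", {
  d <- default_display()
  expect_error(rgb_of_lms(d, c(10, 10, 10)), "gamut")
  expect_error(dot_colors(d, "s_isolating", 0.99), "exceeds the display gamut")
})

test_that("the fixture display's S-cone gamut limit is about 45%", {
  cmax <- max_axis_contrast(default_display(), "s_isolating")
  expect_equal(cmax, 0.45, tolerance = 0.02)
})

test_that("S-isolating dot colors silence L and M on arbitrary displays", {
  set.seed(22)
  for (i in 1:15) {
    M <- diag(3) + matrix(runif(9, -0.2, 0.2), 3)
    d <- display_model(M, gamma = runif(3, 1.8, 2.6))
    c0 <- 0.8 * max_axis_contrast(d, "s_isolating")
    cc <- cone_contrast(d, dot_colors(d, "s_isolating", c0))
    expect_lt(abs(cc["cL"]), 1e-9)
    expect_lt(abs(cc["cM"]), 1e-9)
    expect_equal(unname(cc["cS"]), c0, tolerance = 1e-9)
  }
})

test_that("polarity pairs reflect exactly through the background in LMS", {
  d <- default_display()
  bg <- stereomid:::background_lms(d)
  for (axis in c("achromatic", "s_isolating")) {
    pair <- dot_colors(d, axis, 0.04)
    expect_equal(pair$lms_positive + pair$lms_negative, 2 * bg, tolerance = 1e-12)
  }
  ach <- cone_contrast(d, dot_colors(d, "achromatic", 0.045))
  expect_equal(unname(ach), rep(0.045, 3), tolerance = 1e-9)
})

test_that("zero contrast returns the background", {
  d <- default_display()
  pair <- dot_colors(d, "achromatic", 0)
  expect_equal(pair$positive, stereomid:::background_device(d), tolerance = 1e-12)
  expect_equal(pair$negative, pair$positive)
})

test_that("achromatic contrast scaling is the stated 10% rule", {
  expect_equal(scale_achromatic_contrast(0.45), 0.045)
  expect_equal(scale_achromatic_contrast(0.30), 0.03)
  expect_equal(scale_achromatic_contrast(0.7, policy_ratio = 1), 0.7)
  # linear and order preserving in both arguments
  expect_equal(scale_achromatic_contrast(0.2) + scale_achromatic_contrast(0.3),
               scale_achromatic_contrast(0.5))
  expect_lt(scale_achromatic_contrast(0.2), scale_achromatic_contrast(0.4))
  expect_error(scale_achromatic_contrast(1.5), "0, 1")
})

test_that("the analytic isoluminance point matches a grid search", {
  d <- default_display()
  obs <- flicker_observer()
  expect_equal(solve_isoluminance(d, obs), 0, tolerance = 1e-12)
  # a miscalibrated true display leaves L/M residuals to cancel
  pd <- d
  pd$rgb_to_lms[1, 3] <- pd$rgb_to_lms[1, 3] * 1.15
  pd$rgb_to_lms[2, 3] <- pd$rgb_to_lms[2, 3] * 0.94
  ks <- solve_isoluminance(pd, obs, nominal_display = d)
  expect_false(ks == 0)
  bgn <- stereomid:::background_lms(d)
  rgbm <- solve(d$rgb_to_lms, c(0, 0, 0.3 * bgn[3]))
  base <- as.numeric(pd$rgb_to_lms %*% rgbm)
  grid <- seq(ks - 0.02, ks + 0.02, length.out = 40001)
  res <- vapply(grid, function(k) stereomid:::flicker_residual(pd, obs, k, base),
                numeric(1))
  expect_lt(abs(grid[which.min(res)] - ks), 1e-6)
  # residual at k* is essentially zero compared to the uncorrected residual
  r0 <- stereomid:::flicker_residual(pd, obs, 0, base)
  expect_lt(stereomid:::flicker_residual(pd, obs, ks, base), 1e-9 * r0)
  # scale invariance: doubling (wL, wM) jointly leaves the zero unchanged
  obs2 <- flicker_observer(lum_weights = 2 * obs$lum_weights)
  expect_equal(solve_isoluminance(pd, obs2, nominal_display = d), ks,
               tolerance = 1e-12)
})

test_that("degenerate observers are rejected", {
  expect_error(flicker_observer(lum_weights = c(0, 0, 1)), "wL \\+ wM")
})

test_that("the flicker task averages three settings per eye", {
  d <- default_display()
  noiseless <- flicker_observer(setting_noise_sd = 0)
  res <- simulate_flicker_task(d, noiseless, seed = 1)
  expect_equal(nrow(res$settings), 6L)
  expect_equal(unname(res$mean), c(0, 0))
  obs <- flicker_observer(setting_noise_sd = 0.01)
  res <- simulate_flicker_task(d, obs, settings_per_eye = 3, seed = 1)
  expect_equal(as.vector(table(res$settings$eye)), c(3L, 3L))
})

test_that("the SE of the mean setting scales as sigma over sqrt(n)", {
  d <- default_display()
  obs <- flicker_observer(setting_noise_sd = 0.01)
  means <- vapply(1:400, function(s) {
    unname(simulate_flicker_task(d, obs, settings_per_eye = 3, seed = s)$mean[1])
  }, numeric(1))
  expect_equal(sd(means), 0.01 / sqrt(3), tolerance = 0.15)
  expect_equal(mean(means), 0, tolerance = 0.001)
})
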