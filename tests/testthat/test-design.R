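test_that("seven runs schedule 35 events of every condition with legal ISIs", {
  designs <- lapply(1:7, function(r) generate_run_design(seed = r))
  ev <- do.call(rbind, lapply(designs, function(d) d$events))
  expect_true(all(table(ev$condition) == 35L))
  expect_setequal(unique(ev$condition), mid_conditions())
  for (d in designs) {
    isi <- diff(d$events$onset) - d$duration
    expect_true(all(isi >= 3 - 1e-9 & isi <= 12 + 1e-9))
    expect_true(all(abs(isi / 1.5 - round(isi / 1.5)) < 1e-9))
    # non-overlapping events that fit the run after dummy discard
    expect_true(all(diff(d$events$onset) >= d$duration))
    expect_lte(max(d$events$onset) + d$duration, d$run_time)
    expect_equal(d$run_time, (114 - 4) * 3)
  }
})

test_that("designs are reproducible under the seed and empty when asked", {
  expect_equal(generate_run_design(seed = 3)$events,
               generate_run_design(seed = 3)$events)
  expect_false(identical(generate_run_design(seed = 3)$events$condition,
                         generate_run_design(seed = 4)$events$condition))
  empty <- generate_run_design(list(repeats_per_condition = 0), seed = 1)
  expect_equal(nrow(empty$events), 0L)
})

test_that("the gamma HRF has the stated lag, spread and mode", {
  k <- hrf_kernel(hrf_model(), dt = 0.005)
  expect_equal(k$k[1], 0)
  expect_equal(max(k$k), 1)
  m1 <- sum(k$t * k$k) / sum(k$k)
  expect_equal(m1, 6.0, tolerance = 1e-3)
  sd1 <- sqrt(sum((k$t - m1)^2 * k$k) / sum(k$k))
  expect_equal(sd1, 3.0, tolerance = 1e-2)
  # gamma mode = (shape - 1) * scale = 4.5 s for lag 6, sd 3
  expect_equal(k$t[which.max(k$k)], 4.5, tolerance = 0.01)
  dog <- hrf_kernel(hrf_model("difference_of_gammas"), dt = 0.005)
  expect_equal(max(dog$k), 1)
  expect_lt(min(dog$k), 0) # undershoot present
})

test_that("the design matrix has eight condition regressors plus intercept", {
  d <- generate_run_design(seed = 1)
  X <- build_design_matrix(d, hrf_model())
  expect_equal(ncol(X), 9L)
  expect_equal(nrow(X), 110L)
  expect_true(all(X[, 1] == 1))
  expect_setequal(colnames(X)[-1], setdiff(mid_conditions(), "blank"))
  expect_equal(attr(X, "excluded"), character(0))
})

test_that("conditions without events are excluded and flagged", {
  d <- generate_run_design(seed = 2)
  d$events <- d$events[d$events$condition != "CD_s", ]
  X <- build_design_matrix(d, hrf_model())
  expect_equal(attr(X, "excluded"), "CD_s")
  expect_false("CD_s" %in% colnames(X))
  expect_equal(ncol(X), 8L)
})

test_that("regressor construction matches a brute-force convolution oracle", {
  d <- generate_run_design(list(repeats_per_condition = 1,
                                conditions = c("A", "blank"),
                                n_volumes = 24), seed = 5)
  hrf <- hrf_model()
  dt <- 0.1
  X <- build_design_matrix(d, hrf, dt = dt)
  kern <- hrf_kernel(hrf, dt = dt)
  grid_t <- seq(0, d$run_time + 1e-9, by = dt)
  box <- as.numeric(grid_t >= d$events$onset[d$events$condition == "A"] - 1e-9 &
                      grid_t < d$events$onset[d$events$condition == "A"] + 3 - 1e-9)
  conv <- numeric(length(grid_t))
  for (i in seq_along(grid_t)) {   # double-loop discrete convolution
    for (j in seq_along(kern$k)) {
      if (i - j + 1 >= 1) conv[i] <- conv[i] + box[i - j + 1] * kern$k[j] * dt
    }
  }
  vol_t <- (seq_len(nrow(X)) - 1) * d$tr
  oracle <- approx(grid_t, conv, xout = vol_t, rule = 2)$y
  expect_equal(unname(X[, "A"]), oracle, tolerance = 1e-9)
  # the regressor peaks a few seconds after onset (between HRF mode and
  # lag + duration), as the boxcar-gamma convolution dictates
  peak_t <- vol_t[which.max(X[, "A"])] - d$events$onset[d$events$condition == "A"]
  expect_gt(peak_t, 4.5 - d$tr)
  expect_lt(peak_t, 6 + 3)
})

test_that("OLS recovers noiseless betas exactly and flags rank deficiency", {
  d <- generate_run_design(seed = 6)
  X <- build_design_matrix(d, hrf_model())
  set.seed(61)
  beta <- c(1.5, rnorm(8))
  y <- as.numeric(X %*% beta)
  fit <- fit_glm(y, X)
  expect_equal(unname(fit$betas), beta, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # pure noise: near-zero betas and variance explained
  yn <- rnorm(nrow(X))
  fn <- fit_glm(yn, X)
  expect_lt(fn$r_squared, 0.25)
  expect_lt(max(abs(fn$betas[-1])), 1.5)
  # adding a constant moves only the intercept
  f2 <- fit_glm(y + 10, X)
  expect_equal(unname(f2$betas[1]), beta[1] + 10, tolerance = 1e-9)
  expect_equal(unname(f2$betas[-1]), beta[-1], tolerance = 1e-9)
  expect_error(fit_glm(y, cbind(X, X[, 2])), "rank deficient")
  expect_error(fit_glm(y[-1], X), "match")
})

test_that("OLS betas are unbiased under AR(1) noise", {
  d <- generate_run_design(seed = 7)
  X <- build_design_matrix(d, hrf_model())
  beta <- c(0, rep(c(1, 0.4), 4))
  mu <- as.numeric(X %*% beta)
  set.seed(62)
  err <- replicate(200, {
    noise <- as.numeric(filter(rnorm(length(mu), 0, 0.5), 0.4,
                               method = "recursive"))
    fit_glm(mu + noise, X)$betas - beta
  })
  bias <- rowMeans(err)
  mc_se <- apply(err, 1, sd) / sqrt(ncol(err))
  expect_true(all(abs(bias) < 4 * mc_se + 1e-3))
})

test_that("the QC filter drops low-fit subjects (17 -> 11 style)", {
  bt <- expand.grid(subject = 1:17, roi = c("V1", "hMT"),
                    KEEP.OUT.ATTRS = FALSE)
  bt$r_squared <- 0.30
  bt$r_squared[bt$subject %in% 1:6] <- 0.02 # engineered low-fit subjects
  kept <- qc_filter(bt, 0.05)
  expect_equal(length(unique(kept$subject)), 11L)
  expect_equal(attr(kept, "dropped"), as.character(1:6))
  expect_equal(nrow(qc_filter(bt, 0)), nrow(bt))
  all_good <- bt; all_good$r_squared <- 0.5
  expect_equal(nrow(qc_filter(all_good, 0.05)), nrow(bt))
  expect_error(qc_filter(bt, 1.5), "min_r_squared")
})
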