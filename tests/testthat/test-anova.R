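test_that("paired t matches hand computation and handles edge cases", {
  a <- c(1, 2, 3, 4); b <- c(0, 0, 0, 0)
  res <- paired_t(a, b)
  expect_equal(res$t, mean(a) / (sd(a) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(res$t), 3), tolerance = 1e-12)
  # identical vectors
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # sign flip
  set.seed(51)
  x <- rnorm(6); y <- rnorm(6)
  expect_equal(paired_t(x, y)$t, -paired_t(y, x)$t)
  # constant nonzero difference: flagged infinite, not silent
  expect_warning(inf <- paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_equal(inf$t, Inf)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("rm_table validates completeness and balance", {
  d <- expand.grid(subject = 1:4, cue = c("CD", "IOVD"), chroma = c("a", "s"))
  d$value <- rnorm(16)
  expect_s3_class(rm_table(d), "rm_table")
  expect_error(rm_table(d[-1, ]), "complete and balanced")
  expect_error(rm_table(d[d$subject == 1, ]), "2 subjects")
})

test_that("2x2 interaction F equals the squared paired t on difference-of-differences", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    d <- expand.grid(subject = seq_len(n), cue = c("CD", "IOVD"),
                     chroma = c("ach", "s"))
    d$value <- rnorm(nrow(d)) + ifelse(d$cue == "CD" & d$chroma == "s", 1.5, 0)
    an <- rm_anova(rm_table(d))
    cell <- function(cue, chr) {
      s <- d[d$cue == cue & d$chroma == chr, ]
      s$value[order(s$subject)]
    }
    dod <- (cell("CD", "ach") - cell("CD", "s")) -
      (cell("IOVD", "ach") - cell("IOVD", "s"))
    tt <- paired_t(dod, rep(0, n))
    i <- an[an$effect == "cue:chroma", ]
    expect_equal(i$F, tt$t^2, tolerance = 1e-9)
    expect_equal(i$df1, 1); expect_equal(i$df2, n - 1)
    expect_equal(i$p, tt$p, tolerance = 1e-9)
    expect_equal(i$gg_epsilon, 1) # two levels: sphericity is vacuous
  }
})

test_that("rm_anova effects are invariant to subject offsets and affine scaling", {
  set.seed(53)
  d <- expand.grid(subject = 1:7, cue = c("CD", "IOVD"), chroma = c("ach", "s"))
  d$value <- rnorm(28) + ifelse(d$chroma == "s", 1, 0)
  a0 <- rm_anova(rm_table(d))
  d2 <- d
  d2$value <- d$value + rep(rnorm(7, 0, 10), 4) # per-subject constants
  a2 <- rm_anova(rm_table(d2))
  expect_equal(a2$F, a0$F, tolerance = 1e-9)
  d3 <- d
  d3$value <- 3.7 * d$value - 12 # affine rescale
  a3 <- rm_anova(rm_table(d3))
  expect_equal(a3$partial_eta_sq, a0$partial_eta_sq, tolerance = 1e-9)
  expect_true(all(a0$p >= 0 & a0$p <= 1))
  expect_true(all(a0$partial_eta_sq >= 0 & a0$partial_eta_sq <= 1))
})

test_that("constant tables give zero F throughout", {
  d <- expand.grid(subject = 1:5, cue = c("CD", "IOVD"), chroma = c("a", "s"))
  d$value <- 7
  an <- rm_anova(rm_table(d))
  expect_true(all(an$F == 0))
  expect_true(all(an$p == 1))
})

test_that("Greenhouse-Geisser epsilon matches the covariance-based oracle", {
  # one 4-level within factor; oracle computes epsilon from the covariance
  # of orthonormal contrast scores
  set.seed(54)
  n <- 8
  d <- expand.grid(subject = 1:n, roi = paste0("R", 1:4))
  d$value <- rnorm(nrow(d)) + rep(c(0, 0.5, 1, 0.2), each = n) +
    rep(rnorm(n), 4) * 1.5
  an <- rm_anova(rm_table(d))
  Y <- matrix(d$value[order(d$roi, d$subject)], nrow = n)
  C <- contr.helmert(4)
  C <- qr.Q(qr(C)) # orthonormal contrasts
  S <- cov(Y %*% C)
  eps_oracle <- sum(diag(S))^2 / (ncol(S) * sum(S^2))
  expect_equal(an$gg_epsilon[an$effect == "roi"], eps_oracle, tolerance = 1e-9)
  # GG-adjusted df shrink by epsilon
  expect_equal(an$df1[an$effect == "roi"], 3 * eps_oracle, tolerance = 1e-9)
})

test_that("three-factor tables (roi x cue x chromaticity) are supported", {
  set.seed(55)
  d <- expand.grid(subject = 1:6, roi = c("V1", "hMT", "V3A/B"),
                   cue = c("CD", "IOVD"), chroma = c("ach", "s"))
  d$value <- rnorm(nrow(d)) +
    ifelse((d$cue == "CD") == (d$chroma == "ach"), 0.8, 0)
  an <- rm_anova(rm_table(d))
  expect_setequal(an$effect,
                  c("roi", "cue", "chroma", "roi:cue", "roi:chroma",
                    "cue:chroma", "roi:cue:chroma"))
  # the injected cue-by-chromaticity interaction dominates
  expect_gt(an$F[an$effect == "cue:chroma"], an$F[an$effect == "cue"])
  expect_true(all(is.finite(an$F)))
})

test_that("delta_beta_table subtracts each control from its MID condition", {
  base <- expand.grid(subject = 1:3, roi = c("V1", "hMT"),
                      condition = setdiff(mid_conditions(), "blank"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$beta <- 0.7
  base$beta[base$condition == "CD_ach"] <- 1.2
  dbt <- delta_beta_table(base)
  expect_s3_class(dbt, "rm_table")
  expect_equal(nrow(dbt), 3 * 2 * 4)
  cd_ach <- dbt$value[dbt$cue == "CD" & dbt$chromaticity == "ach"]
  expect_true(all(cd_ach == 0.5))
  expect_true(all(dbt$value[dbt$cue == "IOVD"] == 0))
  # linearity: scaling all betas scales all deltas
  b2 <- base; b2$beta <- 3 * b2$beta
  expect_equal(delta_beta_table(b2)$value, 3 * dbt$value)
  expect_error(delta_beta_table(base[base$condition != "IOVD_s_control", ]),
               "missing conditions")
})

test_that("ROI grouping averages members per subject and preserves means", {
  d <- expand.grid(subject = 1:4, roi = unname(unlist(roi_groups())),
                   cue = c("CD", "IOVD"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  set.seed(56)
  d$value <- rnorm(nrow(d))
  g <- group_rois(rm_table(d))
  expect_setequal(unique(as.character(g$roi)),
                  c("early", "dorsal", "ventral", "motion"))
  # early group = mean of V1, V2, V3
  v <- d[d$subject == 2 & d$cue == "CD" & d$roi %in% c("V1", "V2", "V3"), ]
  expect_equal(g$value[g$subject == 2 & g$cue == "CD" & g$roi == "early"],
               mean(v$value))
  # single-member groups are the identity
  solo <- group_rois(rm_table(d), lapply(unname(unlist(roi_groups())), identity) |>
                       setNames(unname(unlist(roi_groups()))) |> as.list())
  m <- merge(as.data.frame(solo), as.data.frame(d),
             by = c("subject", "roi", "cue"))
  expect_equal(m$value.x, m$value.y)
  # equally sized groups preserve the grand mean
  eq <- group_rois(rm_table(d), list(g1 = c("V1", "V2"), g2 = c("V3", "V4"),
                                     g3 = c("V3A/B", "IPS-0"),
                                     g4 = c("LO-1", "LO-2"),
                                     g5 = c("hMT", "hMST")))
  expect_equal(mean(eq$value), mean(d$value), tolerance = 1e-12)
  expect_error(group_rois(rm_table(d), list(early = "V1")), "absent")
  expect_error(group_rois(rm_table(d),
                          c(roi_groups(), list(dup = "V1"))), "more than one")
})
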