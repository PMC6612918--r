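#' Paired-samples t test
#'
#' Classical paired t on the element-wise differences, `df = n - 1`,
#' two-sided p. Zero-variance differences are handled explicitly rather than
#' erroring silently: identical vectors give `t = 0, p = 1`; a constant
#' nonzero difference gives an infinite t with a warning.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must have equal length >= 2", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    }
    warning("zero variance of differences: t is infinite")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Repeated-measures table
#'
#' Validates a complete, balanced long-format within-subject table: one
#' `subject` column, one `value` column, and one column per within-subject
#' factor (every subject must contribute exactly one value per factor-level
#' cell).
#'
#' @param data A data.frame with columns `subject`, `value`, and the factor
#'   columns.
#' @param factors Character vector naming the within-subject factor columns;
#'   defaults to every column other than `subject` and `value`.
#' @return The validated data.frame with class `rm_table`.
#' @export
rm_table <- function(data, factors = NULL) {
  stopifnot(is.data.frame(data), all(c("subject", "value") %in% names(data)))
  if (is.null(factors)) factors <- setdiff(names(data), c("subject", "value"))
  if (!length(factors) || length(factors) > 3) {
    stop("between 1 and 3 within-subject factors are supported", call. = FALSE)
  }
  if (length(unique(data$subject)) < 2) {
    stop("at least 2 subjects are required", call. = FALSE)
  }
  counts <- table(data[c("subject", factors)])
  if (any(counts != 1)) {
    stop("table must be complete and balanced: exactly one value per subject per cell",
         call. = FALSE)
  }
  attr(data, "factors") <- factors
  class(data) <- c("rm_table", "data.frame")
  data
}

#' Within-subject (repeated-measures) factorial ANOVA
#'
#' Univariate repeated-measures ANOVA for 1--3 within-subject factors, with
#' the partial effect size `partial_eta_sq = SS_effect / (SS_effect +
#' SS_error)` and Greenhouse--Geisser sphericity correction applied to the
#' degrees of freedom of any effect involving a factor with more than two
#' levels (sphericity is vacuous at two levels, where `gg_epsilon = 1`
#' exactly). Sums of squares and epsilon estimates are obtained from a
#' multivariate linear model via [car::Anova()].
#'
#' @param table An [rm_table()] (or a data.frame accepted by it).
#' @param correction `"GG"` (default) applies Greenhouse--Geisser-adjusted
#'   p-values where applicable; `"none"` reports unadjusted p-values.
#' @return A data.frame with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`, `gg_epsilon` (NA where not estimable).
#' @export
#' @examples
#' d <- expand.grid(subject = 1:6, cue = c("CD", "IOVD"),
#'                  chroma = c("ach", "s"))
#' d$value <- rnorm(nrow(d))
#' rm_anova(rm_table(d))
rm_anova <- function(table, correction = c("GG", "none")) {
  correction <- match.arg(correction)
  if (!inherits(table, "rm_table")) table <- rm_table(table)
  factors <- attr(table, "factors")
  for (f in factors) table[[f]] <- factor(table[[f]])
  table$subject <- factor(table$subject)

  idata <- do.call(expand.grid, lapply(table[factors], levels))
  names(idata) <- factors
  ## wide response matrix: subjects x cells, cells ordered as idata rows
  cell_key <- interaction(table[factors], lex.order = FALSE)
  idata_key <- interaction(idata, lex.order = FALSE)
  Y <- matrix(NA_real_, nrow = nlevels(table$subject), ncol = nrow(idata))
  si <- as.integer(table$subject)
  ci <- match(cell_key, idata_key)
  Y[cbind(si, ci)] <- table$value

  effects <- attr(stats::terms(stats::as.formula(
    paste("~", paste(factors, collapse = "*")))), "term.labels")

  ## degenerate all-equal table: every effect has zero sum of squares
  if (stats::var(as.vector(Y)) < 1e-24) {
    return(data.frame(effect = effects, F = 0,
                      df1 = NA_real_, df2 = NA_real_, p = 1,
                      partial_eta_sq = 0, gg_epsilon = NA_real_))
  }

  mod <- stats::lm(Y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(factors, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  ## the Huynh-Feldt epsilon is computed by car but not used here; its
  ## "HF eps > 1" note is expected and silenced
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  ut <- s$univariate.tests
  adj <- s$pval.adjustments

  out <- lapply(effects, function(eff) {
    ss <- ut[eff, "Sum Sq"]; sse <- ut[eff, "Error SS"]
    df1 <- ut[eff, "num Df"]; df2 <- ut[eff, "den Df"]
    Fv <- ut[eff, "F value"]; p <- ut[eff, "Pr(>F)"]
    if (!is.finite(Fv) && ss < 1e-20) { Fv <- 0; p <- 1 }
    eps <- NA_real_
    if (df1 > 1) {
      if (!is.null(adj) && eff %in% rownames(adj)) {
        eps <- adj[eff, "GG eps"]
        if (correction == "GG") {
          p <- adj[eff, "Pr(>F[GG])"]
          df1 <- df1 * eps
          df2 <- df2 * eps
        }
      }
    } else {
      eps <- 1
    }
    data.frame(effect = eff, F = Fv, df1 = df1, df2 = df2, p = p,
               partial_eta_sq = if (ss + sse > 0) ss / (ss + sse) else 0,
               gg_epsilon = eps)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' MID-minus-control response differences
#'
#' Converts a table of per-condition GLM response amplitudes into the four
#' differential responses: for each cue type (CD, IOVD) and chromaticity
#' (achromatic, S-cone), the fitted response to the MID stimulus minus the
#' response to its matched control stimulus.
#'
#' @param betas A data.frame with columns `subject`, `roi`, `condition`,
#'   `beta`, where `condition` spans the 8 non-blank stimulus conditions
#'   (`CD_ach`, `CD_ach_control`, `CD_s`, `CD_s_control`, `IOVD_ach`,
#'   `IOVD_ach_control`, `IOVD_s`, `IOVD_s_control`).
#' @return An [rm_table()] with factor columns `roi`, `cue`, `chromaticity`
#'   and `value` = MID beta minus control beta.
#' @export
delta_beta_table <- function(betas) {
  stopifnot(all(c("subject", "roi", "condition", "beta") %in% names(betas)))
  mids <- c("CD_ach", "CD_s", "IOVD_ach", "IOVD_s")
  need <- c(mids, paste0(mids, "_control"))
  missing <- setdiff(need, unique(betas$condition))
  if (length(missing)) {
    stop("missing conditions: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- function(cond) betas[betas$condition == cond,
                              c("subject", "roi", "beta")]
  out <- lapply(mids, function(cond) {
    m <- key(cond); ctl <- key(paste0(cond, "_control"))
    merged <- merge(m, ctl, by = c("subject", "roi"),
                    suffixes = c("_mid", "_control"))
    if (nrow(merged) != nrow(m)) {
      stop("missing control cells for condition ", cond, call. = FALSE)
    }
    data.frame(
      subject = merged$subject, roi = merged$roi,
      cue = sub("_.*$", "", cond),
      chromaticity = sub("^[^_]*_", "", cond),
      value = merged$beta_mid - merged$beta_control
    )
  })
  out <- do.call(rbind, out)
  rm_table(out, factors = c("roi", "cue", "chromaticity"))
}

#' Default grouping of visual-area ROIs
#'
#' Early visual areas (V1, V2, V3), dorsal areas (V3A/B, IPS-0), ventral
#' areas (V4, LO-1, LO-2), and motion areas (hMT, hMST).
#'
#' @return A named list mapping group name to member ROI labels.
#' @export
roi_groups <- function() {
  list(
    early = c("V1", "V2", "V3"),
    dorsal = c("V3A/B", "IPS-0"),
    ventral = c("V4", "LO-1", "LO-2"),
    motion = c("hMT", "hMST")
  )
}

#' Aggregate ROIs into grouped areas
#'
#' Replaces the `roi` factor of a repeated-measures table by group labels,
#' averaging each subject's member-ROI values within every remaining cell.
#'
#' @param table An [rm_table()] whose factors include `roi`.
#' @param grouping Named list mapping group labels to ROI labels; every ROI in
#'   the table must appear in exactly one group.
#' @return An [rm_table()] with `roi` replaced by the group labels.
#' @export
group_rois <- function(table, grouping = roi_groups()) {
  factors <- attr(table, "factors") %||% setdiff(names(table), c("subject", "value"))
  if (!"roi" %in% factors) stop("table has no 'roi' factor", call. = FALSE)
  map <- unlist(lapply(names(grouping), function(g) {
    stats::setNames(rep(g, length(grouping[[g]])), grouping[[g]])
  }))
  if (anyDuplicated(names(map))) {
    stop("an ROI appears in more than one group", call. = FALSE)
  }
  rois <- unique(as.character(table$roi))
  absent <- setdiff(rois, names(map))
  if (length(absent)) {
    stop("ROIs absent from the grouping: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(table)
  df$roi <- unname(map[as.character(df$roi)])
  agg <- stats::aggregate(df["value"],
                          by = df[c("subject", factors)], FUN = mean)
  rm_table(agg, factors = factors)
}
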