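#' Time-series trace
#'
#' Lightweight container for uniformly sampled validation traces (disparity
#' in arcmin or interocular velocity difference in degrees/s).
#'
#' @param times Sample times in seconds, strictly increasing and uniformly
#'   spaced.
#' @param values Trace values.
#' @param label Optional label describing the quantity and units.
#' @return An object of class `ts_trace`.
#' @export
ts_trace <- function(times, values, label = "") {
  stopifnot(length(times) == length(values))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
      stop("times must be strictly increasing and uniformly spaced", call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "ts_trace")
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("<ts_trace> %s: %d samples, range [%.3g, %.3g]\n",
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Least-squares sinusoid fit
#'
#' Fits `a * sin(2 pi f t) + b * cos(2 pi f t) + c` by linear least squares at
#' each frequency of a search grid, then refines the best frequency by local
#' 1-D optimization of the residual sum of squares. Recovers noiseless
#' sinusoids exactly (r-squared = 1 up to numerical precision).
#'
#' @param trace A [ts_trace()] (or a list with `times` and `values`).
#' @param freq_grid Frequencies to scan, Hz. The default 0.2--3 Hz grid in
#'   0.01 Hz steps brackets both stimulus oscillation frequencies.
#' @return A list with `amplitude`, `frequency` (Hz; `NA` with
#'   `constant = TRUE` for constant input), `phase` (radians), `offset`, and
#'   `r_squared`.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1 / 120)
#' fit_sinusoid(ts_trace(t, 24 * sin(2 * pi * 1.4 * t)))[c("amplitude", "frequency")]
fit_sinusoid <- function(trace, freq_grid = seq(0.2, 3, by = 0.01)) {
  t <- trace$times
  y <- trace$values
  if (length(t) < 4) stop("need at least 4 samples", call. = FALSE)
  span <- diff(range(t))
  if (span * max(freq_grid) < 1) {
    stop("trace must cover at least one full cycle of the searched frequencies",
         call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-24) {
    return(list(amplitude = 0, frequency = NA_real_, phase = NA_real_,
                offset = mean(y), r_squared = NA_real_, constant = TRUE))
  }
  rss_at <- function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss <- vapply(freq_grid, rss_at, numeric(1))
  i <- which.min(rss)
  lo <- freq_grid[max(1L, i - 1L)]
  hi <- freq_grid[min(length(freq_grid), i + 1L)]
  f <- if (lo < hi) stats::optimize(rss_at, c(lo, hi), tol = 1e-10)$minimum else lo
  if (rss_at(f) > rss[i]) f <- freq_grid[i]
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
  fit <- stats::lm.fit(X, y)
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  list(
    amplitude = sqrt(a^2 + b^2),
    frequency = f,
    phase = atan2(b, a),
    offset = unname(fit$coefficients[3]),
    r_squared = 1 - sum(fit$residuals^2) / tss,
    constant = FALSE
  )
}
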