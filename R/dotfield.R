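## Core rejection sampler: place `n` dot centers inside the aperture annulus
## (optionally restricted to stripe bands), at least `min_separation` apart
## from each other and from `existing` dots, with optional extra pairwise
## margins and a trajectory-containment check for moving dots.
##
## `group` labels the motion group of each new dot; `closure` is the extra
## center distance required between dots of *different* groups (worst-case
## closing displacement over a dot lifetime, so that separation holds on
## every frame of a dot's life, not just at spawn). `future_dx` maps a group
## label to the vector of cumulative horizontal offsets the dot will take on
## over its lifetime; every offset position must stay inside the annulus.
##
## Assumes the RNG has already been seeded by the caller.
place_dots <- function(n, params,
                       group = rep("static", n),
                       existing_xy = NULL, existing_group = character(0),
                       closure = 0,
                       future_dx = NULL,
                       bands = NULL,
                       max_attempts = 10000) {
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      group = character(0), stringsAsFactors = FALSE))
  }
  inner <- params$aperture_inner
  outer <- params$aperture_outer
  sep <- params$min_separation

  acc_x <- numeric(0); acc_y <- numeric(0); acc_g <- character(0)
  if (!is.null(existing_xy) && nrow(existing_xy) > 0) {
    acc_x <- existing_xy[, 1]; acc_y <- existing_xy[, 2]
    acc_g <- existing_group
  }
  n_existing <- length(acc_x)

  out_x <- numeric(n); out_y <- numeric(n)
  for (i in seq_len(n)) {
    gi <- group[i]
    dxs <- if (!is.null(future_dx)) future_dx[[gi]] else 0
    placed <- FALSE
    attempts <- 0L
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "could not place dot %d of %d after %d attempts: density too high for the aperture/separation constraints",
          i, n, max_attempts), call. = FALSE)
      }
      pt <- sample_annulus(1L, params, bands = bands)
      x0 <- pt[1, 1]; y0 <- pt[1, 2]
      ## trajectory containment: every future position inside the annulus
      r2 <- (x0 + dxs)^2 + y0^2
      if (any(r2 < inner^2) || any(r2 > outer^2)) next
      if (length(acc_x)) {
        d <- sqrt((acc_x - x0)^2 + (acc_y - y0)^2)
        req <- sep + ifelse(acc_g != gi, closure, 0)
        if (any(d < req)) next
      }
      acc_x <- c(acc_x, x0); acc_y <- c(acc_y, y0); acc_g <- c(acc_g, gi)
      out_x[i] <- x0; out_y[i] <- y0
      placed <- TRUE
    }
  }
  data.frame(x = out_x, y = out_y, group = group, stringsAsFactors = FALSE)
}

#' Generate a single random-dot frame
#'
#' Places `round(density * area)` dots uniformly inside the annular aperture,
#' subject to the minimum center-separation constraint, and assigns each dot a
#' contrast polarity of +1 or -1 with probability 0.5. Placement uses
#' rejection sampling with a bounded number of attempts per dot; an error is
#' raised when the requested density cannot be packed at the requested
#' separation.
#'
#' @param params A [stimulus_params()] object.
#' @param time Nominal frame time in seconds (stored in the output).
#' @param seed Integer seed; the frame is a pure function of
#'   `(params, time, seed)`.
#' @param eye `"left"` or `"right"` label stored in the output.
#' @return A `data.frame` with columns `eye`, `time`, `id`, `x`, `y`
#'   (degrees), `polarity`, `role`, `age`, `stripe`.
#' @export
#' @examples
#' f <- generate_dot_field(stimulus_params(), seed = 1)
#' nrow(f) # 78
generate_dot_field <- function(params, time = 0, seed = 1, eye = "left") {
  validate_stimulus_params(params)
  n <- dot_budget(params)
  with_seed(mix_seed(seed, round(time * params$frame_rate), 7L), {
    pos <- place_dots(n, params)
    pol <- sample(c(-1L, 1L), n, replace = TRUE)
    data.frame(
      eye = rep(eye, n), time = rep(time, n), id = seq_len(n),
      x = pos$x, y = pos$y, polarity = pol,
      role = rep("signal", n), age = rep(1L, n),
      stripe = rep(NA_integer_, n),
      stringsAsFactors = FALSE
    )
  })
}

## Minimum pairwise center distance within one frame (Inf for < 2 dots).
min_pairwise_distance <- function(x, y) {
  if (length(x) < 2) return(Inf)
  min(stats::dist(cbind(x, y)))
}
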