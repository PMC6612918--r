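#' @keywords internal
"_PACKAGE"

## Deterministic seed mixing for independent substreams.
##
## All stochastic operations in the package derive their RNG state from an
## integer seed plus a small counter vector (frame number, run, staircase,
## trial, ...).  Mixing is done in double precision with intermediate values
## kept below 2^53 so the arithmetic is exact, and the result is reduced into
## the positive 32-bit range accepted by set.seed().
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% m
    h <- (h * 69621 + 11) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

## Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
## state afterwards so package functions do not disturb the user's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
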