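## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

## Truncated-normal draws by rejection with an inverse-CDF fallback for
## far-tail truncation; exact for sd = 0.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  deg <- sd == 0
  out[deg] <- pmax(mean[deg], lower)
  bad <- which(out < lower & !deg)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lower]
    tries <- tries + 1L
  }
  if (length(bad)) {
    plo <- stats::pnorm(lower, mean[bad], sd[bad])
    out[bad] <- stats::qnorm(plo + stats::runif(length(bad)) * (1 - plo),
                             mean[bad], sd[bad])
  }
  out
}

## CDF of the lower-truncated normal (used for distributional tests).
ptruncnorm_lower <- function(q, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  pmax(0, (stats::pnorm(q, mean, sd) - plo) / (1 - plo))
}

## Sample standard deviation that returns 0 (not NA) for length-1 input is
## never wanted here; callers require n >= 2 explicitly.
sample_sd <- function(x) stats::sd(x)

## Deterministic child seed derived from a master seed; kept < 2^31.
child_seed <- function(seed, k) {
  ## double arithmetic stays exact well past 2^31 * 1e4; result fits an int
  as.integer((as.numeric(seed) + 747796405 * as.numeric(k)) %% 2147483647)
}
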