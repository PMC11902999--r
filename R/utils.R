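# Internal helpers: seed splitting, rounding and formatting conventions.

# Deterministic child seeds from a single run seed: all randomness in a run
# flows from one seed through this documented rule. Kept below 2^31 - 1.
childSeed <- function(seed, k) {
  s <- (as.numeric(seed) + 1664525 * as.numeric(k)) %% 2147483647
  as.integer(s) + 1L
}

# run expr under a local RNG state so library code never perturbs the
# caller's random stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# round half away from zero (reporting convention for integer percents;
# base round() rounds half to even)
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a mediated proportion as a signed integer percent
#'
#' Rounds half away from zero to the nearest integer percent, the convention
#' used in the mediation report (for example 0.0484 prints as `"5%"`).
#'
#' @param proportion proportion on the raw (not percent) scale.
#' @return character label such as `"5%"` or `"-7%"`.
#' @export
formatPercent <- function(proportion) {
  sprintf("%d%%", as.integer(roundHalfAway(100 * proportion)))
}

# two-sided normal p-value for an estimate/SE pair
zPval <- function(beta, se) 2 * pnorm(-abs(beta / se))

zCrit <- function(level) qnorm(1 - (1 - level) / 2)
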