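# Internal helpers shared across modules.

# 1 mmHg in Pa (conventional conversion factor).
MMHG_TO_PA <- 133.322

#' Round half away from zero
#'
#' Display rounding used in report tables: 0.5 always rounds up, unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Clip to the half-open unit interval (0, 1]; physiological pressure ratios
# cannot be exactly 0 or negative.
clip_unit <- function(x, eps = 1e-6) {
  pmin(pmax(x, eps), 1)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctifr_invalid_parameter", "error")))
}

stop_physics <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctifr_degenerate_physics", "error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a stream of independent child seeds from one master seed; the first
# k children do not depend on how many are requested.
child_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
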