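#' Round half away from zero
#'
#' Commercial rounding: 0.5 always rounds up (for non-negative input), unlike
#' [base::round()]'s round-half-even. All count estimates in the package use
#' this rule.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @return integer vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, 2.6))
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Run `expr` under a deterministic RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generation never perturbs user code.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_ovocount <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ovocount_error")))
}

# scalar integer check with range
check_scalar_int <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min || x > max) {
    stop_ovocount(
      sprintf("`%s` must be a single integer in [%s, %s], got %s",
              name, format(min), format(max), deparse(substitute(x))),
      "ovocount_parameter_error"
    )
  }
  as.integer(x)
}
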