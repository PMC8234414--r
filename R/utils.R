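# Internal helpers shared across modules.

# micrometre -> metre
.UM <- 1e-6

# Classed error so callers can distinguish package failures programmatically.
cf_stop <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "clotforce_error", "error", "condition")))
}

.check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                                 class = "clotforce_invalid_input") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cf_stop(sprintf("`%s` must be a single finite number", name), class)
  if (positive && x <= 0)
    cf_stop(sprintf("`%s` must be strictly positive", name), class)
  if (nonneg && x < 0)
    cf_stop(sprintf("`%s` must be non-negative", name), class)
  invisible(x)
}

.check_numeric_vector <- function(x, name, class = "clotforce_invalid_input") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    cf_stop(sprintf("`%s` must be a finite numeric vector", name), class)
  invisible(x)
}

# set.seed only when a seed is supplied, leaving the caller's RNG choice alone
# otherwise.
.with_seed <- function(seed) {
  if (!is.null(seed)) {
    .check_scalar_number(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
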