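# Internal helpers shared across modules.

# Classed error constructors so callers can distinguish schema problems
# (wrong columns), integrity problems (bad values/keys), and domain errors
# (invalid numeric input) without string matching.
psel_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "preysel_error"), call = call))
}

psel_schema_error    <- function(msg) psel_stop(msg, "preysel_schema_error")
psel_integrity_error <- function(msg) psel_stop(msg, "preysel_integrity_error")
psel_domain_error    <- function(msg) psel_stop(msg, "preysel_domain_error")

# Stopifnot-style numeric checks used by the estimator front doors.
check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    psel_domain_error(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    psel_domain_error(sprintf("`%s` must be positive", name))
  invisible(x)
}

# Full-precision numeric formatting for CSV round trips: %.17g is the
# shortest printf format guaranteed to round-trip IEEE doubles.
format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  } else {
    x
  }
}

# set.seed() only when the caller supplied one; NULL leaves the RNG stream
# untouched so callers can manage seeding globally.
with_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      psel_domain_error("`seed` must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
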