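# Internal validation and error helpers. All user-facing errors carry a
# subclass so callers (and the CLI) can distinguish bad parameters from
# geometry failures.

abort_param <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("cristamorph_parameter_error", "cristamorph_error"))
}

abort_geometry <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("cristamorph_geometry_error", "cristamorph_error"))
}

abort_support <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("cristamorph_support_error", "cristamorph_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_param(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper, if (strict_upper) ")" else "]"
    )
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower) {
    abort_param("`%s` must be an integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_param("`seed` must be a single finite number")
  }
  invisible(as.integer(seed %% .Machine$integer.max))
}

# Deterministic child seed derivation; keeps values inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587)
}
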