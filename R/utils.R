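# Internal argument checks shared across modules.

check_fraction <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1] (got %s)", name,
                 paste(signif(x[x < 0 | x > 1], 4), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  invisible(x)
}

# Offset a base seed, keeping the result a valid 32-bit R integer.
offset_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1))
}
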