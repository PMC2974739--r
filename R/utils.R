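# Typed conditions used across the package. Every user-visible failure carries
# a subclass of "biionic_error" so callers (and tests) can branch on the cause.

abort_invalid <- function(message, ...) {
  abort(message, class = c("biionic_invalid_input", "biionic_error"), ...)
}

abort_config <- function(message, ...) {
  abort(message, class = c("biionic_config_error", "biionic_error"), ...)
}

abort_format <- function(message, ...) {
  abort(message, class = c("biionic_format_error", "biionic_error"), ...)
}

abort_ordering <- function(message, ...) {
  abort(message, class = c("biionic_ordering_error", "biionic_error"), ...)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort_invalid(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (non_negative && x < 0) {
    abort_invalid(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) < 1L) {
    abort_invalid(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (finite && any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must contain only finite values.", name))
  }
  invisible(x)
}

# Integer seed derivation for hierarchical reproducibility: one root seed,
# per-cell and per-sweep children. Kept below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, cell = 0L, sweep = 0L) {
  as.integer((as.double(seed) * 1009 + cell * 7919 + sweep * 104729) %%
               2147483647)
}
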