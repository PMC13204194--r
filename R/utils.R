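# Internal argument checks shared across modules.

assert_scalar_num <- function(x, name, finite = TRUE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
                 class = "mircargo_invalid_parameter")
  }
  if (positive && x <= 0) {
    rlang::abort(sprintf("`%s` must be > 0.", name),
                 class = "mircargo_invalid_parameter")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    rlang::abort(sprintf("`%s` must be an integer >= %d.", name, min),
                 class = "mircargo_invalid_parameter")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  assert_scalar_num(x, name)
  if (x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must lie in [0, 1].", name),
                 class = "mircargo_invalid_parameter")
  }
  invisible(x)
}

assert_cols <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("`%s` is missing column(s): %s.", name,
                         paste(miss, collapse = ", ")),
                 class = "mircargo_invalid_input")
  }
  invisible(df)
}

# Deterministic per-stage seed derived from a master seed; kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * offset) %% 2147483647)
}
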