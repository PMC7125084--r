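# Internal helpers shared across modules.

stop_invalid <- function(msg, class = "rhizo_invalid_argument") {
  abort(msg, class = c(class, "rhizo_error"))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(sprintf(
      "`%s` is missing column(s): %s.", name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Run `expr` under `seed` when given, without disturbing the caller's RNG.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
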