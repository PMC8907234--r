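# internal input checks shared across modules

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (isTRUE(x < lower) || isTRUE(x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  if (integerish && isTRUE(abs(x - round(x)) > 1e-8)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, code) {
  check_number(seed, "seed", integerish = TRUE)
  withr::with_seed(as.integer(seed), code)
}
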