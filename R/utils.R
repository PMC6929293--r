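# internal helpers shared across modules

# Run `code` under a fixed RNG seed when `seed` is given, otherwise use the
# current RNG stream. All user-facing stochastic functions funnel through this
# so a pipeline run is bit-reproducible from one integer.
with_seed_or_stream <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministically derive a child seed from a parent seed and a stage label,
# keeping the result a valid 32-bit integer. Keeps pipeline stages individually
# reproducible while one global seed drives the whole run. The label enters
# through a polynomial rolling hash so that similar labels ("rep18"/"rep64")
# cannot collide the way a positional character sum would.
child_seed <- function(seed, label) {
  if (is.null(seed)) {
    return(NULL)
  }
  m <- 2147483647
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer((h * 48271 + 1) %% m)
}

# Validate a scalar is a single non-missing number.
assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
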