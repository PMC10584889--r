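# internal helpers shared across modules

# scalar checks --------------------------------------------------------------

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g)", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_seed <- function(seed) {
  if (is.null(seed)) abort("`seed` is mandatory: no implicit entropy")
  assert_count(seed, "seed", min = 0L)
}

# column presence on data frames
assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# derive a stream of sub-seeds from one master seed, staying within 32-bit ints
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000003L * seq_len(n)) %% .Machine$integer.max
}

pc_cols <- function(k) paste0("PC", seq_len(k))

# DNA complement used for palindromic-variant detection
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(BASE_COMPLEMENT[a1] == a2)
}
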