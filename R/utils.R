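# Internal helpers: argument checking and seed derivation.

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]%s (got %s).",
                  name, format(lower), format(upper),
                  if (strict_lower) " with the lower bound excluded" else "",
                  format(x)))
  }
  invisible(x)
}

check_fraction <- function(x, name) check_scalar_number(x, name, 0, 1)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Deterministic sub-seed so independent stages of one run never share a
# random stream; kept below 2^31 - 1 for R's 32-bit integer seeds.
derive_seed <- function(seed, offset) {
  seed <- check_count(seed, "seed", min = 0L)
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}

# id column used by cohort-level functions: `sample` for patient cohorts,
# `line` for cell-line panels.
id_column <- function(data) {
  if ("sample" %in% names(data)) return("sample")
  if ("line" %in% names(data)) return("line")
  abort("Expected an identifier column named `sample` or `line`.")
}
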