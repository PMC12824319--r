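# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb ambient randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stopf("'%s' = %g violates constraint %s%g, %g%s", name, x,
          if (strict) "(" else "[", lower, upper, if (strict) ")" else "]")
  invisible(x)
}

# Pixel-center coordinate grids in micrometres, image convention:
# origin at the top-left corner, x along columns, y along rows (y increases
# downward). Pixel (i, j) has its center at ((j - 0.5) px, (i - 0.5) px).
pixel_grid <- function(n_row, n_col, pixel_size) {
  list(x = ((seq_len(n_col) - 0.5) * pixel_size),
       y = ((seq_len(n_row) - 0.5) * pixel_size))
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}
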