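# Independent oracles used by the tests. These re-derive expected values by
# brute force or closed form, separately from the implementation they check.

# Finite-difference oracle: literal case-by-case evaluation of the
# edge/interior stencil for a fully valid map (0-based edge indexing
# translated to 1-based R).
oracle_gradient <- function(T, dx, dy) {
  nr <- nrow(T); nc <- ncol(T)
  gx <- gy <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx[i, j] <- if (j == 1) (T[i, j + 1] - T[i, j]) / dx
    else if (j == nc) (T[i, j] - T[i, j - 1]) / dx
    else (T[i, j + 1] - T[i, j - 1]) / (2 * dx)
    gy[i, j] <- if (i == 1) (T[i + 1, j] - T[i, j]) / dy
    else if (i == nr) (T[i, j] - T[i - 1, j]) / dy
    else (T[i + 1, j] - T[i - 1, j]) / (2 * dy)
  }
  list(gx = gx, gy = gy)
}

# Closed-form OLS slope, independent of stats::lm.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Count strict local maxima of a vector.
count_peaks <- function(v) {
  n <- length(v)
  sum(vapply(2:(n - 1), function(i) v[i] > v[i - 1] && v[i] > v[i + 1],
             logical(1)))
}

# A small noiseless movie used by several tests (single pure rising front:
# huge pulse width so the decay branch is exactly 1 in double precision).
quiet_movie <- function(n_frames = 16, ...) {
  movie_spec(noise_sd = 0, n_frames = n_frames, pulse_width = 1e6,
             migration_velocity = c(0, 0), ...)
}
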