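# Synthetic giant-cell recordings with known ground truth: a migrating
# elliptical cell whose interior follows a traveling sigmoidal wavefront,
# plus trace/trajectory/calcium fixtures for every downstream stage.

# A single pulse: logistic rise at half-time b followed by a mirrored
# logistic decay at b + width. The two branches are combined with min(),
# so within each phase the level equals the corresponding analytic logistic
# exactly (the branches only meet where both are ~1).
pulse_level <- function(t, a, b, width) {
  pmin(logistic(t, a, b), logistic(t, -a, b + width))
}

#' Specification of a synthetic wave movie
#'
#' Describes one recording of a migrating elliptical giant cell whose
#' interior intensity follows a planar sigmoidal wavefront. The defaults
#' mirror typical confocal acquisition of giant amoebae: 5 s frames, a
#' cell tens of micrometres across, a wave at ~3 um/s, and an inverted
#' (cAMP-type) sensor response.
#'
#' @param pixel_size micrometres per pixel (default 0.65).
#' @param frame_interval seconds between frames (default 5).
#' @param n_frames number of frames (default 30).
#' @param cell_center0 initial ellipse center (x, y) um; `NULL` (default)
#'   centers the migration path in the frame.
#' @param cell_axes semi-axes (um) of the elliptical cell (default 34, 25).
#' @param migration_velocity 2-vector (um/s); default 0.03 um/s along the
#'   direction (1, 0.42).
#' @param wave_speed true propagation speed v (um/s), default 2.98.
#' @param wave_slope true sigmoid slope a (1/s), default 0.139.
#' @param pulse_times wave-initiation half-times at the initial cell
#'   center (s), default 30.
#' @param wave_direction unit 2-vector along which the wave travels
#'   (early to late activation). Default: opposite to the migration
#'   direction, i.e. the wave enters from the cell's front.
#' @param pulse_width seconds from rise half-time to decay half-time
#'   (default 60); `Inf` gives a pure rising front.
#' @param baseline,amplitude,background intensity levels (a.u.).
#' @param response_sign `"inverted"` (intensity falls as the signal rises,
#'   cAMP-sensor-like) or `"direct"`.
#' @param noise_sd additive Gaussian noise per pixel per frame (a.u.),
#'   default 2.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param shading optional smooth multiplicative field, a
#'   `function(x, y)` of micrometre coordinates.
#' @param frame_dim optional `c(rows, cols)` in pixels; `NULL` sizes the
#'   frame to contain the cell over the whole path plus a margin.
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return A validated `movie_spec` object.
#' @export
movie_spec <- function(pixel_size = 0.65, frame_interval = 5, n_frames = 30,
                       cell_center0 = NULL, cell_axes = c(34, 25),
                       migration_velocity = 0.03 * c(1, 0.42) / sqrt(1 + 0.42^2),
                       wave_speed = 2.98, wave_slope = 0.139,
                       pulse_times = 30, wave_direction = NULL,
                       pulse_width = 60,
                       baseline = 100, amplitude = 60, background = 10,
                       response_sign = c("inverted", "direct"),
                       noise_sd = 2, noise_model = c("gaussian", "poisson"),
                       shading = NULL, frame_dim = NULL, seed = 1) {
  response_sign <- match.arg(response_sign)
  noise_model <- match.arg(noise_model)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict = TRUE)
  check_scalar(n_frames, "n_frames", lower = 2)
  check_scalar(wave_speed, "wave_speed", lower = 0, strict = TRUE)
  check_scalar(wave_slope, "wave_slope", lower = 0, strict = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(pulse_width, "pulse_width", lower = 0, strict = TRUE)
  stopifnot(length(cell_axes) == 2L, all(cell_axes > 0),
            length(migration_velocity) == 2L, length(pulse_times) >= 1L)
  if (is.null(wave_direction))
    wave_direction <- if (vec_norm(migration_velocity) > 0)
      -unit_vec(migration_velocity) else -unit_vec(c(1, 0.42))
  wave_direction <- unit_vec(as.numeric(wave_direction))
  if (!is.null(shading) && !is.function(shading))
    stopf("shading must be NULL or a function(x, y)")
  spec <- list(pixel_size = pixel_size, frame_interval = frame_interval,
               n_frames = as.integer(n_frames),
               cell_center0 = cell_center0,
               cell_axes = as.numeric(cell_axes),
               migration_velocity = as.numeric(migration_velocity),
               wave_speed = wave_speed, wave_slope = wave_slope,
               pulse_times = as.numeric(pulse_times),
               wave_direction = wave_direction,
               pulse_width = pulse_width,
               baseline = baseline, amplitude = amplitude,
               background = background,
               response_sign = response_sign,
               noise_sd = noise_sd, noise_model = noise_model,
               shading = shading, frame_dim = frame_dim,
               seed = as.integer(seed))
  class(spec) <- "movie_spec"
  spec
}

#' @export
print.movie_spec <- function(x, ...) {
  cat(sprintf(paste0("<movie_spec> %d frames @ %g s, px %g um, cell %g x %g um,\n",
                     "  wave v %g um/s a %g 1/s, %s sensor, noise sd %g, seed %d\n"),
              x$n_frames, x$frame_interval, x$pixel_size,
              2 * x$cell_axes[1], 2 * x$cell_axes[2],
              x$wave_speed, x$wave_slope, x$response_sign, x$noise_sd, x$seed))
  invisible(x)
}

# Resolve frame dimensions and starting center so the ellipse stays inside
# the frame over the whole migration path (margin in um).
resolve_geometry <- function(spec, margin = 3) {
  total_t <- (spec$n_frames - 1) * spec$frame_interval
  disp <- spec$migration_velocity * total_t
  if (is.null(spec$frame_dim)) {
    size_um <- 2 * spec$cell_axes + abs(disp) + 2 * margin
    frame_dim <- ceiling(rev(size_um) / spec$pixel_size)  # (rows, cols)
  } else frame_dim <- spec$frame_dim
  size_um <- rev(frame_dim) * spec$pixel_size             # (x extent, y extent)
  center0 <- spec$cell_center0
  if (is.null(center0)) center0 <- (size_um - disp) / 2
  list(frame_dim = as.integer(frame_dim), size_um = size_um,
       center0 = as.numeric(center0))
}

#' Generate a synthetic wave movie with ground truth
#'
#' Renders a migrating elliptical cell whose interior intensity, at
#' position x and time t, is `baseline -/+ amplitude * level`, where the
#' level follows the logistic pulse with position-dependent half-time
#' \deqn{b(x) = t_0 + \frac{(x - c_0)\cdot \hat w}{v}}
#' (planar wavefront traveling along the unit vector w at speed v; c0 is
#' the initial cell center). Pixels outside the cell sit at the background
#' level. Shading (if any) multiplies the clean image; Gaussian noise is
#' added last. The returned ground truth carries the analytic centroid
#' path, the half-time field as a function, and the true (a, v), so every
#' downstream estimate can be checked against construction.
#'
#' @param spec a [movie_spec].
#' @return A `wave_movie`: list with `stack` (rows x cols x frames),
#'   `mask` (0/1 array), `ground_truth` (list: `centroids` data.frame,
#'   `halftime_field(x, y)`, `decay_halftime_field(x, y)`, `true_slope`,
#'   `true_speed`, `wave_direction`, `origin_center`), and the `spec`.
#' @examples
#' mv <- generate_wave_movie(movie_spec(n_frames = 12, noise_sd = 0))
#' dim(mv$stack)
#' @export
generate_wave_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  geo <- resolve_geometry(spec)
  nr <- geo$frame_dim[1]; nc <- geo$frame_dim[2]; nf <- spec$n_frames
  g <- pixel_grid(nr, nc, spec$pixel_size)
  X <- matrix(g$x, nr, nc, byrow = TRUE)
  Y <- matrix(g$y, nr, nc)
  c0 <- geo$center0
  w <- spec$wave_direction
  # position-dependent rise half-time of the first pulse, offsets for later
  proj <- ((X - c0[1]) * w[1] + (Y - c0[2]) * w[2]) / spec$wave_speed
  shade <- if (is.null(spec$shading)) NULL else spec$shading(X, Y)
  stack <- array(0, dim = c(nr, nc, nf))
  mask <- array(0L, dim = c(nr, nc, nf))
  centers <- matrix(0, nf, 2)
  for (f in seq_len(nf)) {
    t <- (f - 1) * spec$frame_interval
    ct <- c0 + spec$migration_velocity * t
    centers[f, ] <- ct
    lo <- ct - spec$cell_axes; hi <- ct + spec$cell_axes
    if (lo[1] < 0 || lo[2] < 0 || hi[1] > geo$size_um[1] ||
        hi[2] > geo$size_um[2])
      stopf("cell ellipse leaves the frame at frame %d", f)
    inside <- ((X - ct[1]) / spec$cell_axes[1])^2 +
      ((Y - ct[2]) / spec$cell_axes[2])^2 <= 1
    level <- 0
    for (tp in spec$pulse_times)
      level <- level + pulse_level(t, spec$wave_slope, tp + proj,
                                   spec$pulse_width)
    img <- matrix(spec$background, nr, nc)
    sig <- if (spec$response_sign == "inverted")
      spec$baseline - spec$amplitude * level
    else spec$baseline + spec$amplitude * level
    img[inside] <- sig[inside]
    if (!is.null(shade)) img <- img * shade
    stack[, , f] <- img
    mask[, , f] <- inside * 1L
  }
  stack <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      if (spec$noise_model == "gaussian")
        stack + array(stats::rnorm(length(stack), 0, spec$noise_sd), dim(stack))
      else
        array(stats::rpois(length(stack), pmax(stack, 0)), dim(stack))
    } else stack
  })
  gt <- list(
    centroids = data.frame(time_s = (seq_len(nf) - 1) * spec$frame_interval,
                           x_um = centers[, 1], y_um = centers[, 2]),
    halftime_field = function(x, y)
      spec$pulse_times[1] +
      ((x - c0[1]) * w[1] + (y - c0[2]) * w[2]) / spec$wave_speed,
    decay_halftime_field = function(x, y)
      spec$pulse_times[1] + spec$pulse_width +
      ((x - c0[1]) * w[1] + (y - c0[2]) * w[2]) / spec$wave_speed,
    true_slope = spec$wave_slope, true_speed = spec$wave_speed,
    wave_direction = w, origin_center = c0)
  structure(list(stack = stack, mask = mask, ground_truth = gt, spec = spec),
            class = "wave_movie")
}

#' @export
print.wave_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<wave_movie> %d x %d px, %d frames (true v %g um/s, a %g 1/s)\n",
              d[1], d[2], d[3], x$ground_truth$true_speed,
              x$ground_truth$true_slope))
  invisible(x)
}

#' Generate a single logistic trace
#'
#' Fixture for the sigmoid fitter: samples `L(t) = 1/(1+exp(-a(t-b)))`
#' (rise) or `1 - L(t)` (decay) at the given times, plus Gaussian noise.
#'
#' @param a slope (1/s), `b` half-time (s).
#' @param b half-time (s).
#' @param times sampling times (s), strictly increasing.
#' @param direction `"rise"` or `"decay"`.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer (only consulted when `noise_sd > 0`).
#' @return A raw [intensity_trace].
#' @export
generate_trace <- function(a, b, times, direction = c("rise", "decay"),
                           noise_sd = 0, seed = 1) {
  direction <- match.arg(direction)
  v <- logistic(times, a, b)
  if (direction == "decay") v <- 1 - v
  if (noise_sd > 0)
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
  intensity_trace(times, v, kind = "raw")
}

#' Generate a periodic relay trace
#'
#' A pulse train emulating periodic signal relay: one logistic
#' rise-then-decay pulse per cycle, repeated at the given period.
#'
#' @param period pulse period (s), default 420 (7 min).
#' @param n_cycles number of pulses (default 6).
#' @param dt sampling interval (s), default 5.
#' @param slope pulse rise slope (1/s), default 0.05.
#' @param pulse_width rise-to-decay half-time spacing (s), default
#'   `period / 3`.
#' @param t_first half-time of the first rise (s), default 60.
#' @param noise_sd,seed additive Gaussian noise and its seed.
#' @return A raw [intensity_trace] spanning `n_cycles * period` seconds.
#' @export
generate_relay_trace <- function(period = 420, n_cycles = 6, dt = 5,
                                 slope = 0.05, pulse_width = period / 3,
                                 t_first = 60, noise_sd = 0, seed = 1) {
  check_scalar(period, "period", lower = 0, strict = TRUE)
  times <- seq(0, n_cycles * period, by = dt)
  v <- rep(0, length(times))
  for (k in seq_len(n_cycles))
    v <- v + pulse_level(times, slope, t_first + (k - 1) * period, pulse_width)
  if (noise_sd > 0)
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
  intensity_trace(times, v, kind = "raw")
}

#' Generate a noisy linear centroid trajectory
#'
#' Points advance along the direction `(1, slope)` (sign of `speed` sets
#' which way) at `|speed|` um/s, with isotropic Gaussian positional noise.
#'
#' @param slope direction slope dy/dx.
#' @param speed um/s; its sign encodes the travel direction along x.
#' @param n number of points (>= 2).
#' @param dt frame interval (s).
#' @param noise_sd positional noise (um), default 0.
#' @param seed integer.
#' @param start first point (x, y) um.
#' @return A [trajectory].
#' @export
generate_trajectory <- function(slope, speed, n, dt = 5, noise_sd = 0,
                                seed = 1, start = c(0, 0)) {
  check_scalar(n, "n", lower = 2)
  dir <- sign(speed) * unit_vec(c(1, slope))
  s <- (seq_len(n) - 1) * dt * abs(speed)
  pts <- cbind(start[1] + s * dir[1], start[2] + s * dir[2])
  if (noise_sd > 0)
    pts <- with_seed(seed,
                     pts + matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2))
  trajectory((seq_len(n) - 1) * dt, pts)
}

#' Generate biphasic calcium transients on a tile grid
#'
#' Emulates a biphasic Ca2+ response over a 7 x 7 grid: two pulses whose
#' onsets are delayed in proportion to each tile's distance from that
#' phase's origin tile, so each phase propagates outward from its origin.
#'
#' @param n_rows,n_cols grid size (defaults 7).
#' @param first_origin,second_origin origin tiles `c(row, col)` of the two
#'   phases.
#' @param peak_times approximate peak times (s) of the two phases at their
#'   origins; must be separated by more than both widths.
#' @param widths pulse widths (s) of the two phases.
#' @param dt sampling interval (s).
#' @param rise_slope pulse rise slope (1/s), default 0.15.
#' @param delay_per_tile onset delay per unit tile distance (s), default 3.
#' @param duration recording length (s); default covers both phases.
#' @param noise_sd,seed additive Gaussian noise and its seed.
#' @return List with `traces` (list-matrix of [intensity_trace]),
#'   `peak_time1`, `peak_time2` (matrices of true per-tile peak times),
#'   `rise_halftime1`, `rise_halftime2`, and the origin tiles.
#' @export
generate_biphasic_calcium <- function(n_rows = 7, n_cols = 7,
                                      first_origin = c(1, 1),
                                      second_origin = c(7, 7),
                                      peak_times = c(120, 360),
                                      widths = c(40, 40), dt = 5,
                                      rise_slope = 0.15, delay_per_tile = 3,
                                      duration = NULL, noise_sd = 0,
                                      seed = 1) {
  if (abs(diff(peak_times)) <= max(widths))
    stopf("peak times must be separated by more than both widths")
  max_dist <- sqrt((n_rows - 1)^2 + (n_cols - 1)^2)
  if (is.null(duration))
    duration <- max(peak_times) + max(widths) +
      delay_per_tile * max_dist + 60
  times <- seq(0, duration, by = dt)
  traces <- matrix(list(), n_rows, n_cols)
  pk1 <- pk2 <- rh1 <- rh2 <- matrix(NA_real_, n_rows, n_cols)
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n_rows * n_cols * length(times), 0, noise_sd))
  else NULL
  idx <- 0L
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    d1 <- sqrt((i - first_origin[1])^2 + (j - first_origin[2])^2)
    d2 <- sqrt((i - second_origin[1])^2 + (j - second_origin[2])^2)
    b1 <- peak_times[1] - widths[1] / 2 + delay_per_tile * d1
    b2 <- peak_times[2] - widths[2] / 2 + delay_per_tile * d2
    v <- pulse_level(times, rise_slope, b1, widths[1]) +
      pulse_level(times, rise_slope, b2, widths[2])
    if (!is.null(noise)) {
      v <- v + noise[idx + seq_along(times)]
      idx <- idx + length(times)
    }
    traces[[i, j]] <- intensity_trace(times, v, kind = "raw")
    pk1[i, j] <- b1 + widths[1] / 2
    pk2[i, j] <- b2 + widths[2] / 2
    rh1[i, j] <- b1
    rh2[i, j] <- b2
  }
  list(traces = traces, peak_time1 = pk1, peak_time2 = pk2,
       rise_halftime1 = rh1, rise_halftime2 = rh2,
       first_origin = first_origin, second_origin = second_origin,
       times = times)
}

#' Generate a sensor/reference ratiometric channel pair
#'
#' The sensor channel is a [generate_wave_movie()] stack; the reference
#' channel carries the same cell shape and the identical multiplicative
#' shading field but no signal response (constant level inside the mask).
#' Dividing reference by sensor therefore cancels the shading exactly
#' (before noise) while preserving the signal time course.
#'
#' @param spec a [movie_spec]; its `shading` (if any) is shared by both
#'   channels.
#' @param ref_level reference-channel intensity inside the cell (a.u.).
#' @return List with `sensor`, `reference` (arrays), `mask`,
#'   `ground_truth`, `spec`.
#' @export
generate_ratiometric_pair <- function(spec, ref_level = 80) {
  stopifnot(inherits(spec, "movie_spec"))
  mv <- generate_wave_movie(spec)
  geo <- resolve_geometry(spec)
  nr <- dim(mv$stack)[1]; nc <- dim(mv$stack)[2]; nf <- dim(mv$stack)[3]
  g <- pixel_grid(nr, nc, spec$pixel_size)
  X <- matrix(g$x, nr, nc, byrow = TRUE)
  Y <- matrix(g$y, nr, nc)
  shade <- if (is.null(spec$shading)) NULL else spec$shading(X, Y)
  ref <- array(0, dim = dim(mv$stack))
  for (f in seq_len(nf)) {
    img <- matrix(spec$background, nr, nc)
    img[mv$mask[, , f] > 0] <- ref_level
    if (!is.null(shade)) img <- img * shade
    ref[, , f] <- img
  }
  if (spec$noise_sd > 0)
    ref <- with_seed(spec$seed + 1L,
                     ref + array(stats::rnorm(length(ref), 0, spec$noise_sd),
                                 dim(ref)))
  list(sensor = mv$stack, reference = ref, mask = mv$mask,
       ground_truth = mv$ground_truth, spec = spec)
}
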