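# Grid-based propagation analysis: per-tile kinetic maps, finite-difference
# gradient of the half-time map, direction comparison, wave velocity and
# apparent diffusion estimates.

#' Per-tile kinetic map
#'
#' For every tile of the partition with mask coverage at or above the
#' threshold, extracts the tile-mean trace, normalizes it over the phase
#' window, fits the logistic model, and stores |a| and b. A tile is marked
#' invalid when the fit fails to converge, the fitted half-time leaves the
#' window, or the residual per sample exceeds `rss_per_point` (poorly
#' fitting regions are excluded from gradients rather than guessed at).
#'
#' @param stack numeric array `[rows, cols, frames]`.
#' @param partition a [partition_grid()] result in the same micrometre
#'   coordinates as the stack.
#' @param phase a [phase_window] selecting the transition to fit; `NULL`
#'   fits the whole duration as a rise.
#' @param normalize `"inverted"` (cAMP-type sensors) or `"minmax"`
#'   (Ca2+-type sensors or ratios).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param mask_stack optional per-frame 0/1 array; tile means use only
#'   mask-foreground pixels.
#' @param coverage_threshold minimum tile coverage (default 0.5).
#' @param rss_per_point residual-sum-of-squares per sample above which a
#'   tile is flagged invalid (default 0.02).
#' @return A `kinetic_map`: matrices `abs_slope`, `halftime`, `slope`
#'   (signed a), logical `valid`, plus `direction`, `grid` and tile sizes.
#' @export
build_kinetic_map <- function(stack, partition, phase = NULL,
                              normalize = c("inverted", "minmax"),
                              pixel_size, frame_interval,
                              mask_stack = NULL,
                              coverage_threshold = 0.5,
                              rss_per_point = 0.02) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(partition, "grid_partition"), length(dim(stack)) == 3L)
  spec <- partition$spec
  nf <- dim(stack)[3]
  times <- (seq_len(nf) - 1) * frame_interval
  if (!is.null(phase)) {
    stopifnot(inherits(phase, "phase_window"))
    if (phase$t_end > max(times) + 1e-9)
      stopf("phase window [%g, %g] exceeds stack duration %g s",
            phase$t_start, phase$t_end, max(times))
  }
  g <- pixel_grid(dim(stack)[1], dim(stack)[2], pixel_size)
  nr <- spec$n_rows; nc <- spec$n_cols
  abs_slope <- halftime <- slope <- rssm <-
    matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(partition$tiles))) {
    tl <- partition$tiles[k, ]
    if (tl$coverage < coverage_threshold) next
    jx <- which(g$x >= tl$x0 & g$x < tl$x1)
    iy <- which(g$y >= tl$y0 & g$y < tl$y1)
    if (!length(jx) || !length(iy)) next
    vals <- rep(NA_real_, nf); ok <- rep(FALSE, nf)
    for (f in seq_len(nf)) {
      px <- stack[iy, jx, f]
      if (!is.null(mask_stack)) {
        sel <- mask_stack[iy, jx, f] > 0
        px <- px[sel]
      }
      if (length(px)) { vals[f] <- mean(px); ok[f] <- TRUE }
    }
    if (sum(ok) < 5L) next
    tr <- intensity_trace(times, vals, kind = "raw", valid = ok)
    win <- if (is.null(phase))
      phase_window(times[1], times[nf], "rise") else phase
    tr <- tryCatch(trace_window(tr, win$t_start, win$t_end),
                   error = function(e) NULL)
    if (is.null(tr) || sum(tr$valid) < 5L) next
    ntr <- tryCatch(
      if (normalize == "inverted") normalize_inverted(tr)
      else normalize_minmax(tr),
      error = function(e) NULL)
    if (is.null(ntr)) next
    ft <- tryCatch(fit_sigmoid(ntr, window = win, direction = win$direction),
                   error = function(e) NULL)
    if (is.null(ft)) next
    i <- tl$row; j <- tl$col
    slope[i, j] <- ft$a
    abs_slope[i, j] <- abs(ft$a)
    halftime[i, j] <- ft$b
    rssm[i, j] <- ft$rss
    valid[i, j] <- ft$converged && (ft$rss / ft$n) <= rss_per_point
  }
  if (!any(valid)) stopf("all tiles invalid: no usable kinetic map")
  direction <- if (is.null(phase)) "rise" else phase$direction
  structure(list(abs_slope = abs_slope, halftime = halftime, slope = slope,
                 rss = rssm, valid = valid, direction = direction,
                 grid = spec, dx = spec$dx, dy = spec$dy),
            class = "kinetic_map")
}

#' Construct a kinetic map from matrices
#'
#' Assembles a `kinetic_map` from precomputed half-time (and optionally
#' slope) matrices, e.g. when maps were produced elsewhere and only the
#' gradient analysis is needed.
#'
#' @param halftime numeric matrix of half-times (s).
#' @param abs_slope optional matrix of |a| (1/s).
#' @param dx,dy tile sizes in micrometres.
#' @param valid optional logical matrix; default: finite half-times.
#' @param direction `"rise"` or `"decay"`.
#' @export
kinetic_map <- function(halftime, abs_slope = NULL, dx, dy,
                        valid = NULL, direction = "rise") {
  halftime <- as.matrix(halftime)
  if (is.null(valid)) valid <- is.finite(halftime)
  if (is.null(abs_slope)) abs_slope <- matrix(NA_real_, nrow(halftime),
                                              ncol(halftime))
  stopifnot(identical(dim(valid), dim(halftime)))
  spec <- grid_spec(width = dx * ncol(halftime), height = dy * nrow(halftime),
                    n_rows = nrow(halftime), n_cols = ncol(halftime))
  structure(list(abs_slope = as.matrix(abs_slope), halftime = halftime,
                 slope = as.matrix(abs_slope), rss = halftime * NA,
                 valid = valid, direction = direction,
                 grid = spec, dx = dx, dy = dy),
            class = "kinetic_map")
}

#' @export
print.kinetic_map <- function(x, ...) {
  cat(sprintf("<kinetic_map> %s, %d x %d tiles (%d valid), dx %.3f dy %.3f um\n",
              x$direction, nrow(x$halftime), ncol(x$halftime),
              sum(x$valid), x$dx, x$dy))
  invisible(x)
}

# One finite-difference component along an index axis. `line` is the vector
# of values with the target at position k; `ok` its validity. Implements the
# edge/interior scheme: first index forward, last index backward, otherwise
# central, with one-sided fallback next to invalid neighbours.
fd_component <- function(line, ok, k, h) {
  n <- length(line)
  has_prev <- k > 1 && ok[k - 1]
  has_next <- k < n && ok[k + 1]
  if (k == 1) {
    if (has_next) (line[k + 1] - line[k]) / h else NA_real_
  } else if (k == n) {
    if (has_prev) (line[k] - line[k - 1]) / h else NA_real_
  } else if (has_prev && has_next) {
    (line[k + 1] - line[k - 1]) / (2 * h)
  } else if (has_next) {
    (line[k + 1] - line[k]) / h
  } else if (has_prev) {
    (line[k] - line[k - 1]) / h
  } else NA_real_
}

#' Finite-difference gradient of a half-time map
#'
#' Computes the partial derivatives of the activation-time map T(i, j) by
#' the edge-aware scheme: forward difference at the first row/column,
#' backward at the last, central elsewhere (dividing by dx, dy, or twice
#' those). Interior tiles next to an invalid tile fall back to the
#' one-sided difference using their valid neighbour; tiles with no valid
#' neighbour along an axis get `NA` for that component. Means are taken
#' over the finite entries.
#'
#' The gradient points from early activation to late activation (the
#' direction the wave travels); see [compare_direction()] for orientation
#' relative to migration.
#'
#' @param map a `kinetic_map`.
#' @return A `gradient_field`: matrices `gx`, `gy` (s/um), scalars
#'   `mean_gx`, `mean_gy`, `slope` (mean_gy / mean_gx), counts, and the
#'   tile sizes.
#' @export
gradient_field <- function(map) {
  stopifnot(inherits(map, "kinetic_map"))
  T <- map$halftime; ok <- map$valid & is.finite(T)
  nr <- nrow(T); nc <- ncol(T)
  if (sum(apply(ok, 1, any)) < 2L || sum(apply(ok, 2, any)) < 2L)
    stopf("gradient needs valid tiles in at least 2 rows and 2 columns")
  gx <- gy <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!ok[i, j]) next
    gx[i, j] <- fd_component(T[i, ], ok[i, ], j, map$dx)
    gy[i, j] <- fd_component(T[, j], ok[, j], i, map$dy)
  }
  mean_gx <- mean(gx[is.finite(gx)])
  mean_gy <- mean(gy[is.finite(gy)])
  structure(list(gx = gx, gy = gy,
                 mean_gx = mean_gx, mean_gy = mean_gy,
                 n_gx = sum(is.finite(gx)), n_gy = sum(is.finite(gy)),
                 slope = if (abs(mean_gx) > 0) mean_gy / mean_gx else NA_real_,
                 dx = map$dx, dy = map$dy),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> mean grad (%.4g, %.4g) s/um, slope %.4g\n",
              x$mean_gx, x$mean_gy, x$slope))
  invisible(x)
}

#' Gradient slope of the half-time map
#'
#' The ratio of the mean y component to the mean x component of the
#' half-time gradient, the scalar summarizing propagation direction.
#'
#' @param field a [gradient_field()] result.
#' @param tol threshold on |mean gx| below which the slope is undefined
#'   (near-vertical propagation).
#' @return List with `slope` and `defined` flag.
#' @export
gradient_slope <- function(field, tol = 1e-9) {
  stopifnot(inherits(field, "gradient_field"))
  if (!is.finite(field$mean_gx) || abs(field$mean_gx) < tol)
    return(list(slope = NA_real_, defined = FALSE))
  list(slope = field$mean_gy / field$mean_gx, defined = TRUE)
}

#' Angle between migration direction and signal-propagation direction
#'
#' The migration direction is `direction_sign * (1, slope)` from the fitted
#' centroid axis. The half-time gradient `(mean_gx, mean_gy)` points from
#' early to late activation, i.e. *along* the wave's travel; the signal
#' *arrived from* the opposite direction. With `orient = "source"` (the
#' default) the angle is measured between migration and `-grad T` — near 0
#' degrees when the cell migrates toward the side the activation wave
#' entered from, which is the alignment the front-to-rear propagation
#' analysis asks about. `orient = "propagation"` compares migration with
#' `+grad T` instead (the two differ by 180 degrees).
#'
#' @param migration a `linear_fit` (or numeric length-2 direction vector).
#' @param field a `gradient_field` (or numeric length-2 gradient vector).
#' @param orient `"source"` or `"propagation"`.
#' @return Unsigned angle in degrees, in \[0, 180\].
#' @export
compare_direction <- function(migration, field,
                              orient = c("source", "propagation")) {
  orient <- match.arg(orient)
  m <- if (inherits(migration, "linear_fit"))
    migration$direction_sign * c(1, migration$slope) else as.numeric(migration)
  g <- if (inherits(field, "gradient_field"))
    c(field$mean_gx, field$mean_gy) else as.numeric(field)
  if (orient == "source") g <- -g
  m <- unit_vec(m); g <- unit_vec(g)
  acos(max(-1, min(1, sum(m * g)))) * 180 / pi
}

#' One-dimensional wave velocity from front/rear half-times
#'
#' The default estimator: distance between the front and rear region
#' centers divided by the difference of their fitted half-times,
#' `v = d / |b_front - b_rear|`. Flagged unreliable when the half-time
#' difference is smaller than one frame interval (the fits cannot resolve
#' it).
#'
#' @param front,rear `sigmoid_fit` objects for the two regions (same
#'   direction, both converged).
#' @param front_region,rear_region the matching [region_spec]s.
#' @param frame_interval seconds between frames (reliability threshold).
#' @return A `propagation_estimate`: `v` (um/s), `method = "front_rear"`,
#'   `distance`, `delta_b`, `reliable`.
#' @export
estimate_velocity <- function(front, rear, front_region, rear_region,
                              frame_interval = 5) {
  stopifnot(inherits(front, "sigmoid_fit"), inherits(rear, "sigmoid_fit"),
            inherits(front_region, "region_spec"),
            inherits(rear_region, "region_spec"))
  if (front$direction != rear$direction)
    stopf("front (%s) and rear (%s) fits are for different phases",
          front$direction, rear$direction)
  if (!front$converged || !rear$converged)
    warning("velocity estimated from non-converged fits", call. = FALSE)
  d <- vec_norm(front_region$center - rear_region$center)
  db <- abs(front$b - rear$b)
  reliable <- db >= frame_interval
  structure(list(v = if (db > 0) d / db else NA_real_,
                 method = "front_rear", distance = d, delta_b = db,
                 reliable = reliable),
            class = "propagation_estimate")
}

#' Wave velocity from the mean half-time gradient
#'
#' Alternative estimator: the reciprocal of the mean half-time gradient
#' magnitude, `v = 1 / |(mean_gx, mean_gy)|` — a gradient of `g` s/um means
#' the activation time advances by `g` seconds per micrometre.
#'
#' @param field a [gradient_field()] result.
#' @return A `propagation_estimate` with `method = "gradient"`.
#' @export
velocity_from_gradient <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  gn <- vec_norm(c(field$mean_gx, field$mean_gy))
  structure(list(v = if (gn > 0) 1 / gn else NA_real_,
                 method = "gradient", distance = NA_real_, delta_b = NA_real_,
                 reliable = is.finite(gn) && gn > 0),
            class = "propagation_estimate")
}

#' @export
print.propagation_estimate <- function(x, ...) {
  cat(sprintf("<propagation_estimate> v = %.3g um/s (method %s)%s\n",
              x$v, x$method, if (isTRUE(x$reliable)) "" else " [UNRELIABLE]"))
  invisible(x)
}

#' Apparent diffusion coefficient of the propagating front
#'
#' A model-based estimate reported with an explicit method tag. The default
#' `"v2_over_a"` takes the spatial front width `v / |a|` times the speed:
#' `D = v^2 / |a|`. The derivation behind any particular published value of
#' this quantity is a modelling choice; outputs always carry the tag so the
#' assumption is visible.
#'
#' @param v propagation velocity (um/s).
#' @param abs_slope representative absolute sigmoid slope |a| (1/s).
#' @param method currently only `"v2_over_a"`.
#' @return List with `D` (um^2/s), `method`.
#' @export
estimate_diffusion <- function(v, abs_slope, method = "v2_over_a") {
  method <- match.arg(method, c("v2_over_a"))
  check_scalar(v, "v", lower = 0, strict = TRUE)
  check_scalar(abs_slope, "abs_slope", lower = 0, strict = TRUE)
  list(D = v^2 / abs_slope, method = method)
}
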