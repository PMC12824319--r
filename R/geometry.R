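# Cell geometry: centroid extraction, migration-axis fitting, front/rear
# region construction, and the 7x7 analysis grid.

#' Area centroid of a binary mask
#'
#' @param mask logical or 0/1 matrix (rows = y, cols = x).
#' @param pixel_size micrometres per pixel (default 1).
#' @return Named numeric `c(x =, y =)` in micrometres, pixel-center
#'   convention (origin at the image's top-left, y down).
#' @export
compute_centroid <- function(mask, pixel_size = 1) {
  m <- mask > 0
  if (!any(m)) stopf("empty mask: centroid undefined")
  idx <- which(m, arr.ind = TRUE)
  c(x = mean((idx[, 2] - 0.5) * pixel_size),
    y = mean((idx[, 1] - 0.5) * pixel_size))
}

#' Centroid trajectory
#'
#' @param times frame times (s), strictly increasing.
#' @param points n x 2 matrix or data.frame of (x, y) positions in
#'   micrometres.
#' @return A `trajectory` object.
#' @export
trajectory <- function(times, points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) == length(times))
  if (length(times) >= 2L && any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 x = as.numeric(points[, 1]), y = as.numeric(points[, 2])),
            class = "trajectory")
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x_um = x$x, y_um = x$y)
}

#' Fit the migration axis by least squares
#'
#' Ordinary least squares of y on x over the centroid path; the migration
#' axis is the fitted line and the travel direction along it is the sign of
#' the net x displacement.
#'
#' @param traj a [trajectory].
#' @return A `linear_fit` object: `slope` (dy/dx), `intercept` (um),
#'   `direction_sign` (+1 toward +x, -1 toward -x), `r_squared`.
#' @export
fit_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$x) < 2L) stopf("trajectory needs >= 2 points")
  if (diff(range(traj$x)) == 0)
    stopf("degenerate trajectory: no x extent (near-vertical path)")
  fm <- stats::lm(y ~ x, data = data.frame(x = traj$x, y = traj$y))
  net <- traj$x[length(traj$x)] - traj$x[1]
  if (net == 0) stopf("zero net x displacement: travel direction undefined")
  structure(list(slope = unname(stats::coef(fm)[2]),
                 intercept = unname(stats::coef(fm)[1]),
                 direction_sign = sign(net),
                 r_squared = suppressWarnings(summary(fm)$r.squared)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g, intercept %.4g um, direction %+d, R2 %.3f\n",
              x$slope, x$intercept, x$direction_sign, x$r_squared))
  invisible(x)
}

#' Front and rear measurement regions
#'
#' Places the two regions on the fitted migration axis at a fixed offset in
#' x from the centroid: front at
#' `centroid + direction_sign * (x_offset, slope * x_offset)`, rear at its
#' reflection through the centroid. The offsets are x-parameterized (not
#' arc length), so a slope of 0.42 with a 20 um offset gives the
#' (+/-20, +/-8.4) um displacements.
#'
#' @param fit a [fit_trajectory()] result.
#' @param centroid numeric (x, y) in micrometres, usually the mean centroid.
#' @param x_offset offset along x in micrometres (default 20).
#' @param diameter region diameter in micrometres (default 11).
#' @return List with `front` and `rear` [region_spec] objects.
#' @export
define_front_rear <- function(fit, centroid, x_offset = 20, diameter = 11) {
  stopifnot(inherits(fit, "linear_fit"), length(centroid) == 2L)
  if (abs(fit$slope) > 5)
    stopf("|slope| = %.3g > 5: axis too steep for x-parameterized offsets",
          abs(fit$slope))
  off <- fit$direction_sign * c(x_offset, fit$slope * x_offset)
  list(front = region_spec(as.numeric(centroid) + off, diameter),
       rear  = region_spec(as.numeric(centroid) - off, diameter))
}

#' Analysis-grid specification
#'
#' The rectangular analysis box and its division into tiles. Defaults match
#' a 45 x 35 um box split 7 x 7, giving tiles of 6.429 x 5.000 um, each
#' about the footprint of one normal-sized amoeba.
#'
#' @param origin (x, y) of the rectangle's top-left corner, micrometres.
#' @param width,height box size in micrometres (defaults 45, 35).
#' @param n_rows,n_cols tile counts (defaults 7, 7).
#' @return A `grid_spec` with derived tile sizes `dx = width/n_cols`,
#'   `dy = height/n_rows`.
#' @export
grid_spec <- function(origin = c(0, 0), width = 45, height = 35,
                      n_rows = 7, n_cols = 7) {
  check_scalar(width, "width", lower = 0, strict = TRUE)
  check_scalar(height, "height", lower = 0, strict = TRUE)
  check_scalar(n_rows, "n_rows", lower = 1)
  check_scalar(n_cols, "n_cols", lower = 1)
  structure(list(origin = as.numeric(origin), width = width, height = height,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 dx = width / n_cols, dy = height / n_rows),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g x %g um at (%.2f, %.2f), %d x %d tiles (dx %.3f, dy %.3f um)\n",
              x$width, x$height, x$origin[1], x$origin[2],
              x$n_rows, x$n_cols, x$dx, x$dy))
  invisible(x)
}

#' Partition the analysis box into tiles
#'
#' Tile (i, j) (row i, column j, both 1-based; row index increases
#' downward) spans the half-open rectangle
#' `[x0 + (j-1) dx, x0 + j dx) x [y0 + (i-1) dy, y0 + i dy)`, so boundary
#' pixels are never double-counted and the tiles exactly cover the box.
#'
#' @param spec a [grid_spec].
#' @param mask optional 0/1 matrix; with `pixel_size`, per-tile coverage is
#'   the fraction of the tile's pixel centers that are mask foreground.
#' @param pixel_size micrometres per pixel (required when `mask` given).
#' @return A `grid_partition`: the spec plus a data.frame `tiles` with
#'   columns row, col, x0, x1, y0, y1, cx, cy, coverage.
#' @export
partition_grid <- function(spec, mask = NULL, pixel_size = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  ij <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  x0 <- spec$origin[1] + (ij$col - 1) * spec$dx
  y0 <- spec$origin[2] + (ij$row - 1) * spec$dy
  tiles <- data.frame(row = ij$row, col = ij$col,
                      x0 = x0, x1 = x0 + spec$dx,
                      y0 = y0, y1 = y0 + spec$dy,
                      cx = x0 + spec$dx / 2, cy = y0 + spec$dy / 2,
                      coverage = 1)
  if (!is.null(mask)) {
    if (is.null(pixel_size)) stopf("pixel_size required when mask is given")
    g <- pixel_grid(nrow(mask), ncol(mask), pixel_size)
    for (k in seq_len(nrow(tiles))) {
      jx <- which(g$x >= tiles$x0[k] & g$x < tiles$x1[k])
      iy <- which(g$y >= tiles$y0[k] & g$y < tiles$y1[k])
      tiles$coverage[k] <- if (length(jx) && length(iy))
        mean(mask[iy, jx, drop = FALSE] > 0) else 0
    }
  }
  structure(list(spec = spec, tiles = tiles), class = "grid_partition")
}

#' @export
print.grid_partition <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  mean tile coverage %.2f\n", mean(x$tiles$coverage)))
  invisible(x)
}
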