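# Fluorescence signal quantification: normalization of raw intensities to
# relative signal levels, ratiometric correction, region traces, kymographs.

norm_core <- function(values, valid) {
  v <- values[valid]
  if (length(v) < 2L || !all(is.finite(v)))
    stopf("normalization needs at least 2 finite valid samples")
  if (max(v) == min(v))
    stopf("degenerate input: trace is constant, normalization undefined")
  v
}

#' Inverted normalization (relative cAMP level)
#'
#' Converts a raw trace from an intensiometric sensor whose fluorescence
#' *decreases* as the signal rises (e.g. Flamindo2 for cAMP) into a relative
#' signal level in \[0, 1\]. The transform subtracts the maximum and divides
#' by the (negative) minimum of the shifted values:
#' \deqn{I_a = I - \max(I), \qquad I_b = I_a / \min(I_a)}
#' so the brightest frame maps to 0, the dimmest to 1, and the mapping is
#' order-reversing in the raw intensity. It is invariant under affine
#' rescaling (camera gain/offset) of the raw values.
#'
#' The normalization window is whatever the passed trace spans: restrict
#' with [trace_window()] first to normalize over a phase rather than a full
#' recording.
#'
#' @param trace a raw [intensity_trace] (non-constant over valid samples).
#' @return An `intensity_trace` of kind `"cAMP_level"` with values in
#'   \[0, 1\]; min 0 and max 1 are attained. Invalid samples get `NA`.
#' @examples
#' normalize_inverted(intensity_trace(0:2, c(10, 8, 6)))$values  # 0 0.5 1
#' @seealso [normalize_minmax()] for direct-reading sensors.
#' @export
normalize_inverted <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- norm_core(trace$values, trace$valid)
  ia <- trace$values - max(v)
  out <- ia / min(ia[trace$valid])
  out[!trace$valid] <- NA_real_
  intensity_trace(trace$times, out, kind = "cAMP_level", valid = trace$valid)
}

#' Min-max normalization (relative calcium level)
#'
#' For direct-reading sensors (fluorescence increases with the signal, e.g.
#' GCaMP6s for Ca2+): \eqn{I_a = I - \min(I)}, \eqn{I_b = I_a / \max(I_a)}.
#' Order-preserving, range exactly \[0, 1\], affine-invariant.
#'
#' @inheritParams normalize_inverted
#' @return An `intensity_trace` of kind `"Ca_level"`.
#' @export
normalize_minmax <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- norm_core(trace$values, trace$valid)
  ia <- trace$values - min(v)
  out <- ia / max(ia[trace$valid])
  out[!trace$valid] <- NA_real_
  intensity_trace(trace$times, out, kind = "Ca_level", valid = trace$valid)
}

#' Ratiometric correction
#'
#' Divides a signal-insensitive reference channel by the sensor channel
#' (reference / sensor), pixelwise for image stacks or samplewise for
#' traces. Any multiplicative field shared by the two channels (shading,
#' probe concentration, cell thickness) cancels exactly. With an inverted
#' sensor in the denominator the ratio *rises* with the signal, so
#' downstream normalization uses [normalize_minmax()].
#'
#' @param reference,sensor numeric arrays of identical shape, or two
#'   [intensity_trace] objects on the same time base.
#' @param mask optional logical/0-1 array delimiting where the ratio is
#'   meaningful; outside the mask the ratio is set to `NA`.
#' @return Array of the same shape, or an `intensity_trace` of kind
#'   `"ratio"`.
#' @export
compute_ratio <- function(reference, sensor, mask = NULL) {
  if (inherits(reference, "intensity_trace")) {
    stopifnot(inherits(sensor, "intensity_trace"))
    if (length(reference) != length(sensor) ||
        any(reference$times != sensor$times))
      stopf("reference and sensor traces are not on the same time base")
    ok <- reference$valid & sensor$valid
    bad <- sum(sensor$values[ok] <= 0)
    if (bad > 0)
      stopf("sensor has %d non-positive values; ratio undefined", bad)
    return(intensity_trace(reference$times,
                           ifelse(ok, reference$values / sensor$values, NA_real_),
                           kind = "ratio", valid = ok))
  }
  if (!identical(dim(reference), dim(sensor)))
    stopf("reference and sensor stacks differ in shape")
  inside <- if (is.null(mask)) rep(TRUE, length(sensor)) else as.logical(mask)
  bad <- sum(sensor[inside] <= 0, na.rm = TRUE)
  if (bad > 0)
    stopf("sensor has %d non-positive pixels inside the mask; ratio undefined",
          bad)
  out <- reference / sensor
  out[!inside] <- NA_real_
  out
}

#' Circular measurement region
#'
#' @param center numeric length-2 point (x, y) in micrometres.
#' @param diameter region diameter in micrometres (default 11, about the
#'   footprint of one normal-sized amoeba).
#' @return A `region_spec` object.
#' @export
region_spec <- function(center, diameter = 11) {
  stopifnot(is.numeric(center), length(center) == 2L)
  check_scalar(diameter, "diameter", lower = 0, strict = TRUE)
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> center (%.2f, %.2f) um, diameter %.2f um\n",
              x$center[1], x$center[2], x$diameter))
  invisible(x)
}

#' Mean-intensity trace of a circular region
#'
#' Averages, per frame, the pixels whose centers fall inside the region
#' circle, optionally intersected with a per-frame cell mask. Frames where
#' the intersection is empty are flagged invalid (not zero).
#'
#' @param stack numeric array `[rows, cols, frames]`.
#' @param region a [region_spec] in micrometre coordinates.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param mask_stack optional 0/1 array of the same shape; when given, only
#'   pixels inside both circle and mask contribute.
#' @param t0 acquisition time of the first frame (s).
#' @return A raw [intensity_trace], one sample per frame.
#' @export
extract_region_trace <- function(stack, region, pixel_size, frame_interval,
                                 mask_stack = NULL, t0 = 0) {
  stopifnot(inherits(region, "region_spec"), length(dim(stack)) == 3L)
  if (!is.null(mask_stack) && !identical(dim(mask_stack), dim(stack)))
    stopf("mask_stack shape differs from stack")
  g <- pixel_grid(dim(stack)[1], dim(stack)[2], pixel_size)
  dx2 <- outer((g$y - region$center[2])^2, (g$x - region$center[1])^2, `+`)
  in_circle <- dx2 <= (region$diameter / 2)^2
  if (!any(in_circle))
    stopf("region circle contains no pixel centers")
  nf <- dim(stack)[3]
  vals <- rep(NA_real_, nf)
  ok <- rep(FALSE, nf)
  for (f in seq_len(nf)) {
    sel <- in_circle
    if (!is.null(mask_stack)) sel <- sel & (mask_stack[, , f] > 0)
    if (any(sel)) {
      vals[f] <- mean(stack[, , f][sel])
      ok[f] <- TRUE
    }
  }
  if (!any(ok))
    stopf("region has no pixels inside the mask in any frame")
  intensity_trace(t0 + (seq_len(nf) - 1) * frame_interval, vals,
                  kind = "raw", valid = ok)
}

#' Kymograph along a line segment
#'
#' Builds the familiar position-versus-time matrix used to visualize
#' traveling waves: the segment is divided into bins one pixel wide, and
#' each bin's value per frame is the mean intensity over the rectangle of
#' the given width centered on the segment.
#'
#' @param stack numeric array `[rows, cols, frames]`.
#' @param segment 2x2 numeric matrix, rows = the two endpoints (x, y) in
#'   micrometres.
#' @param width rectangle width in micrometres; `width = pixel_size` reduces
#'   to the single-pixel line profile.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @return A `kymograph` object: list with `matrix` (frames x bins),
#'   `positions` (bin centers, um), `times` (s), `segment`, `width`.
#' @export
build_kymograph <- function(stack, segment, width, pixel_size, frame_interval) {
  segment <- matrix(as.numeric(segment), 2, 2)
  p1 <- segment[1, ]; p2 <- segment[2, ]
  len <- vec_norm(p2 - p1)
  if (len <= 0) stopf("segment endpoints coincide")
  u <- (p2 - p1) / len
  n_bins <- ceiling(len / pixel_size)
  bin_w <- len / n_bins
  g <- pixel_grid(dim(stack)[1], dim(stack)[2], pixel_size)
  X <- matrix(g$x, nrow = dim(stack)[1], ncol = dim(stack)[2], byrow = TRUE)
  Y <- matrix(g$y, nrow = dim(stack)[1], ncol = dim(stack)[2])
  s <- (X - p1[1]) * u[1] + (Y - p1[2]) * u[2]       # along-axis coordinate
  d <- abs((X - p1[1]) * (-u[2]) + (Y - p1[2]) * u[1]) # perpendicular distance
  in_rect <- s >= 0 & s <= len & d <= width / 2
  if (!any(in_rect)) stopf("kymograph rectangle contains no pixel centers")
  bin_idx <- pmin(floor(s / bin_w) + 1L, n_bins)
  nf <- dim(stack)[3]
  m <- matrix(NA_real_, nrow = nf, ncol = n_bins)
  idx <- bin_idx[in_rect]
  for (f in seq_len(nf)) {
    fr <- stack[, , f][in_rect]
    m[f, ] <- as.numeric(tapply(fr, factor(idx, levels = seq_len(n_bins)), mean))
  }
  structure(list(matrix = m,
                 positions = (seq_len(n_bins) - 0.5) * bin_w,
                 times = (seq_len(nf) - 1) * frame_interval,
                 segment = segment, length = len, width = width),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d bins, segment length %.1f um, width %.1f um\n",
              nrow(x$matrix), ncol(x$matrix), x$length, x$width))
  invisible(x)
}
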