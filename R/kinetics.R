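# Sigmoid activation/decay kinetics: logistic fitting for slope and
# half-time, phase segmentation, and oscillation-period estimation.

#' Logistic signal level
#'
#' The two-parameter model fitted throughout the package:
#' \deqn{L(t) = \frac{1}{1 + e^{-a (t - b)}}}
#' with slope `a` (1/s, signed: negative for decay phases) and half-time
#' `b` (s), the instant at which the level crosses 0.5.
#'
#' @param t time(s), seconds.
#' @param a slope, 1/s.
#' @param b half-time, s.
#' @return Numeric vector of levels in (0, 1).
#' @export
logistic <- function(t, a, b) 1 / (1 + exp(-a * (t - b)))

#' Phase window
#'
#' A time interval containing one monotone transition (rise or decay) of a
#' normalized trace, as produced by [segment_phases()].
#'
#' @param t_start,t_end window bounds (s), `t_start < t_end`.
#' @param direction `"rise"` or `"decay"`.
#' @param amplitude normalized level change across the window.
#' @export
phase_window <- function(t_start, t_end, direction = c("rise", "decay"),
                         amplitude = NA_real_) {
  direction <- match.arg(direction)
  if (t_start >= t_end) stopf("t_start must be < t_end")
  structure(list(t_start = t_start, t_end = t_end, direction = direction,
                 amplitude = amplitude),
            class = "phase_window")
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf("<phase_window> %s [%g, %g] s, amplitude %.3g\n",
              x$direction, x$t_start, x$t_end, x$amplitude))
  invisible(x)
}

#' Fit the logistic model to a normalized trace
#'
#' Least-squares estimation of (a, b) in `L(t) = 1/(1 + exp(-a(t - b)))`
#' over one phase window. Decay phases use the same parameterization with
#' `a < 0` (not `1 - L`), so reversing a trace negates the fitted slope and
#' preserves the half-time.
#'
#' Initialization: `a0 = +/-4 / (t90 - t10)` from the empirical 10--90%
#' crossing times and `b0` at the first 0.5 crossing; parameters are
#' box-bounded (`|a| <= max_abs_slope`, `b` inside the window) and fitted by
#' Levenberg--Marquardt (`minpack.lm`), falling back to `L-BFGS-B` if that
#' fails. `converged` is `FALSE` when the optimizer fails or the fitted
#' half-time leaves the window.
#'
#' @param trace a normalized [intensity_trace] (values in \[0, 1\]).
#' @param window optional [phase_window]; default spans the whole trace.
#' @param direction `"auto"` (infer from the net level change in the
#'   window), `"rise"` or `"decay"`.
#' @param max_abs_slope bound on |a| (1/s), default 10.
#' @return A `sigmoid_fit` object: list with `a`, `b`, `direction`, `rss`,
#'   `n`, `converged`, `window`.
#' @examples
#' tr <- generate_trace(a = 0.2, b = 30, times = seq(0, 60, 5))
#' fit_sigmoid(tr)
#' @export
fit_sigmoid <- function(trace, window = NULL,
                        direction = c("auto", "rise", "decay"),
                        max_abs_slope = 10) {
  stopifnot(inherits(trace, "intensity_trace"))
  direction <- match.arg(direction)
  if (is.null(window))
    window <- phase_window(min(trace$times), max(trace$times), "rise")
  keep <- trace$valid & trace$times >= window$t_start &
    trace$times <= window$t_end
  t <- trace$times[keep]; y <- trace$values[keep]
  if (length(t) < 5L)
    stopf("sigmoid fit needs >= 5 valid samples in the window (got %d)",
          length(t))
  if (!all(is.finite(y))) stopf("non-finite values in the fit window")
  rising <- switch(direction,
                   rise = TRUE, decay = FALSE,
                   auto = {
                     k <- max(1L, min(3L, length(y) %/% 3L))
                     mean(utils::tail(y, k)) >= mean(utils::head(y, k))
                   })
  dir_lab <- if (rising) "rise" else "decay"
  yy <- if (rising) y else 1 - y   # work on a rising copy for initialization
  cross_time <- function(level) {
    idx <- which(yy >= level)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    if (i == 1L) return(t[1])
    # linear interpolation between the bracketing samples
    t[i - 1] + (level - yy[i - 1]) / (yy[i] - yy[i - 1]) * (t[i] - t[i - 1])
  }
  t10 <- cross_time(0.1); t50 <- cross_time(0.5); t90 <- cross_time(0.9)
  span <- max(t) - min(t)
  a0 <- if (is.finite(t10) && is.finite(t90) && t90 > t10)
    4 / (t90 - t10) else 4 / span
  a0 <- min(a0, max_abs_slope * 0.99)
  b0 <- if (is.finite(t50)) t50 else stats::median(t)
  if (!rising) a0 <- -a0
  b_lo <- window$t_start; b_hi <- window$t_end
  b0 <- min(max(b0, b_lo), b_hi)
  fitted <- tryCatch({
    df <- data.frame(t = t, y = y)
    fm <- minpack.lm::nlsLM(
      y ~ 1 / (1 + exp(-a * (t - b))), data = df,
      start = list(a = a0, b = b0),
      lower = c(a = -max_abs_slope, b = b_lo),
      upper = c(a = max_abs_slope, b = b_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- stats::coef(fm)
    list(a = unname(p["a"]), b = unname(p["b"]),
         rss = sum(stats::resid(fm)^2), ok = TRUE)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fitted)) {
    rssf <- function(p) sum((y - logistic(t, p[1], p[2]))^2)
    op <- tryCatch(
      stats::optim(c(a0, b0), rssf, method = "L-BFGS-B",
                   lower = c(-max_abs_slope, b_lo),
                   upper = c(max_abs_slope, b_hi)),
      error = function(e) NULL)
    fitted <- if (is.null(op)) {
      list(a = a0, b = b0, rss = rssf(c(a0, b0)), ok = FALSE)
    } else {
      list(a = op$par[1], b = op$par[2], rss = op$value,
           ok = op$convergence == 0)
    }
  }
  b_inside <- fitted$b > b_lo && fitted$b < b_hi
  structure(list(a = fitted$a, b = fitted$b, direction = dir_lab,
                 rss = fitted$rss, n = length(t),
                 converged = isTRUE(fitted$ok) && b_inside,
                 window = window),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %s: a = %.4g 1/s, b = %.4g s, rss = %.3g (n = %d)%s\n",
              x$direction, x$a, x$b, x$rss, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# Strict local extrema of a numeric vector, endpoints included; plateaus
# contribute their first index.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(seq_len(n))
  d <- diff(v)
  d <- d[d != 0]
  # indices where the (nonzero) slope changes sign
  dd <- diff(v)
  ext <- integer(0)
  last_sign <- 0
  for (i in seq_along(dd)) {
    s <- sign(dd[i])
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) ext <- c(ext, i)
      last_sign <- s
    }
  }
  sort(unique(c(1L, ext, n)))
}

#' Segment a normalized trace into rise/decay phases
#'
#' Smooths the trace with a centered moving average, locates local extrema,
#' discards oscillations whose level change is below `min_amplitude`, and
#' returns the alternating monotone windows between the surviving extrema.
#'
#' @param trace a normalized [intensity_trace].
#' @param min_amplitude minimum normalized level change for a phase to
#'   count (default 0.5).
#' @param smooth_window moving-average width in samples (odd; default 3).
#' @return A list of [phase_window] objects, time-ordered and disjoint;
#'   empty when no transition reaches `min_amplitude`.
#' @export
segment_phases <- function(trace, min_amplitude = 0.5, smooth_window = 3) {
  stopifnot(inherits(trace, "intensity_trace"))
  keep <- trace$valid
  t <- trace$times[keep]; v <- trace$values[keep]
  n <- length(v)
  if (n < 3L) return(list())
  if (smooth_window > 1L) {
    k <- min(smooth_window, n)
    if (k %% 2L == 0L) k <- k - 1L
    if (k >= 3L) {
      sm <- stats::filter(v, rep(1 / k, k), sides = 2)
      h <- (k - 1L) %/% 2L
      sm[seq_len(h)] <- v[seq_len(h)]
      sm[(n - h + 1L):n] <- v[(n - h + 1L):n]
      v <- as.numeric(sm)
    }
  }
  ext <- local_extrema(v)
  # prune wiggles below threshold, keeping alternation
  repeat {
    if (length(ext) < 2L) break
    amps <- abs(diff(v[ext]))
    small <- which(amps < min_amplitude)
    # ignore leading/trailing sub-threshold segments here; drop them at the end
    interior <- small[small > 1L & small < length(ext) - 1L]
    if (!length(interior)) break
    k <- interior[which.min(amps[interior])]
    # merge by removing the two extrema bounding the small segment; the
    # surrounding segments join into one monotone-in-trend window
    ext <- ext[-c(k, k + 1L)]
    ext <- sort(unique(c(1L, ext, length(v))))
  }
  if (length(ext) < 2L) return(list())
  out <- list()
  for (k in seq_len(length(ext) - 1L)) {
    i1 <- ext[k]; i2 <- ext[k + 1L]
    amp <- abs(v[i2] - v[i1])
    if (amp < min_amplitude) next
    out[[length(out) + 1L]] <-
      phase_window(t[i1], t[i2],
                   direction = if (v[i2] > v[i1]) "rise" else "decay",
                   amplitude = amp)
  }
  out
}

#' Oscillation period by autocorrelation
#'
#' Estimates the dominant period of a relay trace as the lag of the first
#' positive-lag local maximum of the autocorrelation of the mean-subtracted
#' values. The estimate is flagged unreliable when no autocorrelation peak
#' exceeds `min_corr` or when the recording is shorter than two detected
#' periods.
#'
#' @param trace an [intensity_trace] on a uniform time base.
#' @param min_corr minimum autocorrelation at the peak (default 0.2).
#' @return List with `period` (s, `NA` when undetectable), `reliable`
#'   (logical), `peak_corr`, and `lag` (samples).
#' @export
estimate_period <- function(trace, min_corr = 0.2) {
  stopifnot(inherits(trace, "intensity_trace"))
  keep <- trace$valid
  t <- trace$times[keep]; v <- trace$values[keep]
  n <- length(v)
  if (n < 8L) return(list(period = NA_real_, reliable = FALSE,
                          peak_corr = NA_real_, lag = NA_integer_))
  dt <- stats::median(diff(t))
  ac <- as.numeric(stats::acf(v - mean(v), lag.max = n - 2L,
                              plot = FALSE, demean = FALSE)$acf)
  # interior local maxima over positive lags (ac[1] is lag 0); lag 1 itself
  # never qualifies, since the autocorrelation always starts high at lag 0
  r <- ac[-1]
  nn <- length(r)
  peaks <- which(vapply(2:(nn - 1), function(i)
    r[i] > r[i - 1] && r[i] >= r[i + 1], logical(1))) + 1L
  peaks <- peaks[r[peaks] >= min_corr]
  if (!length(peaks))
    return(list(period = NA_real_, reliable = FALSE,
                peak_corr = if (length(r)) max(r) else NA_real_,
                lag = NA_integer_))
  lag <- peaks[1]
  period <- lag * dt
  duration <- max(t) - min(t)
  list(period = period, reliable = duration >= 2 * period,
       peak_corr = r[lag], lag = lag)
}
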