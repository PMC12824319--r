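#' Intensity trace
#'
#' A time-stamped sequence of fluorescence values for one region or pixel,
#' the basic currency passed between quantification and kinetics functions.
#' Samples carry an explicit validity flag: frames where a region had no
#' pixels (e.g. the cell moved away) are kept in place but marked invalid,
#' and fitting functions skip them.
#'
#' @param times numeric vector of acquisition times (s), strictly increasing.
#' @param values numeric vector of intensities, same length as `times`.
#'   Raw values are in arbitrary camera units; normalized kinds lie in
#'   \[0, 1\].
#' @param kind one of `"raw"`, `"cAMP_level"`, `"Ca_level"`, `"ratio"`.
#' @param valid logical vector flagging usable samples (default all `TRUE`).
#' @return An object of class `intensity_trace`: a list with fields
#'   `times`, `values`, `valid`, `kind`.
#' @examples
#' tr <- intensity_trace(c(0, 5, 10), c(10, 8, 6))
#' normalize_inverted(tr)$values
#' @export
intensity_trace <- function(times, values,
                            kind = c("raw", "cAMP_level", "Ca_level", "ratio"),
                            valid = NULL) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stopf("times (%d) and values (%d) differ in length",
          length(times), length(values))
  if (length(times) >= 2L && any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(times))
  if (length(valid) != length(times))
    stopf("valid flag length mismatch")
  structure(list(times = times, values = values,
                 valid = as.logical(valid), kind = kind),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> kind=%s, %d samples (%d valid), t in [%g, %g] s\n",
              x$kind, length(x$times), sum(x$valid),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.intensity_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, valid = x$valid)
}

#' @export
length.intensity_trace <- function(x) length(x$times)

#' Restrict a trace to a time window
#'
#' @param trace an [intensity_trace].
#' @param t_start,t_end window bounds (s), inclusive.
#' @return An `intensity_trace` containing the samples with
#'   `t_start <= t <= t_end`.
#' @export
trace_window <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (t_start >= t_end) stopf("t_start must be < t_end")
  keep <- trace$times >= t_start & trace$times <= t_end
  if (!any(keep)) stopf("window [%g, %g] contains no samples", t_start, t_end)
  intensity_trace(trace$times[keep], trace$values[keep],
                  kind = trace$kind, valid = trace$valid[keep])
}
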