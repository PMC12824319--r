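# Discrete-time stochastic cell growth/division (sizer) model: synchronous
# size doubling, probabilistic size-gated division, asymmetric partitioning.

#' Parameters of the growth/division model
#'
#' @param n0 initial number of cells (>= 1).
#' @param s0 initial size of every cell (um^2, > 0).
#' @param steps number of time steps T (>= 0).
#' @param p_div division probability in \[0, 1\] for cells above the size
#'   threshold.
#' @param s_min minimum size for division eligibility (strictly exceeded).
#' @param p_min,p_max bounds of the uniform partition-ratio draw, in (0, 1)
#'   with `p_min <= p_max`.
#' @param seed integer RNG seed.
#' @return A `size_model_params` object.
#' @note The defaults are placeholders for exploring the model, not a
#'   calibrated parameter set.
#' @export
size_model_params <- function(n0 = 100, s0 = 50, steps = 8, p_div = 0.9,
                              s_min = 50, p_min = 0.4, p_max = 0.6,
                              seed = 1) {
  check_scalar(n0, "n0", lower = 1)
  check_scalar(s0, "s0", lower = 0, strict = TRUE)
  check_scalar(steps, "steps", lower = 0)
  check_scalar(p_div, "p_div", lower = 0, upper = 1)
  check_scalar(s_min, "s_min", lower = 0)
  check_scalar(p_min, "p_min", lower = 0, upper = 1, strict = TRUE)
  check_scalar(p_max, "p_max", lower = 0, upper = 1, strict = TRUE)
  if (p_min > p_max) stopf("p_min must be <= p_max")
  structure(list(n0 = as.integer(n0), s0 = s0, steps = as.integer(steps),
                 p_div = p_div, s_min = s_min,
                 p_min = p_min, p_max = p_max, seed = as.integer(seed)),
            class = "size_model_params")
}

#' Growth phase: synchronous size doubling
#'
#' @param sizes numeric vector of positive cell sizes.
#' @return The sizes, each doubled.
#' @export
step_grow <- function(sizes) {
  if (!length(sizes)) stopf("empty population: nothing to grow")
  2 * sizes
}

#' Division phase: probabilistic size-gated asymmetric division
#'
#' Each cell whose size strictly exceeds `s_min` divides independently with
#' probability `p_div`; a dividing cell of size s is replaced by daughters
#' `p * s` and `(1 - p) * s` with `p ~ Uniform(p_min, p_max)` drawn per
#' division. Cells are processed in population order so a given RNG state
#' yields exactly one outcome. Total size is conserved exactly.
#'
#' @param sizes numeric vector of positive cell sizes.
#' @param params a [size_model_params]; the ambient RNG stream is used
#'   (seed handling lives in [run_model()]).
#' @return The new size vector (daughters replace their parent in place).
#' @export
step_divide <- function(sizes, params) {
  if (!length(sizes)) stopf("empty population: nothing to divide")
  out <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    divides <- s > params$s_min &&
      (params$p_div >= 1 ||
         (params$p_div > 0 && stats::runif(1) < params$p_div))
    if (divides) {
      p <- stats::runif(1, params$p_min, params$p_max)
      out[[k]] <- c(p * s, (1 - p) * s)
    } else out[[k]] <- s
  }
  unlist(out, use.names = FALSE)
}

#' Run the growth/division model
#'
#' Iterates growth-then-division for `steps` steps from `n0` identical
#' cells of size `s0`, recording the population after every step. The
#' model conserves total size exactly: after step k the population sums to
#' `n0 * s0 * 2^k` regardless of how many divisions occurred.
#'
#' @param params a [size_model_params].
#' @return A `population_series`: list of `steps + 1` states, each a list
#'   with `step` and `sizes`, plus the `params`.
#' @examples
#' ps <- run_model(size_model_params(n0 = 4, s0 = 10, steps = 3, seed = 42))
#' sum(ps$states[[4]]$sizes)  # 4 * 10 * 2^3
#' @export
run_model <- function(params) {
  stopifnot(inherits(params, "size_model_params"))
  with_seed(params$seed, {
    sizes <- rep(params$s0, params$n0)
    states <- vector("list", params$steps + 1L)
    states[[1L]] <- list(step = 0L, sizes = sizes)
    for (k in seq_len(params$steps)) {
      sizes <- step_grow(sizes)
      sizes <- step_divide(sizes, params)
      states[[k + 1L]] <- list(step = k, sizes = sizes)
    }
    structure(list(states = states, params = params),
              class = "population_series")
  })
}

#' @export
print.population_series <- function(x, ...) {
  fin <- x$states[[length(x$states)]]
  cat(sprintf("<population_series> %d steps, final %d cells, total size %.6g\n",
              x$params$steps, length(fin$sizes), sum(fin$sizes)))
  invisible(x)
}

#' Size-distribution statistics
#'
#' Median and strict-exceedance fractions, the summaries used to compare
#' simulated size distributions with measured cell-area histograms.
#'
#' @param sizes numeric vector of cell sizes (um^2).
#' @param thresholds numeric thresholds (um^2), default `c(200, 500)`.
#' @return List with `median`, `fractions` (named, fraction of sizes
#'   strictly greater than each threshold), and `n`.
#' @export
size_stats <- function(sizes, thresholds = c(200, 500)) {
  if (!length(sizes)) stopf("no sizes")
  fr <- vapply(thresholds, function(th) mean(sizes > th), numeric(1))
  names(fr) <- as.character(thresholds)
  list(median = stats::median(sizes), fractions = fr, n = length(sizes))
}
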