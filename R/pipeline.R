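# End-to-end orchestration: trajectory -> front/rear kinetics -> grid maps
# -> gradient direction -> velocity/diffusion, plus result serialization.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

first_window <- function(windows, direction) {
  for (w in windows) if (w$direction == direction) return(w)
  NULL
}

#' Run the full propagation analysis
#'
#' Orchestrates the whole analysis on one recording: per-frame mask
#' centroids and migration-axis fit; front/rear region construction;
#' region traces, normalization, phase segmentation, and sigmoid fits;
#' 7 x 7 kinetic maps for the rise (and, when present, decay) phase;
#' finite-difference gradient of the rise half-time map; migration/wave
#' direction comparison; and the velocity and apparent-diffusion
#' estimates.
#'
#' @param stack numeric array `[rows, cols, frames]` of sensor intensities.
#' @param mask_stack 0/1 array of the same shape (cell masks).
#' @param config a [pipeline_config()]; `pixel_size` and `frame_interval`
#'   must describe the stack.
#' @param grid_origin optional (x, y) of the analysis-box top-left corner
#'   (um); default centers the box on the mean centroid.
#' @return A `wave_analysis` list: `trajectory`, `trajectory_fit`,
#'   `front`/`rear` regions, raw and normalized traces, `phases`,
#'   `front_rise`/`rear_rise`/`front_decay`/`rear_decay` fits,
#'   `map_rise`/`map_decay`, `gradient`, `gradient_slope`,
#'   `direction_angle_deg`, `velocity`, `diffusion`, `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(stack, mask_stack, config = pipeline_config(),
                         grid_origin = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(mask_stack)) stopf("mask stack is required")
  if (!identical(dim(stack), dim(mask_stack)))
    stopf("stack and mask_stack differ in shape")
  px <- config$pixel_size; dt <- config$frame_interval
  nf <- dim(stack)[3]
  times <- (seq_len(nf) - 1) * dt

  traj <- stage("centroids", {
    pts <- t(vapply(seq_len(nf),
                    function(f) compute_centroid(mask_stack[, , f], px),
                    numeric(2)))
    trajectory(times, pts)
  })
  tfit <- stage("trajectory_fit", fit_trajectory(traj))
  centroid <- c(mean(traj$x), mean(traj$y))
  fr <- stage("front_rear",
              define_front_rear(tfit, centroid,
                                x_offset = config$x_offset,
                                diameter = config$region_diameter))

  norm_fun <- if (config$normalization == "inverted")
    normalize_inverted else normalize_minmax
  get_trace <- function(region)
    extract_region_trace(stack, region, px, dt, mask_stack = mask_stack)
  tr_front <- stage("front_trace", get_trace(fr$front))
  tr_rear <- stage("rear_trace", get_trace(fr$rear))
  n_front <- stage("normalize", norm_fun(tr_front))
  n_rear <- stage("normalize", norm_fun(tr_rear))

  # shared phase windows from the whole-cell mean trace
  whole <- stage("whole_cell_trace", {
    vals <- vapply(seq_len(nf), function(f) {
      sel <- mask_stack[, , f] > 0
      if (any(sel)) mean(stack[, , f][sel]) else NA_real_
    }, numeric(1))
    norm_fun(intensity_trace(times, vals, valid = is.finite(vals)))
  })
  phases <- stage("segment_phases",
                  segment_phases(whole, min_amplitude = config$min_amplitude,
                                 smooth_window = config$smooth_window))
  rise_w <- first_window(phases, "rise")
  decay_w <- first_window(phases, "decay")
  if (is.null(rise_w)) stopf("pipeline stage 'segment_phases': no rise phase found")

  fit_in <- function(ntrace, w)
    fit_sigmoid(ntrace, window = w, direction = w$direction,
                max_abs_slope = config$max_abs_slope)
  f_rise <- stage("front_rise_fit", fit_in(n_front, rise_w))
  r_rise <- stage("rear_rise_fit", fit_in(n_rear, rise_w))
  f_decay <- if (!is.null(decay_w))
    stage("front_decay_fit", fit_in(n_front, decay_w)) else NULL
  r_decay <- if (!is.null(decay_w))
    stage("rear_decay_fit", fit_in(n_rear, decay_w)) else NULL

  gspec <- grid_spec(
    origin = if (is.null(grid_origin))
      centroid - c(config$grid_width, config$grid_height) / 2
    else as.numeric(grid_origin),
    width = config$grid_width, height = config$grid_height,
    n_rows = config$n_rows, n_cols = config$n_cols)
  mean_mask <- (apply(mask_stack, c(1, 2), mean) >= 0.5) * 1
  part <- stage("partition_grid", partition_grid(gspec, mean_mask, px))
  map_rise <- stage("kinetic_map_rise",
                    build_kinetic_map(stack, part, phase = rise_w,
                                      normalize = config$normalization,
                                      pixel_size = px, frame_interval = dt,
                                      mask_stack = mask_stack,
                                      coverage_threshold = config$coverage_threshold,
                                      rss_per_point = config$rss_per_point))
  map_decay <- if (!is.null(decay_w)) tryCatch(
    build_kinetic_map(stack, part, phase = decay_w,
                      normalize = config$normalization,
                      pixel_size = px, frame_interval = dt,
                      mask_stack = mask_stack,
                      coverage_threshold = config$coverage_threshold,
                      rss_per_point = config$rss_per_point),
    error = function(e) NULL) else NULL

  grad <- stage("gradient", gradient_field(map_rise))
  gslope <- gradient_slope(grad)
  angle <- stage("direction", compare_direction(tfit, grad))

  vel <- stage("velocity", {
    if (config$velocity_method == "front_rear")
      estimate_velocity(f_rise, r_rise, fr$front, fr$rear,
                        frame_interval = dt)
    else velocity_from_gradient(grad)
  })
  rep_slope <- mean(map_rise$abs_slope[map_rise$valid], na.rm = TRUE)
  diff_est <- if (is.finite(vel$v) && is.finite(rep_slope) && rep_slope > 0)
    estimate_diffusion(vel$v, rep_slope, method = config$diffusion_method)
  else list(D = NA_real_, method = config$diffusion_method)

  structure(list(trajectory = traj, trajectory_fit = tfit,
                 centroid = centroid, front = fr$front, rear = fr$rear,
                 trace_front = tr_front, trace_rear = tr_rear,
                 norm_front = n_front, norm_rear = n_rear,
                 phases = phases,
                 front_rise = f_rise, rear_rise = r_rise,
                 front_decay = f_decay, rear_decay = r_decay,
                 map_rise = map_rise, map_decay = map_decay,
                 gradient = grad, gradient_slope = gslope,
                 direction_angle_deg = angle,
                 velocity = vel, diffusion = diff_est,
                 config = config, config_hash = config_hash(config)),
            class = "wave_analysis")
}

#' @export
print.wave_analysis <- function(x, ...) {
  cat("<wave_analysis>\n")
  cat(sprintf("  migration slope %.3f (direction %+d), R2 %.3f\n",
              x$trajectory_fit$slope, x$trajectory_fit$direction_sign,
              x$trajectory_fit$r_squared))
  cat(sprintf("  front rise: a %.4g 1/s, b %.4g s | rear rise: a %.4g 1/s, b %.4g s\n",
              x$front_rise$a, x$front_rise$b, x$rear_rise$a, x$rear_rise$b))
  cat(sprintf("  gradient slope %.3f, migration/wave-source angle %.1f deg\n",
              x$gradient_slope$slope, x$direction_angle_deg))
  cat(sprintf("  v = %.3g um/s (%s), D = %.3g um^2/s (%s)\n",
              x$velocity$v, x$velocity$method,
              x$diffusion$D, x$diffusion$method))
  invisible(x)
}

write_matrix_csv <- function(m, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", stamp), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits the result bundle as plain-text files (CSV matrices and JSON
#' estimates); every file carries the configuration hash and seed.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "wave_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("config_hash=%s seed=%d", result$config_hash,
                   result$config$seed)
  files <- character(0)
  put <- function(name) { f <- file.path(dir, name); files <<- c(files, f); f }

  df <- as.data.frame(result$trajectory)
  f <- put("trajectory.csv")
  writeLines(sprintf("# %s", stamp), f)
  suppressWarnings(utils::write.table(df, f, sep = ",", row.names = FALSE,
                                      append = TRUE))
  tr <- data.frame(time_s = result$trace_front$times,
                   front_raw = result$trace_front$values,
                   rear_raw = result$trace_rear$values,
                   front_level = result$norm_front$values,
                   rear_level = result$norm_rear$values)
  f <- put("front_rear_traces.csv")
  writeLines(sprintf("# %s", stamp), f)
  suppressWarnings(utils::write.table(tr, f, sep = ",", row.names = FALSE,
                                      append = TRUE))
  fits <- do.call(rbind, lapply(
    Filter(Negate(is.null),
           list(front_rise = result$front_rise, rear_rise = result$rear_rise,
                front_decay = result$front_decay,
                rear_decay = result$rear_decay)),
    function(ft) data.frame(direction = ft$direction, a_per_s = ft$a,
                            abs_a_per_s = abs(ft$a), b_s = ft$b,
                            rss = ft$rss, converged = ft$converged)))
  fits <- cbind(region = rownames(fits), fits)
  f <- put("sigmoid_fits.csv")
  writeLines(sprintf("# %s", stamp), f)
  suppressWarnings(utils::write.table(fits, f, sep = ",", row.names = FALSE,
                                      append = TRUE))
  write_matrix_csv(result$map_rise$abs_slope,
                   put("map_rise_abs_slope.csv"), stamp)
  write_matrix_csv(result$map_rise$halftime,
                   put("map_rise_halftime.csv"), stamp)
  if (!is.null(result$map_decay)) {
    write_matrix_csv(result$map_decay$abs_slope,
                     put("map_decay_abs_slope.csv"), stamp)
    write_matrix_csv(result$map_decay$halftime,
                     put("map_decay_halftime.csv"), stamp)
  }
  write_matrix_csv(result$gradient$gx, put("gradient_gx.csv"), stamp)
  write_matrix_csv(result$gradient$gy, put("gradient_gy.csv"), stamp)
  jsonlite::write_json(
    list(config_hash = result$config_hash, seed = result$config$seed,
         migration_slope = result$trajectory_fit$slope,
         direction_sign = result$trajectory_fit$direction_sign,
         gradient_slope = result$gradient_slope$slope,
         direction_angle_deg = result$direction_angle_deg,
         velocity_um_per_s = result$velocity$v,
         velocity_method = result$velocity$method,
         diffusion_um2_per_s = result$diffusion$D,
         diffusion_method = result$diffusion$method),
    put("estimates.json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}
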