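# TIFF stack I/O and pipeline configuration. Stacks are stored as 16-bit
# grayscale multi-frame TIFF with an intensity scale recorded in a JSON
# sidecar (<path>.json), so arbitrary-unit intensities survive the trip.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-frame grayscale TIFF stack
#'
#' Intensities are divided by `scale`, quantized to 16 bits and written one
#' frame per TIFF directory; `scale`, `pixel_size` and `frame_interval` go
#' to a JSON sidecar next to the file. Values are pre-rounded to the 16-bit
#' grid so a write/read round trip is exact for already-quantized data.
#'
#' @param stack numeric array `[rows, cols, frames]`, non-negative.
#' @param path output file path.
#' @param pixel_size,frame_interval acquisition metadata for the sidecar.
#' @param scale intensity corresponding to the 16-bit maximum; default the
#'   stack maximum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size = NA, frame_interval = NA,
                        scale = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  if (min(stack) < 0) stopf("negative intensities cannot be stored; offset first")
  if (is.null(scale)) scale <- max(stack)
  if (scale <= 0) scale <- 1
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    q <- pmin(stack[, , f] / scale, 1)
    round(q * 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size = pixel_size,
                            frame_interval = frame_interval,
                            scale = scale, n_frames = dim(stack)[3],
                            bits = 16L),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' @param path TIFF file written by [write_stack()] (or any grayscale
#'   multi-frame TIFF; without a sidecar the scale defaults to 1 and
#'   metadata must come from the arguments).
#' @param pixel_size,frame_interval override the sidecar values; a
#'   conflicting override wins with a warning.
#' @return Numeric array `[rows, cols, frames]` with attributes
#'   `pixel_size`, `frame_interval`, `scale`.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) > 2L, logical(1))))
    stopf("unsupported TIFF layout: multi-channel (RGB) frames in %s", path)
  meta <- list(pixel_size = NA, frame_interval = NA, scale = 1)
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- utils::modifyList(meta, jsonlite::read_json(sp))
  for (fld in c("pixel_size", "frame_interval")) {
    ov <- get(fld)
    if (!is.null(ov)) {
      if (!is.na(meta[[fld]]) && !isTRUE(all.equal(ov, meta[[fld]])))
        warning(sprintf("%s: argument (%g) overrides sidecar (%g)",
                        fld, ov, as.numeric(meta[[fld]])), call. = FALSE)
      meta[[fld]] <- ov
    }
  }
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames))
    arr[, , f] <- round(frames[[f]] * 65535) / 65535 * as.numeric(meta$scale)
  attr(arr, "pixel_size") <- as.numeric(meta$pixel_size)
  attr(arr, "frame_interval") <- as.numeric(meta$frame_interval)
  attr(arr, "scale") <- as.numeric(meta$scale)
  arr
}

#' Write a binary mask stack (0/255 8-bit TIFF)
#'
#' @param mask 0/1 array `[rows, cols, frames]`.
#' @param path output file path.
#' @export
write_mask_stack <- function(mask, path) {
  stopifnot(length(dim(mask)) == 3L)
  if (!all(mask %in% c(0, 1)))
    stopf("mask must contain only 0 and 1")
  frames <- lapply(seq_len(dim(mask)[3]),
                   function(f) matrix(as.numeric(mask[, , f] > 0),
                                      dim(mask)[1], dim(mask)[2]))
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask stack
#'
#' @param path 8-bit TIFF whose pixel values are all 0 or 255.
#' @return 0/1 integer array `[rows, cols, frames]`.
#' @export
read_mask_stack <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0L, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) {
    v <- frames[[f]]
    if (!all(v %in% c(0, 1)))
      stopf("mask %s has values other than {0, 255}", path)
    arr[, , f] <- as.integer(v)
  }
  arr
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with validation; each
#' numeric field is checked on construction and the violated constraint is
#' named in the error.
#'
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param grid_width,grid_height analysis-box size (um), defaults 45 x 35.
#' @param n_rows,n_cols grid tile counts, defaults 7 x 7.
#' @param region_diameter front/rear region diameter (um), default 11.
#' @param x_offset front/rear x offset from the centroid (um), default 20.
#' @param normalization `"inverted"` or `"minmax"`.
#' @param coverage_threshold minimum tile mask coverage, default 0.5.
#' @param rss_per_point per-sample residual cutoff for valid tiles.
#' @param max_abs_slope sigmoid slope bound (1/s).
#' @param min_amplitude phase-segmentation amplitude threshold.
#' @param smooth_window phase-segmentation smoothing width (frames).
#' @param velocity_method `"front_rear"` or `"gradient"`.
#' @param diffusion_method diffusion estimator tag.
#' @param seed integer seed recorded in all outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size = 0.65, frame_interval = 5,
                            grid_width = 45, grid_height = 35,
                            n_rows = 7, n_cols = 7,
                            region_diameter = 11, x_offset = 20,
                            normalization = c("inverted", "minmax"),
                            coverage_threshold = 0.5, rss_per_point = 0.02,
                            max_abs_slope = 10, min_amplitude = 0.5,
                            smooth_window = 3,
                            velocity_method = c("front_rear", "gradient"),
                            diffusion_method = "v2_over_a", seed = 1) {
  normalization <- match.arg(normalization)
  velocity_method <- match.arg(velocity_method)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict = TRUE)
  check_scalar(grid_width, "grid_width", lower = 0, strict = TRUE)
  check_scalar(grid_height, "grid_height", lower = 0, strict = TRUE)
  check_scalar(n_rows, "n_rows", lower = 1)
  check_scalar(n_cols, "n_cols", lower = 1)
  check_scalar(region_diameter, "region_diameter", lower = 0, strict = TRUE)
  check_scalar(x_offset, "x_offset", lower = 0, strict = TRUE)
  check_scalar(coverage_threshold, "coverage_threshold", lower = 0, upper = 1)
  check_scalar(rss_per_point, "rss_per_point", lower = 0, strict = TRUE)
  check_scalar(max_abs_slope, "max_abs_slope", lower = 0, strict = TRUE)
  check_scalar(min_amplitude, "min_amplitude", lower = 0, upper = 1)
  check_scalar(smooth_window, "smooth_window", lower = 1)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 grid_width = grid_width, grid_height = grid_height,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 region_diameter = region_diameter, x_offset = x_offset,
                 normalization = normalization,
                 coverage_threshold = coverage_threshold,
                 rss_per_point = rss_per_point,
                 max_abs_slope = max_abs_slope,
                 min_amplitude = min_amplitude,
                 smooth_window = as.integer(smooth_window),
                 velocity_method = velocity_method,
                 diffusion_method = diffusion_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   unknown keys are rejected.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), names(formals(pipeline_config)))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  plain <- unclass(config)
  jsonlite::write_json(plain[order(names(plain))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}
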