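# Normalization, ratiometric correction, region traces, kymographs.

test_that("inverted normalization reproduces the defining formulas", {
  expect_equal(normalize_inverted(intensity_trace(0:2, c(10, 8, 6)))$values,
               c(0, 0.5, 1))
  # Ia = [0, -4, -2], divided by min(Ia) = -4
  expect_equal(normalize_inverted(intensity_trace(0:2, c(7, 3, 5)))$values,
               c(0, 1, 0.5))
  expect_error(normalize_inverted(intensity_trace(0:2, c(5, 5, 5))),
               "constant")
})

test_that("min-max normalization reproduces the defining formulas", {
  expect_equal(normalize_minmax(intensity_trace(0:2, c(2, 4, 6)))$values,
               c(0, 0.5, 1))
  expect_equal(normalize_minmax(intensity_trace(0:2, c(1, 9, 5)))$values,
               c(0, 1, 0.5))
  expect_error(normalize_minmax(intensity_trace(0:2, c(3, 3, 3))),
               "constant")
})

test_that("normalizations are affine-invariant, span [0,1], and are dual", {
  set.seed(42)
  for (rep in 1:20) {
    v <- runif(25, 10, 200)
    tr <- intensity_trace(seq_along(v), v)
    gain <- runif(1, 0.1, 10); offset <- runif(1, -50, 50)
    tr2 <- intensity_trace(seq_along(v), gain * v + offset)
    for (f in list(normalize_inverted, normalize_minmax)) {
      n1 <- f(tr); n2 <- f(tr2)
      expect_equal(n1$values, n2$values, tolerance = 1e-10)
      expect_equal(range(n1$values), c(0, 1))
    }
    # inverted(c - x) == minmax(x) for any c >= max(x)
    cc <- max(v) + runif(1, 0, 10)
    expect_equal(normalize_inverted(intensity_trace(seq_along(v), cc - v))$values,
                 normalize_minmax(tr)$values, tolerance = 1e-10)
  }
})

test_that("invalid samples are excluded from normalization and flagged NA", {
  tr <- intensity_trace(1:5, c(10, 8, 999, 6, 7),
                        valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  out <- normalize_inverted(tr)
  expect_true(is.na(out$values[3]))
  expect_equal(range(out$values[out$valid]), c(0, 1))
})

test_that("ratio of proportional channels is constant and shading cancels", {
  s <- array(runif(4 * 5 * 3, 50, 100), c(4, 5, 3))
  expect_equal(compute_ratio(2 * s, s), array(2, dim(s)))
  # shared multiplicative field cancels
  g <- pixel_grid(4, 5, 1)
  shade <- outer(g$y, g$x, function(y, x) 1 + 0.5 * sin(x) * cos(y))
  sh <- array(rep(shade, 3), dim(s))
  expect_equal(compute_ratio(2 * s * sh, s * sh), array(2, dim(s)),
               tolerance = 1e-12)
  expect_error(compute_ratio(s, s - 200), "non-positive")
})

test_that("ratiometric pair: shading field cancels in the ratio pipeline", {
  shade_fun <- function(x, y) 1 + 0.4 * sin(x / 9) * cos(y / 7) + 0.002 * x
  sp_flat <- quiet_movie()
  sp_shade <- quiet_movie(shading = shade_fun)
  p_flat <- generate_ratiometric_pair(sp_flat)
  p_shade <- generate_ratiometric_pair(sp_shade)
  r_flat <- compute_ratio(p_flat$reference, p_flat$sensor, p_flat$mask)
  r_shade <- compute_ratio(p_shade$reference, p_shade$sensor, p_shade$mask)
  inside <- p_flat$mask > 0
  expect_equal(r_shade[inside], r_flat[inside], tolerance = 1e-10)
})

test_that("ratio trace rises monotonically with the ground-truth signal", {
  pr <- generate_ratiometric_pair(quiet_movie())
  ratio <- compute_ratio(pr$reference, pr$sensor, pr$mask)
  ctr <- as.numeric(pr$ground_truth$centroids[1, c("x_um", "y_um")])
  tr <- extract_region_trace(ratio, region_spec(ctr, 11),
                             pr$spec$pixel_size, pr$spec$frame_interval,
                             mask_stack = pr$mask)
  expect_true(all(diff(tr$values) >= -1e-12))
  # reference channel alone is constant in time at noise 0
  rtr <- extract_region_trace(pr$reference, region_spec(ctr, 11),
                              pr$spec$pixel_size, pr$spec$frame_interval,
                              mask_stack = pr$mask)
  expect_equal(diff(range(rtr$values)), 0)
})

test_that("region traces average the circle, flag empty frames, and error when always empty", {
  stack <- array(7, c(20, 20, 3))
  tr <- extract_region_trace(stack, region_spec(c(10, 10), 8), 1, 5)
  expect_equal(tr$values, c(7, 7, 7))
  # half 0 / half 10 split on a pixel-aligned edge: mean 5 up to discretization
  img <- matrix(0, 40, 40); img[, 21:40] <- 10
  stack2 <- array(img, c(40, 40, 1))
  reg <- region_spec(c(20, 20), 11)
  tr2 <- extract_region_trace(stack2, reg, 1, 5)
  # pixel-counting oracle
  g <- pixel_grid(40, 40, 1)
  inc <- outer((g$y - 20)^2, (g$x - 20)^2, `+`) <= 5.5^2
  expect_equal(tr2$values[1], mean(img[inc]))
  expect_lt(abs(tr2$values[1] - 5), 0.5)
  # mask gating: region entirely outside the mask in all frames errors
  mask <- array(0L, dim(stack))
  expect_error(extract_region_trace(stack, region_spec(c(10, 10), 4), 1, 5,
                                    mask_stack = mask), "no pixels")
  # partially masked frames are flagged, not zeroed
  mask[, , 2] <- 1L
  tr3 <- extract_region_trace(stack, region_spec(c(10, 10), 4), 1, 5,
                              mask_stack = mask)
  expect_equal(tr3$valid, c(FALSE, TRUE, FALSE))
  expect_true(is.na(tr3$values[1]))
})

test_that("kymograph of a static ramp repeats rows; width 1 px is the line profile", {
  img <- matrix(rep(seq_len(30), each = 30), 30, 30)  # ramp along x
  stack <- array(rep(img, 4), c(30, 30, 4))
  ky <- build_kymograph(stack, rbind(c(2, 15), c(28, 15)), width = 6,
                        pixel_size = 1, frame_interval = 5)
  for (f in 2:4) expect_equal(ky$matrix[f, ], ky$matrix[1, ])
  expect_true(all(diff(ky$matrix[1, ]) > 0))
  ky1 <- build_kymograph(stack, rbind(c(2, 15), c(28, 15)), width = 1,
                         pixel_size = 1, frame_interval = 5)
  prof <- img[15, 3:28]
  expect_equal(ky1$matrix[1, ], as.numeric(prof))
})

test_that("kymograph of a noiseless wave movie shows a straight 0.5-contour of slope 1/v", {
  mv <- generate_wave_movie(quiet_movie())
  sp <- mv$spec; gt <- mv$ground_truth
  ctr <- as.numeric(gt$centroids[1, c("x_um", "y_um")])
  u <- -gt$wave_direction   # along the cell's long axis, against propagation
  seg <- rbind(ctr - 15 * u, ctr + 15 * u)
  ky <- build_kymograph(mv$stack, seg, width = 4, pixel_size = sp$pixel_size,
                        frame_interval = sp$frame_interval)
  mid <- sp$baseline - sp$amplitude / 2
  cross <- vapply(seq_len(ncol(ky$matrix)), function(k) {
    v <- ky$matrix[, k]
    i <- which(v <= mid)[1]   # inverted sensor: intensity falls through mid
    if (is.na(i) || i == 1) return(NA_real_)
    ky$times[i - 1] + (mid - v[i - 1]) / (v[i] - v[i - 1]) *
      (ky$times[i] - ky$times[i - 1])
  }, numeric(1))
  ok <- is.finite(cross)
  slope <- oracle_ols_slope(ky$positions[ok], cross[ok])
  expect_equal(abs(slope), 1 / gt$true_speed, tolerance = 0.05)
})
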