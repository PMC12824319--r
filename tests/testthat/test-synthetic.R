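# Synthetic-data generators: ground-truth consistency and determinism.

test_that("wave movie interior traces follow the analytic logistic exactly", {
  mv <- generate_wave_movie(quiet_movie())
  gt <- mv$ground_truth
  px <- mv$spec$pixel_size
  times <- (seq_len(dim(mv$stack)[3]) - 1) * mv$spec$frame_interval
  # three fixed interior pixels
  ctr <- as.numeric(gt$centroids[1, c("x_um", "y_um")])
  for (off in list(c(0, 0), c(10, 5), c(-12, -8))) {
    p <- ctr + off
    i <- round(p[2] / px + 0.5); j <- round(p[1] / px + 0.5)
    xc <- (j - 0.5) * px; yc <- (i - 0.5) * px
    b <- gt$halftime_field(xc, yc)
    expected <- mv$spec$baseline -
      mv$spec$amplitude * logistic(times, gt$true_slope, b)
    expect_equal(mv$stack[i, j, ], expected, tolerance = 0)
  }
})

test_that("ground-truth half-times are affine: separation d along the wave gives d/v", {
  mv <- generate_wave_movie(quiet_movie())
  gt <- mv$ground_truth
  w <- gt$wave_direction
  p0 <- c(40, 30)
  for (d in c(3, 10, 25.5)) {
    p1 <- p0 + d * w
    expect_equal(gt$halftime_field(p1[1], p1[2]) -
                   gt$halftime_field(p0[1], p0[2]),
                 d / gt$true_speed, tolerance = 1e-12)
  }
})

test_that("identical spec and seed give bit-identical output", {
  sp <- movie_spec(n_frames = 8, seed = 7)
  m1 <- generate_wave_movie(sp)
  m2 <- generate_wave_movie(sp)
  expect_identical(m1$stack, m2$stack)
  expect_identical(m1$mask, m2$mask)
  tr1 <- generate_trace(0.1, 40, seq(0, 100, 5), noise_sd = 0.05, seed = 3)
  tr2 <- generate_trace(0.1, 40, seq(0, 100, 5), noise_sd = 0.05, seed = 3)
  expect_identical(tr1$values, tr2$values)
  tj1 <- generate_trajectory(0.3, 0.1, 20, noise_sd = 0.5, seed = 5)
  tj2 <- generate_trajectory(0.3, 0.1, 20, noise_sd = 0.5, seed = 5)
  expect_identical(tj1$x, tj2$x)
})

test_that("generator does not disturb the ambient RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_wave_movie(movie_spec(n_frames = 6, seed = 1)))
  expect_identical(runif(1), a)
})

test_that("an explicit frame too small for the cell names the offending frame", {
  sp <- movie_spec(n_frames = 10, frame_dim = c(60, 60), cell_center0 = c(20, 20))
  expect_error(generate_wave_movie(sp), "frame 1")
})

test_that("generate_trace matches the logistic formula at key points", {
  tr <- generate_trace(a = 0.2, b = 30, times = c(0, 30, 60))
  expect_equal(tr$values[2], 0.5)
  expect_equal(tr$values[1], 1 / (1 + exp(6)), tolerance = 1e-12)
  # monotone rise at noise 0
  tr2 <- generate_trace(0.2, 30, seq(0, 60, 5))
  expect_true(all(diff(tr2$values) >= 0))
  # decay is the mirror
  tr3 <- generate_trace(0.2, 30, seq(0, 60, 5), direction = "decay")
  expect_equal(tr3$values, 1 - tr2$values)
})

test_that("noiseless trajectories lie exactly on the requested line", {
  tj <- generate_trajectory(slope = 0.42, speed = 0.1, n = 30)
  expect_equal(oracle_ols_slope(tj$x, tj$y), 0.42, tolerance = 1e-12)
  expect_equal(fit_trajectory(tj)$slope, 0.42, tolerance = 1e-12)
  # slope 0: constant y
  tj0 <- generate_trajectory(0, 0.1, 10)
  expect_true(all(tj0$y == tj0$y[1]))
  # negative speed encodes direction
  tjn <- generate_trajectory(0.42, -0.1, 10)
  expect_lt(tjn$x[10], tjn$x[1])
  expect_equal(fit_trajectory(tjn)$direction_sign, -1)
})

test_that("noisy trajectory slope refits near truth (regression oracle)", {
  tj <- generate_trajectory(0.42, 0.1, n = 60, dt = 5, noise_sd = 0.5, seed = 11)
  s_oracle <- oracle_ols_slope(tj$x, tj$y)
  expect_equal(fit_trajectory(tj)$slope, s_oracle, tolerance = 1e-10)
  expect_lt(abs(s_oracle - 0.42), 0.05)
})

test_that("biphasic calcium traces have two peaks propagating from each origin", {
  bp <- generate_biphasic_calcium(noise_sd = 0, seed = 1)
  for (i in c(1, 4, 7)) for (j in c(1, 4, 7)) {
    tr <- bp$traces[[i, j]]
    expect_equal(count_peaks(tr$values), 2)
    # peak times recovered by argmax within one frame interval
    dt <- diff(tr$times)[1]
    k1 <- which(tr$times < mean(c(bp$peak_time1[i, j], bp$peak_time2[i, j])))
    t_pk1 <- tr$times[k1][which.max(tr$values[k1])]
    expect_lte(abs(t_pk1 - bp$peak_time1[i, j]), dt)
  }
  # each phase's origin tile activates first
  expect_equal(which.min(bp$rise_halftime1),
               (bp$first_origin[2] - 1) * 7 + bp$first_origin[1])
  expect_equal(which.min(bp$rise_halftime2),
               (bp$second_origin[2] - 1) * 7 + bp$second_origin[1])
  # onset delay grows with distance from the origin
  d <- sqrt((row(bp$rise_halftime1) - 1)^2 + (col(bp$rise_halftime1) - 1)^2)
  expect_true(all(diff(bp$rise_halftime1[order(d)]) >= 0))
})

test_that("mask centroid matches the analytic ellipse center to < 0.5 px", {
  mv <- generate_wave_movie(movie_spec(n_frames = 6, noise_sd = 0))
  px <- mv$spec$pixel_size
  for (f in c(1, 6)) {
    truth <- as.numeric(mv$ground_truth$centroids[f, c("x_um", "y_um")])
    got <- compute_centroid(mv$mask[, , f], px)
    expect_lt(max(abs(got - truth)), 0.5 * px)
  }
})
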