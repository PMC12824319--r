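# Kinetic maps, finite-difference gradients, direction, velocity, diffusion.

test_that("gradient of a constant map is zero with undefined slope", {
  km <- kinetic_map(matrix(42, 7, 7), dx = 6.429, dy = 5)
  gf <- gradient_field(km)
  expect_true(all(gf$gx == 0))
  expect_true(all(gf$gy == 0))
  expect_false(gradient_slope(gf)$defined)
})

test_that("all 49 stencil positions are exact on affine maps (brute-force oracle)", {
  dx <- 45 / 7; dy <- 5
  # the worked case T = alpha*i + beta*j (0-based indices), alpha=2, beta=3
  iz <- matrix(rep(0:6, 7), 7, 7)          # 0-based row index
  jz <- t(iz)                              # 0-based column index
  T0 <- 2 * iz + 3 * jz
  gf <- gradient_field(kinetic_map(T0, dx = dx, dy = dy))
  orc <- oracle_gradient(T0, dx, dy)
  expect_equal(gf$gx, orc$gx, tolerance = 1e-12)
  expect_equal(gf$gy, orc$gy, tolerance = 1e-12)
  expect_equal(gf$mean_gx, 3 / dx, tolerance = 1e-12)
  expect_equal(gf$mean_gy, 2 / dy, tolerance = 1e-12)
  expect_equal(round(gf$mean_gx, 4), 0.4667)
  expect_equal(gradient_slope(gf)$slope, (2 / dy) / (3 / dx),
               tolerance = 1e-12)
  expect_equal(round(gradient_slope(gf)$slope, 4), 0.8571)
  # random affine maps: every tile exact, edge and interior schemes agree
  set.seed(5)
  for (rep in 1:20) {
    al <- runif(1, -5, 5); be <- runif(1, -5, 5); c0 <- runif(1, 0, 100)
    T1 <- al * iz + be * jz + c0
    gf1 <- gradient_field(kinetic_map(T1, dx = dx, dy = dy))
    expect_equal(gf1$gx, matrix(be / dx, 7, 7), tolerance = 1e-9)
    expect_equal(gf1$gy, matrix(al / dy, 7, 7), tolerance = 1e-9)
  }
})

test_that("linear-in-column map gives uniform gx, zero gy, zero slope", {
  T0 <- matrix(rep(0:6, each = 7), 7, 7) * 4   # T = 4*j
  gf <- gradient_field(kinetic_map(T0, dx = 2, dy = 3))
  expect_true(all(abs(gf$gx - 2) < 1e-12))
  expect_true(all(gf$gy == 0))
  expect_equal(gradient_slope(gf)$slope, 0)
})

test_that("transposing the map and swapping tile sizes swaps the gradient components", {
  set.seed(9)
  T0 <- matrix(runif(49, 0, 60), 7, 7)
  g1 <- gradient_field(kinetic_map(T0, dx = 6.429, dy = 5))
  g2 <- gradient_field(kinetic_map(t(T0), dx = 5, dy = 6.429))
  expect_equal(g2$gx, t(g1$gy), tolerance = 1e-12)
  expect_equal(g2$gy, t(g1$gx), tolerance = 1e-12)
})

test_that("invalid tiles fall back to one-sided differences and stay exact on affine maps", {
  dx <- 6.429; dy <- 5
  iz <- matrix(rep(0:6, 7), 7, 7); jz <- t(iz)
  T0 <- 2 * iz + 3 * jz
  valid <- matrix(TRUE, 7, 7); valid[4, 4] <- FALSE
  gf <- gradient_field(kinetic_map(T0, dx = dx, dy = dy, valid = valid))
  expect_true(is.na(gf$gx[4, 4]) && is.na(gf$gy[4, 4]))
  fin <- is.finite(gf$gx)
  expect_true(all(abs(gf$gx[fin] - 3 / dx) < 1e-9))
  fin <- is.finite(gf$gy)
  expect_true(all(abs(gf$gy[fin] - 2 / dy) < 1e-9))
  # an isolated valid tile has no usable neighbours
  v2 <- matrix(FALSE, 7, 7); v2[1, 1] <- TRUE; v2[1, 2] <- TRUE
  v2[7, 6] <- TRUE; v2[6, 6] <- TRUE; v2[4, 4] <- TRUE
  gf2 <- gradient_field(kinetic_map(T0, dx = dx, dy = dy, valid = v2))
  expect_true(is.na(gf2$gx[4, 4]))
  expect_true(is.na(gf2$gy[4, 4]))
  expect_equal(gf2$gx[1, 1], 3 / dx, tolerance = 1e-9)   # forward to valid
  expect_equal(gf2$gy[7, 6], 2 / dy, tolerance = 1e-9)   # backward to valid
})

test_that("direction comparison handles parallel, orthogonal, and oriented cases", {
  expect_equal(compare_direction(c(1, 0.42), c(1, 0.42),
                                 orient = "propagation"), 0, tolerance = 1e-4)
  expect_equal(compare_direction(c(1, 0), c(0, 1),
                                 orient = "propagation"), 90)
  # wave traveling against migration = wave arrived from the front
  expect_equal(compare_direction(c(1, 0.42), -c(1, 0.42),
                                 orient = "source"), 0, tolerance = 1e-4)
  expect_equal(compare_direction(c(1, 0.42), c(1, 0.42),
                                 orient = "source"), 180, tolerance = 1e-4)
})

test_that("velocity estimator: worked example, scale invariance, reliability flag", {
  mkfit <- function(b) structure(list(a = 0.14, b = b, direction = "rise",
                                      rss = 0, n = 20, converged = TRUE,
                                      window = NULL), class = "sigmoid_fit")
  d <- 2 * sqrt(20^2 + 8.4^2)             # 43.39 um front-rear separation
  fr <- region_spec(c(0, 0)); rr <- region_spec(c(d, 0))
  est <- estimate_velocity(mkfit(100), mkfit(114.56), fr, rr)
  expect_equal(est$v, 2.98, tolerance = 1e-3)
  expect_true(est$reliable)
  # doubling both distance and half-time difference leaves v unchanged
  rr2 <- region_spec(c(2 * d, 0))
  est2 <- estimate_velocity(mkfit(100), mkfit(129.12), fr, rr2)
  expect_equal(est2$v, est$v, tolerance = 1e-12)
  # equal half-times: unreliable
  est3 <- estimate_velocity(mkfit(100), mkfit(100), fr, rr)
  expect_false(est3$reliable)
})

test_that("diffusion estimate follows its tagged formula", {
  expect_equal(estimate_diffusion(2, 0.1)$D, 40)
  expect_equal(estimate_diffusion(4, 0.1)$D, 160)       # scales as v^2
  expect_equal(estimate_diffusion(2.98, 0.139)$D, 63.9, tolerance = 1e-2)
  expect_equal(estimate_diffusion(1, 1)$method, "v2_over_a")
})

test_that("kinetic map of a noiseless movie matches the ground-truth half-time field", {
  mv <- generate_wave_movie(quiet_movie())
  sp <- mv$spec; gt <- mv$ground_truth
  ctr <- as.numeric(gt$centroids[1, c("x_um", "y_um")])
  gs <- grid_spec(origin = ctr - c(45, 35) / 2)
  part <- partition_grid(gs, (apply(mv$mask, c(1, 2), mean) >= 0.5) * 1,
                         sp$pixel_size)
  km <- build_kinetic_map(mv$stack, part,
                          phase = phase_window(0, 75, "rise"),
                          normalize = "inverted",
                          pixel_size = sp$pixel_size,
                          frame_interval = sp$frame_interval,
                          mask_stack = mv$mask)
  expect_true(all(km$valid))
  for (k in seq_len(nrow(part$tiles))) {
    tl <- part$tiles[k, ]
    b_true <- gt$halftime_field(tl$cx, tl$cy)
    expect_lt(abs(km$halftime[tl$row, tl$col] - b_true), sp$frame_interval)
  }
  # fitted half-times are monotone along the wave direction
  w <- gt$wave_direction
  proj <- part$tiles$cx * w[1] + part$tiles$cy * w[2]
  b_hat <- km$halftime[cbind(part$tiles$row, part$tiles$col)]
  expect_true(all(diff(b_hat[order(proj)]) > -1e-6))
  # and the map's gradient points along the wave to within a few degrees
  ang <- compare_direction(-w, gradient_field(km))   # migration = -w here
  expect_lt(ang, 5)
})

test_that("spatially uniform activation yields a flat half-time map", {
  sp <- quiet_movie(wave_speed = 1e9)   # effectively simultaneous everywhere
  mv <- generate_wave_movie(sp)
  ctr <- as.numeric(mv$ground_truth$centroids[1, c("x_um", "y_um")])
  part <- partition_grid(grid_spec(origin = ctr - c(45, 35) / 2),
                         (apply(mv$mask, c(1, 2), mean) >= 0.5) * 1,
                         sp$pixel_size)
  km <- build_kinetic_map(mv$stack, part, phase = phase_window(0, 75, "rise"),
                          normalize = "inverted",
                          pixel_size = sp$pixel_size,
                          frame_interval = sp$frame_interval,
                          mask_stack = mv$mask)
  bs <- km$halftime[km$valid]
  expect_lt(diff(range(bs)), 0.5)
})

test_that("an impossible coverage threshold invalidates every tile", {
  mv <- generate_wave_movie(quiet_movie(n_frames = 12))
  ctr <- as.numeric(mv$ground_truth$centroids[1, c("x_um", "y_um")])
  part <- partition_grid(grid_spec(origin = ctr - c(45, 35) / 2),
                         (apply(mv$mask, c(1, 2), mean) >= 0.5) * 1,
                         mv$spec$pixel_size)
  expect_error(
    build_kinetic_map(mv$stack, part, phase = phase_window(0, 55, "rise"),
                      normalize = "inverted",
                      pixel_size = mv$spec$pixel_size,
                      frame_interval = mv$spec$frame_interval,
                      mask_stack = mv$mask, coverage_threshold = 1.1),
    "all tiles invalid")
})
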