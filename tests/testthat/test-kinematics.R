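test_that("centroid is the mean of unmasked landmarks with a validity floor", {
  s <- pose_series(paste0("lm", 1:4),
                   x = rbind(c(0, 0, 2, 2)), y = rbind(c(0, 2, 0, 2)),
                   likelihood = rbind(rep(0.9, 4)), fps = 30)
  ce <- compute_centroid(s, min_valid_landmarks = 2)
  expect_equal(ce$x, 1)
  expect_equal(ce$y, 1)
  expect_true(ce$valid)

  # one masked landmark: mean of the remaining three, still valid
  s$x[1, 4] <- NA; s$y[1, 4] <- NA
  ce <- compute_centroid(s, min_valid_landmarks = 2)
  expect_equal(ce$x, mean(c(0, 0, 2)))
  expect_true(ce$valid)

  # all masked: invalid frame
  s$x[1, ] <- NA
  ce <- compute_centroid(s, min_valid_landmarks = 2)
  expect_false(ce$valid)
})

test_that("antenna landmarks are excluded from the centroid by default", {
  s <- pose_series(c("pm_left", "antenna_tip_left"),
                   x = rbind(c(10, 100)), y = rbind(c(10, 100)),
                   likelihood = rbind(c(0.9, 0.9)), fps = 30)
  expect_equal(compute_centroid(s, 1)$x, 10)
  expect_equal(compute_centroid(s, 1, exclude_pattern = NULL)$x, 55)
})

test_that("calibration maps pixels linearly and clamps out-of-bounds points", {
  arena <- arena_spec(scale_x = 0.25, scale_y = 0.25)
  tr <- trajectory(100, 40, fps = 30, units = "px")
  mm <- calibrate(tr, arena)
  expect_equal(mm$x, 25)
  expect_equal(mm$y, 10)

  ident <- arena_spec(scale_x = 1, scale_y = 1)
  tr <- trajectory(c(50, 120), c(30, 60), fps = 30, units = "px")
  mm <- calibrate(tr, ident)
  expect_equal(mm$x, c(50, 120))

  # a point 3 mm outside is clamped to the boundary with a warning
  tr <- trajectory(-3, 5, fps = 30, units = "px")
  expect_warning(mm <- calibrate(tr, ident), "clamped")
  expect_equal(mm$x, 0)
  expect_equal(mm$y, 5)
})

test_that("centroid and calibration commute under uniform scaling", {
  set.seed(21)
  arena <- arena_spec(scale_x = 0.25, scale_y = 0.25, origin_px = c(12, 7))
  for (i in 1:5) {
    s <- square_series(cx = runif(30, 50, 600), cy = runif(30, 50, 250),
                       half = runif(1, 0.5, 4))
    a <- calibrate(compute_centroid(s), arena)
    # calibrate each landmark first, then average
    sx <- (s$x - arena$origin_px[1]) * arena$scale_x
    sy <- (s$y - arena$origin_px[2]) * arena$scale_y
    expect_equal(a$x, rowMeans(sx), tolerance = 1e-12)
    expect_equal(a$y, rowMeans(sy), tolerance = 1e-12)
  }
})

test_that("short gaps are interpolated, long gaps split the trajectory", {
  tr <- trajectory(c(0, NA, 2), c(0, NA, 4), valid = c(TRUE, FALSE, TRUE),
                   fps = 30)
  fl <- interpolate_gaps(tr, 15)
  expect_equal(fl$x[2], 1)
  expect_equal(fl$y[2], 2)
  expect_true(all(fl$valid))

  # a 16-frame gap stays untouched at max_gap 15
  x <- c(0, rep(NA, 16), 17); v <- c(TRUE, rep(FALSE, 16), TRUE)
  tr <- trajectory(x, x, valid = v, fps = 30)
  fl <- interpolate_gaps(tr, 15)
  expect_equal(fl$valid, v)
  # but a 15-frame gap is bridged linearly
  x <- c(0, rep(NA, 15), 16); v <- c(TRUE, rep(FALSE, 15), TRUE)
  fl <- interpolate_gaps(trajectory(x, x, valid = v, fps = 30), 15)
  expect_true(all(fl$valid))
  expect_equal(fl$x, 0:16)

  # fully valid input is unchanged
  tr <- trajectory(1:10, 1:10, fps = 30)
  expect_identical(interpolate_gaps(tr, 15), tr)
})

test_that("leading/trailing invalid frames are never fabricated", {
  tr <- trajectory(c(NA, NA, 5, 6, NA), c(NA, NA, 5, 6, NA),
                   valid = c(FALSE, FALSE, TRUE, TRUE, FALSE), fps = 30)
  fl <- interpolate_gaps(tr, 15)
  expect_equal(fl$valid, tr$valid)
})

test_that("the smoother passes DC exactly and attenuates per the squared response", {
  fps <- 30
  tr <- trajectory(rep(5, 200), rep(3, 200), fps = fps, units = "mm")
  sm <- butterworth_smooth(tr, 2, 6)
  expect_lt(max(abs(sm$x - 5)), 1e-6)
  expect_lt(max(abs(sm$y - 3)), 1e-6)

  n <- 3000; t <- (0:(n - 1)) / fps
  measured_gain <- function(f_hz) {
    x <- 40 + 10 * sin(2 * pi * f_hz * t)
    y <- butterworth_smooth(trajectory(x, rep(40, n), fps = fps, units = "mm"),
                            2, 6)$x
    mid <- 1000:2000
    ft <- lm(y[mid] ~ sin(2 * pi * f_hz * t[mid]) + cos(2 * pi * f_hz * t[mid]))
    sqrt(sum(coef(ft)[2:3]^2)) / 10
  }
  # zero-phase squares the order-2 Butterworth magnitude: 1/2 at the cutoff
  expect_equal(measured_gain(6), 0.5, tolerance = 0.02)
  # far below the cutoff the squared analytic response 1/(1+(f/fc)^4) is ~1
  expect_gt(measured_gain(1), 0.99)
})

test_that("zero-phase filtering leaves a symmetric pulse symmetric", {
  x <- 20 + 30 * exp(-((0:400 - 200) / 20)^2)
  tr <- trajectory(x, rep(1, 401), fps = 30, units = "mm")
  y <- butterworth_smooth(tr, 2, 6)$x
  expect_lt(max(abs(y - rev(y))), 1e-9)
  # cross-correlation peaks at zero lag
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the smoother reduces white-noise variance and high-frequency energy", {
  set.seed(5)
  x <- rnorm(500)
  tr <- trajectory(x + 50, rep(40, 500), fps = 30, units = "mm")
  y <- butterworth_smooth(tr, 2, 6)$x - 50
  expect_lt(var(y), var(x))
  hi_band <- function(v) {
    sp <- Mod(fft(v))^2
    n <- length(v)
    f <- (0:(n - 1)) / n * 30
    sum(sp[f > 6 & f < 15])
  }
  expect_lt(hi_band(y), 0.2 * hi_band(x))
})

test_that("cutoff at or above Nyquist is a configuration error", {
  tr <- trajectory(1:100, 1:100, fps = 30, units = "mm")
  expect_error(butterworth_smooth(tr, 2, 15), "Nyquist")
  expect_error(butterworth_smooth(tr, 2, 20), "Nyquist")
})

test_that("segments too short to filter pass through unchanged", {
  v <- c(rep(TRUE, 5), FALSE, rep(TRUE, 100))
  x <- c(1:5, NA, cumsum(rnorm(100)) + 50)
  tr <- trajectory(x, x, valid = v, fps = 30)
  sm <- butterworth_smooth(tr, 2, 6)
  expect_equal(sm$x[1:5], 1:5)        # 5 <= 3 * order, untouched
  expect_false(isTRUE(all.equal(sm$x[7:106], x[7:106])))
})

test_that("speeds are distance times frame rate, valid only between valid frames", {
  tr <- trajectory(c(0, 1), c(0, 0), fps = 30)
  expect_equal(compute_speed(tr)$speed_mm_s, 30)
  tr <- trajectory(c(0, 3), c(0, 4), fps = 30)
  expect_equal(compute_speed(tr)$speed_mm_s, 150)  # 3-4-5 triangle
  tr <- trajectory(rep(2, 10), rep(2, 10), fps = 30)
  expect_true(all(compute_speed(tr)$speed_mm_s == 0))
  tr <- trajectory(c(0, NA, 2), c(0, NA, 2), valid = c(TRUE, FALSE, TRUE),
                   fps = 30)
  expect_equal(compute_speed(tr)$valid, c(FALSE, FALSE))
})

test_that("the speed gate removes the later frame, strictly above threshold, one pass", {
  # 10 mm jump at 30 fps = 300 mm/s > 230: later frame invalidated
  tr <- trajectory(c(0, 0, 10, 10), rep(0, 4), fps = 30)
  g <- apply_speed_gate(tr, compute_speed(tr), 230)
  expect_equal(g$valid, c(TRUE, TRUE, FALSE, TRUE))

  # exactly at the threshold: kept (23 mm steps at 10 fps = exactly 230 mm/s)
  tr <- trajectory(23 * (0:5), rep(0, 6), fps = 10)
  expect_equal(unique(compute_speed(tr)$speed_mm_s), 230)
  g <- apply_speed_gate(tr, compute_speed(tr), 230)
  expect_true(all(g$valid))

  # all-slow trajectory unchanged; first frame never invalidated
  tr <- trajectory(cumsum(c(0, rep(1, 9))), rep(0, 10), fps = 30)
  g <- apply_speed_gate(tr, compute_speed(tr), 230)
  expect_identical(g, tr)
})

test_that("re-gating after removing an isolated spike is a no-op", {
  set.seed(9)
  x <- cumsum(rnorm(200, 0, 0.5)) + 90
  x[100] <- x[100] + 20                     # single-frame spike
  tr <- trajectory(x, rep(40, 200), fps = 30)
  g1 <- apply_speed_gate(tr, compute_speed(tr), 230)
  expect_true(g1$valid[1])
  g2 <- apply_speed_gate(g1, compute_speed(g1), 230)
  expect_identical(g2, g1)
})

test_that("the full chain preserves the frame count at every stage", {
  cfg <- simulation_config(trial_duration_s = 30)
  sim <- simulate_trajectory(cfg, seed = 42)
  pose <- render_pose_table(sim)
  n <- pose$n_frames
  pc <- pipeline_config()
  masked <- apply_pcutoff(pose, pc$p_cutoff)
  expect_equal(masked$n_frames, n)
  ce <- compute_centroid(masked, pc$min_valid_landmarks)
  expect_equal(ce$n_frames, n)
  mm <- suppressWarnings(calibrate(ce, cfg$arena))
  fl <- interpolate_gaps(mm, pc$max_gap_frames)
  sm <- butterworth_smooth(fl, pc$filter_order, pc$filter_cutoff_hz)
  expect_equal(sm$n_frames, n)
  sp <- compute_speed(sm)
  expect_equal(length(sp$speed_mm_s), n - 1)
  g <- apply_speed_gate(sm, sp, pc$max_speed_mm_s)
  expect_equal(g$n_frames, n)
  proc <- suppressMessages(process_trajectory(pose, cfg$arena, pc))
  expect_equal(proc$trajectory$n_frames, n)
})
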