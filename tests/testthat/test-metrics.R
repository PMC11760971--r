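test_that("average speed is mean per-frame displacement expressed per second", {
  # uniform 2 mm per frame at 30 fps
  tr <- trajectory(cumsum(c(0, rep(2, 30))), rep(0, 31), fps = 30)
  expect_equal(average_speed(compute_speed(tr)), 60)
  # stationary
  tr <- trajectory(rep(5, 20), rep(5, 20), fps = 30)
  expect_equal(average_speed(compute_speed(tr)), 0)
  # five 1 mm intervals and five 0 mm intervals: (5/10) * 30
  x <- cumsum(c(0, rep(c(1, 0), 5)))
  tr <- trajectory(x, rep(0, 11), fps = 30)
  expect_equal(average_speed(compute_speed(tr)), 15)
})

test_that("the average-speed denominator option divides by all intervals", {
  x <- c(0, 1, NA, NA, 3)
  tr <- trajectory(x, rep(0, 5), valid = !is.na(x), fps = 30)
  sp <- compute_speed(tr)                     # 1 valid interval of 1 mm
  expect_equal(average_speed(sp, "valid"), 30)
  expect_equal(average_speed(sp, "total"), 30 / 4)
})

test_that("a trial without valid intervals is flagged undefined", {
  tr <- trajectory(c(1, NA, 3), c(1, NA, 3), valid = c(TRUE, FALSE, TRUE),
                   fps = 30)
  expect_warning(v <- average_speed(compute_speed(tr)), "undefined")
  expect_true(is.na(v))
})

test_that("walk bouts follow the strict threshold and inclusive duration rule", {
  fps <- 30
  # 45 supra-threshold intervals (1.5 s): one bout
  w <- detect_walks(speed_fixture(rep(15, 45)), 10, 1)
  expect_equal(nrow(w), 1)
  expect_equal(w$duration_s, 1.5)
  expect_equal(w$mean_speed_mm_s, 15)
  # 29 intervals (0.967 s): below the minimum
  expect_equal(nrow(detect_walks(speed_fixture(rep(15, 29)), 10, 1)), 0)
  # exactly 30 intervals (1.0 s): inclusive minimum, one bout
  expect_equal(nrow(detect_walks(speed_fixture(rep(15, 30)), 10, 1)), 1)
  # a single sub-threshold interval splits the run into two bouts
  w <- detect_walks(speed_fixture(c(rep(15, 40), 5, rep(15, 40))), 10, 1)
  expect_equal(nrow(w), 2)
  # speed exactly at the threshold does not count as walking
  expect_equal(nrow(detect_walks(speed_fixture(rep(10, 60)), 10, 1)), 0)
  # an invalid interval also terminates a run
  w <- detect_walks(speed_fixture(rep(15, 81),
                                  valid = c(rep(TRUE, 40), FALSE, rep(TRUE, 40))),
                    10, 1)
  expect_equal(nrow(w), 2)
})

test_that("bout frame indices delimit the supra-threshold intervals", {
  sp <- speed_fixture(c(rep(0, 10), rep(20, 35), rep(0, 5)))
  w <- detect_walks(sp, 10, 1)
  expect_equal(w$start_frame, 10)    # 0-based first frame of the run
  expect_equal(w$end_frame, 45)      # inclusive last frame
  expect_equal(w$duration_s, 35 / 30)
  # every interval inside the bout is supra-threshold (postcondition re-check)
  expect_true(all(sp$speed_mm_s[(w$start_frame + 1):w$end_frame] > 10))
})

test_that("walk detection agrees with the quadratic brute-force oracle on small fixtures", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    sp <- rexp(n, 1 / 12)
    valid <- runif(n) > 0.1
    got <- nrow(detect_walks(speed_fixture(sp, valid), 10, 0.5))
    expect_identical(got,
                     oracle_walk_count_bruteforce(sp, valid, 10, 0.5, 30))
  }
})

test_that("walk detection agrees with the independent grouping oracle on random series", {
  set.seed(32)
  for (i in 1:300) {
    n <- sample(10:600, 1)
    # mix of regimes so runs of many lengths occur
    sp <- abs(rnorm(n, mean = sample(c(5, 10, 12), 1), sd = 6))
    valid <- runif(n) > 0.05
    thr <- sample(c(8, 10), 1)
    got <- nrow(detect_walks(speed_fixture(sp, valid), thr, 1))
    expect_identical(got, oracle_walk_count(sp, valid, thr, 1, 30))
  }
})

test_that("zone membership uses floor indexing with the far-edge convention", {
  arena <- arena_spec()
  grid <- zone_grid(3, 6, arena)
  # stationary animal: one zone
  tr <- trajectory(rep(5, 10), rep(5, 10), fps = 30)
  expect_equal(zones_explored(tr, arena, grid), 1)
  # boustrophedon sweep through every cell centre: all 18 zones
  cx <- (seq_len(6) - 0.5) * arena$length_mm / 6
  cy <- (seq_len(3) - 0.5) * arena$width_mm / 3
  path <- do.call(rbind, lapply(seq_len(3), function(r) {
    xs <- if (r %% 2 == 1) cx else rev(cx)
    cbind(xs, cy[r])
  }))
  tr <- trajectory(path[, 1], path[, 2], fps = 30)
  expect_equal(zones_explored(tr, arena, grid), 18)
  # a point exactly on the far edge belongs to the last column
  tr <- trajectory(c(184, 185), c(5, 5), fps = 30)
  expect_equal(zones_explored(tr, arena, grid), 1)
})

test_that("zone count is monotone along trial prefixes", {
  set.seed(33)
  for (i in 1:20) {
    cfg <- simulation_config(trial_duration_s = 60)
    sim <- simulate_trajectory(cfg, seed = 500 + i)
    tr <- sim$trajectory
    lens <- sort(sample(2:tr$n_frames, 6))
    counts <- vapply(lens, function(L) {
      zones_explored(trajectory(tr$x[1:L], tr$y[1:L], fps = tr$fps),
                     cfg$arena)
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("metrics transform predictably under translation and scaling", {
  set.seed(34)
  cfg <- simulation_config(trial_duration_s = 120,
                           arena = arena_spec(1000, 1000))
  sim <- simulate_trajectory(cfg, seed = 77)
  tr <- sim$trajectory
  sp <- compute_speed(tr)
  w0 <- nrow(detect_walks(sp))
  v0 <- average_speed(sp)

  # translation leaves both walks and speed unchanged
  tt <- trajectory(tr$x + 3, tr$y + 7, fps = tr$fps)
  expect_equal(nrow(detect_walks(compute_speed(tt))), w0)
  expect_equal(average_speed(compute_speed(tt)), v0)

  # 180-degree rotation about the arena centre stays in bounds: invariant
  rot <- trajectory(1000 - tr$x, 1000 - tr$y, fps = tr$fps)
  expect_equal(average_speed(compute_speed(rot)), v0)
  expect_equal(nrow(detect_walks(compute_speed(rot))), w0)

  # scaling positions by c scales average speed by exactly c
  sc <- trajectory(tr$x * 2.5, tr$y * 2.5, fps = tr$fps)
  expect_equal(average_speed(compute_speed(sc)), 2.5 * v0, tolerance = 1e-12)
})

test_that("bout time never exceeds valid time and summaries are deterministic", {
  cfg <- simulation_config(trial_duration_s = 120)
  sim <- simulate_trajectory(cfg, seed = 12)
  pose <- render_pose_table(sim)
  proc <- suppressMessages(process_trajectory(pose, cfg$arena))
  w <- detect_walks(proc$speeds)
  expect_lte(sum(w$duration_s), sum(proc$speeds$valid) / proc$speeds$fps)

  row <- list(individual_id = "a", tag_group = "untagged",
              tag_type = "none", block = "b1")
  s1 <- summarize_trial(row, proc)
  s2 <- summarize_trial(row, proc)
  expect_identical(s1, s2)
  expect_equal(s1$n_walks, nrow(w))
})

test_that("a stationary trial summarises to zero speed, zero walks, one zone", {
  tr <- trajectory(rep(90, 100), rep(40, 100), fps = 30)
  proc <- list(trajectory = tr, speeds = compute_speed(tr))
  s <- summarize_trial(list(individual_id = "a", tag_group = "untagged",
                            tag_type = "none", block = "b1"), proc)
  expect_equal(s$avg_speed_mm_s, 0)
  expect_equal(s$n_walks, 0)
  expect_equal(s$n_zones_explored, 1)
})
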