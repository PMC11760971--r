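#' Simulation configuration
#'
#' Parameters of the synthetic open-field trial generator: a two-state
#' (pause/walk) renewal process with exponential state durations, a
#' correlated random walk at a gamma-distributed per-bout speed during
#' walks, wall-following (thigmotactic) heading bias near the arena walls,
#' and a landmark-level observation model (fixed body-frame landmark
#' offsets, Gaussian pixel jitter, likelihood dropout).
#'
#' @param trial_duration_s trial length (s); 1200 s = the 20-min measurement
#'   period of an open-field trial.
#' @param fps frame rate (Hz).
#' @param arena an [arena_spec()].
#' @param pause_duration_s mean of the exponential pause lengths (s).
#' @param walk_duration_s mean of the exponential walk-bout lengths (s).
#' @param walk_speed_mm_s mean per-bout speed (mm/s); bout speeds are
#'   gamma-distributed across bouts with shape `walk_speed_shape`.
#' @param walk_speed_shape gamma shape of the bout-speed distribution.
#' @param turning_sd_rad per-frame heading noise during walks (rad).
#' @param thigmotaxis_weight in [0, 1]: strength of the blend of the heading
#'   toward the nearest wall tangent within `thigmotaxis_margin_mm` of a
#'   wall (0 = none, 1 = full lock onto the wall).
#' @param thigmotaxis_margin_mm wall distance (mm) within which the bias
#'   acts, ramping linearly to full strength at the wall.
#' @param landmark_offsets_mm 4 x 2 matrix of body-frame landmark positions
#'   (mm, zero-mean so that the landmark average is the body centroid);
#'   rows: left/right prothorax-mesothorax boundary, left/right cerci.
#' @param jitter_sd_px per-landmark digitization noise (px).
#' @param dropout_prob probability that a landmark detection falls below
#'   the confidence cutoff in a frame.
#' @param p_cutoff confidence cutoff used to draw likelihood values
#'   (dropped-out landmarks get likelihoods uniform on [0, p_cutoff),
#'   retained ones uniform on [p_cutoff, 1]).
#' @param tag_speed_multiplier multiplicative tag effect: walk-initiation
#'   rate and bout speed of tagged individuals are multiplied by it
#'   (1 = null).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(trial_duration_s = 1200,
                              fps = 30,
                              arena = arena_spec(),
                              pause_duration_s = 20,
                              walk_duration_s = 3,
                              walk_speed_mm_s = 25,
                              walk_speed_shape = 4,
                              turning_sd_rad = 0.4,
                              thigmotaxis_weight = 0.7,
                              thigmotaxis_margin_mm = 20,
                              landmark_offsets_mm = default_landmarks(),
                              jitter_sd_px = 1.0,
                              dropout_prob = 0.02,
                              p_cutoff = 0.6,
                              tag_speed_multiplier = 1.0) {
  landmark_offsets_mm <- as.matrix(landmark_offsets_mm)
  stopifnot(trial_duration_s > 0, fps > 0, inherits(arena, "arena_spec"),
            pause_duration_s > 0, walk_duration_s > 0,
            walk_speed_mm_s > 0, walk_speed_shape > 0,
            turning_sd_rad >= 0,
            thigmotaxis_weight >= 0, thigmotaxis_weight <= 1,
            thigmotaxis_margin_mm > 0,
            ncol(landmark_offsets_mm) == 2, nrow(landmark_offsets_mm) >= 1,
            jitter_sd_px >= 0, dropout_prob >= 0, dropout_prob <= 1,
            p_cutoff >= 0, p_cutoff <= 1,
            tag_speed_multiplier > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Default body-frame landmark layout
#'
#' Four zero-mean body landmarks (mm): the left/right prothorax-mesothorax
#' boundary ahead of the body centre and the left/right cerci behind it.
#' Zero mean guarantees the landmark average reproduces the body centroid
#' exactly.
#' @return A 4 x 2 numeric matrix.
#' @export
default_landmarks <- function() {
  m <- rbind(pm_left = c(8, 5), pm_right = c(8, -5),
             cercus_left = c(-8, 4), cercus_right = c(-8, -4))
  colnames(m) <- c("x", "y")
  m
}

#' Simulate one open-field trial
#'
#' Generates the noise-free centroid path of one animal under the two-state
#' renewal model and records ground truth: the behavioral bout list of the
#' renewal process and the three traits as measured on the noise-free path
#' by the standard deterministic chain (6 Hz zero-phase smoothing, speeds,
#' metrics). Defining true traits through the same measurement chain makes
#' them the values an ideal noise-free tracker would report, so recovery
#' errors under noise isolate the effect of the observation noise.
#'
#' Uses R's RNG: call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param config a [simulation_config()]; the tag multiplier in it is
#'   applied to walk-initiation rate and bout speed.
#' @param seed optional integer seed set before generation.
#' @param pipeline a [pipeline_config()] defining the measurement chain for
#'   the ground-truth traits.
#' @return An object of class `sim_trial`: `trajectory` (noise-free mm
#'   [trajectory()]), `heading` (rad per frame), and `truth` (list with
#'   `bouts` data.frame from the renewal process, `avg_speed_mm_s`,
#'   `n_walks`, `n_zones_explored`).
#' @export
simulate_trajectory <- function(config = simulation_config(), seed = NULL,
                                pipeline = pipeline_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  eff <- config$tag_speed_multiplier
  n <- round(config$trial_duration_s * config$fps)
  sim <- sim_crw(n_frames = n, fps = config$fps,
                 arena_l = config$arena$length_mm,
                 arena_w = config$arena$width_mm,
                 pause_mean_s = config$pause_duration_s / eff,
                 walk_mean_s = config$walk_duration_s,
                 speed_mean = config$walk_speed_mm_s * eff,
                 speed_shape = config$walk_speed_shape,
                 turning_sd = config$turning_sd_rad,
                 thigmo_weight = config$thigmotaxis_weight,
                 margin_mm = config$thigmotaxis_margin_mm)
  traj <- trajectory(sim$x, sim$y, rep(TRUE, n), fps = config$fps,
                     units = "mm")
  bouts <- data.frame(start_frame = sim$bout_start,
                      end_frame = sim$bout_end,
                      speed_mm_s = sim$bout_speed[seq_along(sim$bout_end)])
  bouts$duration_s <- (bouts$end_frame - bouts$start_frame) / config$fps
  truth <- measure_truth(traj, pipeline, config$arena)
  truth$bouts <- bouts
  structure(list(trajectory = traj, heading = sim$heading,
                 bout_id = sim$bout_id, truth = truth, config = config),
            class = "sim_trial")
}

# ground-truth traits: the noise-free path through the deterministic
# measurement chain (smoothing -> speeds -> metrics)
measure_truth <- function(traj, pipeline, arena) {
  sm <- butterworth_smooth(traj, pipeline$filter_order,
                           pipeline$filter_cutoff_hz, pipeline$zero_phase)
  sm$x <- pmin(pmax(sm$x, 0), arena$length_mm)
  sm$y <- pmin(pmax(sm$y, 0), arena$width_mm)
  sp <- compute_speed(sm)
  gated <- apply_speed_gate(sm, sp, pipeline$max_speed_mm_s)
  s <- summarize_trajectory(gated, compute_speed(gated), pipeline, arena)
  list(avg_speed_mm_s = s$avg_speed_mm_s, n_walks = s$n_walks,
       n_zones_explored = s$n_zones_explored)
}

#' Render a simulated trial as tracker output
#'
#' Inverse of the kinematics chain: places the body-frame landmarks at each
#' frame's position rotated by the heading, converts to pixels through the
#' arena calibration, adds Gaussian pixel jitter, and draws likelihoods
#' (below the cutoff for dropped-out landmarks, above it otherwise).
#'
#' @param sim a [simulate_trajectory()] result.
#' @param config a [simulation_config()] (defaults to the one stored in
#'   `sim`).
#' @return A [pose_series()] in pixels.
#' @export
render_pose_table <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_trial"))
  off <- config$landmark_offsets_mm
  arena <- config$arena
  n <- sim$trajectory$n_frames
  k <- nrow(off)
  ct <- cos(sim$heading); st <- sin(sim$heading)
  X <- matrix(NA_real_, n, k); Y <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    lx <- sim$trajectory$x + off[j, 1] * ct - off[j, 2] * st
    ly <- sim$trajectory$y + off[j, 1] * st + off[j, 2] * ct
    X[, j] <- lx / arena$scale_x + arena$origin_px[1]
    Y[, j] <- ly / arena$scale_y + arena$origin_px[2]
  }
  if (config$jitter_sd_px > 0) {
    X <- X + matrix(rnorm(n * k, 0, config$jitter_sd_px), n, k)
    Y <- Y + matrix(rnorm(n * k, 0, config$jitter_sd_px), n, k)
  }
  drop <- matrix(runif(n * k) < config$dropout_prob, n, k)
  lik <- matrix(runif(n * k, config$p_cutoff, 1), n, k)
  if (any(drop))
    lik[drop] <- runif(sum(drop), 0, config$p_cutoff)
  nm <- rownames(config$landmark_offsets_mm)
  if (is.null(nm)) nm <- paste0("landmark", seq_len(k))
  pose_series(nm, X, Y, lik, fps = config$fps)
}

# deterministic per-individual seed below 2^31
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 101159) %% 2147483647L) + 1L
}

#' Simulate a two-group tagging study
#'
#' Emulates the study design the analysis targets: `n_tagged` +
#' `n_untagged` individuals interleaved across `n_blocks` experimental
#' blocks round-robin (so every block holds both groups), each with one
#' simulated trial. Tagged individuals' walk-initiation rate and bout speed
#' are multiplied by `effect`. Per-individual seeds are derived
#' deterministically from `seed`, so any single trial can be regenerated in
#' isolation.
#'
#' @param n_tagged,n_untagged group sizes.
#' @param n_blocks number of experimental blocks.
#' @param effect tag multiplier on walk-initiation rate and bout speed
#'   (1 = null).
#' @param config base [simulation_config()] shared by both groups.
#' @param seed master seed (integer).
#' @param tag_type label written in the manifest for tagged individuals.
#' @return An object of class `sim_study`: `manifest` (data.frame),
#'   `trials` (named list of `sim_trial`), `truth` (per-individual true
#'   traits), `seed`.
#' @export
simulate_study <- function(n_tagged = 15, n_untagged = 15, n_blocks = 4,
                           effect = 1.0, config = simulation_config(),
                           seed = 1L, tag_type = "marker") {
  stopifnot(n_tagged >= 1, n_untagged >= 1, n_blocks >= 1, effect > 0)
  n <- n_tagged + n_untagged
  # interleave groups so round-robin blocks each contain both
  tagged <- rep(c(TRUE, FALSE), length.out = n)
  extra <- n_tagged - sum(tagged)
  if (extra != 0) { # unequal group sizes: fix up the tail
    pool <- if (extra > 0) which(!tagged) else which(tagged)
    flip <- tail(pool, abs(extra))
    tagged[flip] <- !tagged[flip]
  }
  ids <- sprintf("%s%02d", ifelse(tagged, "T", "U"),
                 stats::ave(seq_len(n), tagged, FUN = seq_along))
  manifest <- data.frame(
    individual_id = ids,
    tag_group = factor(ifelse(tagged, "tagged", "untagged"),
                       levels = c("untagged", "tagged")),
    tag_type = ifelse(tagged, tag_type, "none"),
    block = factor(paste0("block",
                          rep(seq_len(n_blocks),
                              n %/% n_blocks + (seq_len(n_blocks) <= n %% n_blocks)))),
    pose_path = paste0(ids, ".csv"),
    stringsAsFactors = FALSE
  )
  trials <- vector("list", n)
  names(trials) <- ids
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$tag_speed_multiplier <- if (tagged[i]) effect else 1.0
    trials[[i]] <- simulate_trajectory(cfg_i, seed = derive_seed(seed, i))
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- trials[[i]]$truth
    data.frame(individual_id = ids[i],
               tag_group = as.character(manifest$tag_group[i]),
               block = as.character(manifest$block[i]),
               avg_speed_mm_s = tr$avg_speed_mm_s,
               n_walks = tr$n_walks,
               n_zones_explored = tr$n_zones_explored,
               stringsAsFactors = FALSE)
  }))
  structure(list(manifest = manifest, trials = trials, truth = truth,
                 effect = effect, seed = seed, config = config),
            class = "sim_study")
}

#' Behavioral metrics of a simulated study
#'
#' Observes every simulated animal and runs the measurement chain.
#' `observe = "noisy"` renders landmark-level tracker output (jitter,
#' dropout), masks it at the confidence cutoff and runs the full kinematics
#' chain — the realistic route. `observe = "true"` measures the noise-free
#' path directly, isolating the behavioral and statistical layers from
#' observation noise.
#'
#' Rendering consumes random numbers: the noisy route is reproducible
#' given the RNG state at call time.
#'
#' @param study a [simulate_study()] result.
#' @param config a [pipeline_config()].
#' @param observe `"noisy"` or `"true"`.
#' @return Metrics table with one row per individual (see
#'   [summarize_trial()]).
#' @export
compute_study_metrics <- function(study, config = pipeline_config(),
                                  observe = c("noisy", "true")) {
  stopifnot(inherits(study, "sim_study"))
  observe <- match.arg(observe)
  arena <- study$config$arena
  rows <- lapply(seq_len(nrow(study$manifest)), function(i) {
    sim <- study$trials[[i]]
    if (observe == "noisy") {
      pose <- render_pose_table(sim)
      proc <- process_trajectory(pose, arena, config)
    } else {
      traj <- sim$trajectory
      sm <- butterworth_smooth(traj, config$filter_order,
                               config$filter_cutoff_hz, config$zero_phase)
      sm$x <- pmin(pmax(sm$x, 0), arena$length_mm)
      sm$y <- pmin(pmax(sm$y, 0), arena$width_mm)
      sp <- compute_speed(sm)
      gated <- apply_speed_gate(sm, sp, config$max_speed_mm_s)
      proc <- list(trajectory = gated, speeds = compute_speed(gated))
    }
    summarize_trial(study$manifest[i, ], proc, config, arena)
  })
  do.call(rbind, rows)
}

#' Write a simulated study to disk
#'
#' Emits one DeepLabCut-style pose CSV per individual (rendered with the
#' study's observation-noise settings), the trial manifest, and the
#' ground-truth trait table, so the file-based pipeline entry point can be
#' exercised end to end.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param render_seed seed for the rendering noise (per-individual seeds
#'   derived from it).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir, render_seed = study$seed + 1L) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(study$manifest))) {
    set.seed(derive_seed(render_seed, i))
    pose <- render_pose_table(study$trials[[i]])
    write_pose_table(pose, file.path(dir, study$manifest$pose_path[i]))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(study$manifest, mpath, row.names = FALSE)
  write.csv(study$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(mpath)
}
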