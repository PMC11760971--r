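#' Average speed of a trial
#'
#' Sum of all valid inter-frame displacements divided by the number of
#' intervals, expressed per second: mean per-frame displacement times the
#' frame rate. With `denominator = "valid"` (default) the divisor is the
#' number of valid intervals, which does not deflate the speed of
#' individuals with more masked frames; `"total"` divides by all intervals
#' of the trial.
#'
#' @param speeds a [compute_speed()] result.
#' @param denominator `"valid"` or `"total"`.
#' @return Average speed in mm/s, or `NA` (with a warning) when no valid
#'   interval exists.
#' @export
average_speed <- function(speeds, denominator = c("valid", "total")) {
  stopifnot(inherits(speeds, "speed_series"))
  denominator <- match.arg(denominator)
  n_ok <- sum(speeds$valid)
  if (n_ok == 0) {
    warning("no valid intervals: average speed undefined")
    return(NA_real_)
  }
  total_dist_per_s <- sum(speeds$speed_mm_s[speeds$valid])
  den <- if (denominator == "valid") n_ok else length(speeds$speed_mm_s)
  total_dist_per_s / den
}

#' Detect walk bouts
#'
#' A walk is a maximal run of consecutive valid intervals whose speed is
#' strictly above `walk_speed_mm_s`, lasting at least
#' `walk_min_duration_s` (inclusive). A single sub-threshold or invalid
#' interval terminates a run: movement must be continuous, with no dip
#' tolerance. The duration of a bout is the number of supra-threshold
#' intervals divided by the frame rate, i.e. the time actually spent
#' moving; `start_frame`/`end_frame` (0-based, inclusive) delimit the
#' frames spanned by those intervals.
#'
#' @param speeds a [compute_speed()] result.
#' @param walk_speed_mm_s speed threshold (mm/s, strict); 10 mm/s = 1 cm/s.
#' @param walk_min_duration_s minimum bout duration (s, inclusive).
#' @return A `data.frame` with one row per bout, in temporal order:
#'   `start_frame`, `end_frame`, `duration_s`, `mean_speed_mm_s`.
#' @export
detect_walks <- function(speeds, walk_speed_mm_s = 10,
                         walk_min_duration_s = 1.0) {
  stopifnot(inherits(speeds, "speed_series"))
  sp <- speeds$speed_mm_s
  ok <- speeds$valid & !is.na(sp) & sp > walk_speed_mm_s
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), mean_speed_mm_s = numeric(0))
  if (!any(ok)) return(empty)
  r <- runs_of(ok)
  r <- r[r$value, , drop = FALSE]
  dur <- (r$end - r$start + 1L) / speeds$fps
  keep <- dur >= walk_min_duration_s
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0) return(empty)
  data.frame(
    start_frame = r$start - 1L,          # interval i spans frames i-1 .. i
    end_frame = r$end,                   # 0-based inclusive
    duration_s = dur[keep],
    mean_speed_mm_s = vapply(seq_len(nrow(r)),
                             function(k) mean(sp[r$start[k]:r$end[k]]),
                             numeric(1)),
    row.names = NULL
  )
}

#' Count explored zones
#'
#' Assigns every valid centroid position to a cell of the zone grid
#' (`floor(x / cell_length)`, `floor(y / cell_width)`; points exactly on the
#' far arena edges belong to the last row/column) and returns the number of
#' distinct cells visited.
#'
#' @param traj a calibrated millimetre [trajectory()].
#' @param arena an [arena_spec()].
#' @param grid a [zone_grid()]; defaults to the 3 x 6 grid for `arena`.
#' @return Integer count of unique zones entered (0 for a trial with no
#'   valid frame).
#' @export
zones_explored <- function(traj, arena = arena_spec(),
                           grid = zone_grid(arena = arena)) {
  stopifnot(inherits(traj, "trajectory"), inherits(grid, "zone_grid"))
  x <- traj$x[traj$valid]; y <- traj$y[traj$valid]
  if (length(x) == 0) return(0L)
  col <- pmin(pmax(floor(x / grid$cell_length_mm), 0), grid$cols - 1L)
  row <- pmin(pmax(floor(y / grid$cell_width_mm), 0), grid$rows - 1L)
  length(unique(row * grid$cols + col))
}

# shared by summarize_trial and the simulator's ground-truth metrics
summarize_trajectory <- function(traj, speeds, config, arena) {
  walks <- detect_walks(speeds, config$walk_speed_mm_s,
                        config$walk_min_duration_s)
  grid <- zone_grid(config$zone_rows, config$zone_cols, arena)
  avg <- if (sum(speeds$valid) == 0) NA_real_ else
    average_speed(speeds, config$speed_denominator)
  list(avg_speed_mm_s = avg,
       n_walks = nrow(walks),
       n_zones_explored = zones_explored(traj, arena, grid),
       n_valid_frames = sum(traj$valid),
       walks = walks)
}

#' Summarise one trial into the three behavioral traits
#'
#' Bundles average speed, walk-bout count and zone exploration with the
#' trial's metadata. Deterministic for fixed input. Trials with no valid
#' interval get `NA` average speed and are flagged in the `flag` column.
#'
#' @param manifest_row one row of a [read_manifest()] table (or any list
#'   with `individual_id`, `tag_group`, `tag_type`, `block`).
#' @param processed a [process_trajectory()] result (or a list with
#'   `trajectory` and `speeds`).
#' @param config a [pipeline_config()].
#' @param arena an [arena_spec()].
#' @return A one-row `data.frame`: `individual_id`, `tag_group`, `tag_type`,
#'   `block`, `avg_speed_mm_s`, `n_walks`, `n_zones_explored`,
#'   `n_valid_frames`, `flag`.
#' @export
summarize_trial <- function(manifest_row, processed,
                            config = pipeline_config(),
                            arena = arena_spec()) {
  s <- summarize_trajectory(processed$trajectory, processed$speeds,
                            config, arena)
  data.frame(
    individual_id = as.character(manifest_row$individual_id),
    tag_group = as.character(manifest_row$tag_group),
    tag_type = as.character(manifest_row$tag_type),
    block = as.character(manifest_row$block),
    avg_speed_mm_s = s$avg_speed_mm_s,
    n_walks = s$n_walks,
    n_zones_explored = s$n_zones_explored,
    n_valid_frames = s$n_valid_frames,
    flag = if (is.na(s$avg_speed_mm_s)) "no_valid_intervals" else "",
    stringsAsFactors = FALSE
  )
}
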