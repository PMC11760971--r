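#' Pipeline configuration
#'
#' Bundles every tunable constant of the processing and analysis chain with
#' its default. Defaults follow the tracking-study conventions the package
#' implements: a DeepLabCut-default confidence cutoff of 0.6, a second-order
#' 6 Hz low-pass Butterworth smoother, a 230 mm/s (23 cm/s) biological
#' maximum-speed gate, walk bouts defined as >= 1 s of continuous movement
#' above 10 mm/s (1 cm/s), and an 18-zone (3 x 6) partition of the arena
#' floor for the exploration metric.
#'
#' @param p_cutoff minimum landmark confidence for a detection to enter the
#'   analysis; detections with likelihood strictly below it are masked, a
#'   likelihood exactly equal to the cutoff is kept.
#' @param filter_order Butterworth filter order.
#' @param filter_cutoff_hz low-pass cutoff frequency (Hz); must stay below
#'   the Nyquist frequency of the recording.
#' @param zero_phase logical; apply the filter forward then backward so the
#'   output has no time lag (squares the magnitude response). Default `TRUE`,
#'   the gait-analysis convention.
#' @param max_speed_mm_s speed gate (mm/s); frames reached faster than this
#'   are treated as tracking errors and invalidated.
#' @param walk_speed_mm_s minimum speed (mm/s) for an interval to count as
#'   walking (strict inequality).
#' @param walk_min_duration_s minimum duration (s, inclusive) of a walk bout.
#' @param zone_rows,zone_cols shape of the exploration zone grid.
#' @param alpha significance level for the group comparison and for the
#'   Shapiro-Wilk residual check.
#' @param max_gap_frames longest run of invalid frames bridged by linear
#'   interpolation (longer gaps split the trajectory into independent
#'   filtering segments).
#' @param min_valid_landmarks minimum number of unmasked landmarks needed to
#'   form a centroid for a frame. The default (4, all body landmarks of the
#'   standard rig) rejects partial-landmark frames: with an asymmetric
#'   landmark layout the mean of a subset is offset from the body centre by
#'   several millimetres, which masquerades as a speed spike; briefly
#'   rejected frames are bridged by gap interpolation instead. Set to 2 for
#'   the permissive behavior.
#' @param speed_denominator `"valid"` (default) divides the summed
#'   displacement by the number of valid inter-frame intervals; `"total"`
#'   divides by all intervals of the trial.
#' @param trim_start_s seconds trimmed from the start of each trial before
#'   analysis (0 when the input already covers only the measurement period).
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$filter_cutoff_hz
#' @export
pipeline_config <- function(p_cutoff = 0.6,
                            filter_order = 2L,
                            filter_cutoff_hz = 6,
                            zero_phase = TRUE,
                            max_speed_mm_s = 230,
                            walk_speed_mm_s = 10,
                            walk_min_duration_s = 1.0,
                            zone_rows = 3L,
                            zone_cols = 6L,
                            alpha = 0.05,
                            max_gap_frames = 15L,
                            min_valid_landmarks = 4L,
                            speed_denominator = c("valid", "total"),
                            trim_start_s = 0) {
  speed_denominator <- match.arg(speed_denominator)
  cfg <- list(
    p_cutoff = as.numeric(p_cutoff),
    filter_order = as.integer(filter_order),
    filter_cutoff_hz = as.numeric(filter_cutoff_hz),
    zero_phase = isTRUE(zero_phase),
    max_speed_mm_s = as.numeric(max_speed_mm_s),
    walk_speed_mm_s = as.numeric(walk_speed_mm_s),
    walk_min_duration_s = as.numeric(walk_min_duration_s),
    zone_rows = as.integer(zone_rows),
    zone_cols = as.integer(zone_cols),
    n_zones = as.integer(zone_rows) * as.integer(zone_cols),
    alpha = as.numeric(alpha),
    max_gap_frames = as.integer(max_gap_frames),
    min_valid_landmarks = as.integer(min_valid_landmarks),
    speed_denominator = speed_denominator,
    trim_start_s = as.numeric(trim_start_s)
  )
  stopifnot(
    cfg$p_cutoff >= 0, cfg$p_cutoff <= 1,
    cfg$filter_order >= 1,
    cfg$filter_cutoff_hz > 0,
    cfg$max_speed_mm_s > 0,
    cfg$walk_speed_mm_s > 0,
    cfg$walk_min_duration_s > 0,
    cfg$zone_rows >= 1, cfg$zone_cols >= 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$max_gap_frames >= 0,
    cfg$min_valid_landmarks >= 1,
    cfg$trim_start_s >= 0
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Arena geometry and pixel calibration
#'
#' Describes the open-field arena: interior floor dimensions in millimetres
#' and the affine pixel-to-millimetre map (per-axis scale factors derived
#' from imaged known lengths, plus the pixel position of the arena corner
#' that maps to the metric origin). Anisotropic scales are supported because
#' calibration from separate horizontal and vertical reference lengths can
#' differ slightly.
#'
#' @param length_mm interior arena length (mm), the x extent.
#' @param width_mm interior arena width (mm), the y extent.
#' @param scale_x,scale_y millimetres per pixel along image x and y.
#' @param origin_px numeric length-2: pixel coordinates mapped to (0, 0) mm.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()            # 185 x 80 mm arena at 0.25 mm/px
#' @export
arena_spec <- function(length_mm = 185, width_mm = 80,
                       scale_x = 0.25, scale_y = 0.25,
                       origin_px = c(0, 0)) {
  stopifnot(length_mm > 0, width_mm > 0, scale_x > 0, scale_y > 0,
            length(origin_px) == 2, all(is.finite(origin_px)))
  structure(list(length_mm = as.numeric(length_mm),
                 width_mm = as.numeric(width_mm),
                 scale_x = as.numeric(scale_x),
                 scale_y = as.numeric(scale_y),
                 origin_px = as.numeric(origin_px)),
            class = "arena_spec")
}

#' Exploration zone grid
#'
#' Partition of the arena floor into `rows x cols` equal rectangular cells
#' for the zone-exploration metric. The default 3 x 6 = 18 cells best matches
#' the 185:80 aspect ratio of the default arena with near-square cells
#' (~30.8 x 26.7 mm).
#'
#' @param rows,cols grid shape.
#' @param arena an [arena_spec()] used to derive cell sizes.
#' @return An object of class `zone_grid` with cell dimensions in mm.
#' @export
zone_grid <- function(rows = 3L, cols = 6L, arena = arena_spec()) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1)
  structure(list(rows = rows, cols = cols,
                 cell_length_mm = arena$length_mm / cols,
                 cell_width_mm = arena$width_mm / rows),
            class = "zone_grid")
}
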