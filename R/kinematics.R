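#' Construct a trajectory
#'
#' Per-frame centroid path with a validity mask. Units are pixels straight
#' after [compute_centroid()] and millimetres after [calibrate()]; the unit
#' is carried in the `units` attribute.
#'
#' @param x,y numeric vectors of positions.
#' @param valid logical vector; positions must be finite wherever valid.
#' @param fps frame rate (Hz).
#' @param units `"px"` or `"mm"`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(x, y, valid = is.finite(x) & is.finite(y),
                       fps, units = "mm") {
  stopifnot(length(x) == length(y), length(valid) == length(x),
            is.numeric(fps), fps > 0)
  valid <- valid & is.finite(x) & is.finite(y)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 valid = as.logical(valid),
                 fps = as.numeric(fps), n_frames = length(x),
                 units = units),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames at %g fps (%s), %d valid (%.1f%%)\n",
              x$n_frames, x$fps, x$units, sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Collapse landmarks to a centroid path
#'
#' Per frame, the centroid is the arithmetic mean of all unmasked landmark
#' positions. Frames with fewer than `min_valid_landmarks` unmasked
#' landmarks are marked invalid. Antenna-tip landmarks, when present, are
#' excluded by default: they are tracked by some setups but are not body
#' landmarks.
#'
#' @param series a [pose_series()] (typically after [apply_pcutoff()]).
#' @param min_valid_landmarks minimum unmasked landmarks per frame.
#' @param exclude_pattern regular expression matching landmark names to drop
#'   before averaging (`NULL` to keep all).
#' @return A pixel-unit [trajectory()].
#' @export
compute_centroid <- function(series, min_valid_landmarks = 2L,
                             exclude_pattern = "antenna") {
  stopifnot(inherits(series, "pose_series"))
  keep <- rep(TRUE, length(series$landmarks))
  if (!is.null(exclude_pattern))
    keep <- !grepl(exclude_pattern, series$landmarks, ignore.case = TRUE)
  if (!any(keep))
    stop("no body landmarks left after exclusion")
  X <- series$x[, keep, drop = FALSE]
  Y <- series$y[, keep, drop = FALSE]
  ok <- is.finite(X) & is.finite(Y)
  X[!ok] <- NA_real_; Y[!ok] <- NA_real_
  n_ok <- rowSums(ok)
  cx <- rowMeans(X, na.rm = TRUE)
  cy <- rowMeans(Y, na.rm = TRUE)
  valid <- n_ok >= min_valid_landmarks
  cx[!valid] <- NA_real_; cy[!valid] <- NA_real_
  trajectory(cx, cy, valid, fps = series$fps, units = "px")
}

#' Calibrate a pixel trajectory to arena millimetres
#'
#' Applies the affine pixel-to-metric map `x_mm = (x_px - origin_x) *
#' scale_x` (likewise for y). Valid points falling outside the arena
#' rectangle are clamped to its boundary with a warning reporting the count
#' and the largest excursion; an excursion beyond `tolerance_mm` usually
#' indicates a wrong scale or origin and is flagged as such.
#'
#' @param traj a pixel-unit [trajectory()].
#' @param arena an [arena_spec()].
#' @param tolerance_mm excursion (mm) beyond which the warning escalates.
#' @return A millimetre-unit [trajectory()].
#' @export
calibrate <- function(traj, arena, tolerance_mm = 5) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_spec"))
  x <- (traj$x - arena$origin_px[1]) * arena$scale_x
  y <- (traj$y - arena$origin_px[2]) * arena$scale_y
  v <- traj$valid
  exc <- pmax(0, -x, x - arena$length_mm, -y, y - arena$width_mm)
  exc[!v | !is.finite(exc)] <- 0
  if (any(exc > 0)) {
    msg <- sprintf("%d point(s) outside the arena clamped to the boundary (max excursion %.2f mm)",
                   sum(exc > 0), max(exc))
    if (max(exc) > tolerance_mm)
      msg <- paste0(msg, sprintf(" - exceeds tolerance %.1f mm; check scale/origin",
                                 tolerance_mm))
    warning(msg)
  }
  x <- pmin(pmax(x, 0), arena$length_mm)
  y <- pmin(pmax(y, 0), arena$width_mm)
  trajectory(x, y, v, fps = traj$fps, units = "mm")
}

# maximal runs of a logical vector; returns data.frame(start, end, value)
runs_of <- function(v) {
  r <- rle(v)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' Bridge short tracking gaps by linear interpolation
#'
#' Runs of at most `max_gap_frames` invalid frames flanked on both sides by
#' valid frames are filled by per-coordinate linear interpolation and marked
#' valid. Longer runs (and invalid runs touching either end of the trial)
#' stay invalid and later split the trajectory into independent filtering
#' segments.
#'
#' @param traj a [trajectory()].
#' @param max_gap_frames longest bridgeable gap (frames).
#' @return The gap-filled [trajectory()].
#' @export
interpolate_gaps <- function(traj, max_gap_frames = 15L) {
  stopifnot(inherits(traj, "trajectory"))
  if (all(traj$valid) || max_gap_frames < 1) return(traj)
  r <- runs_of(traj$valid)
  gaps <- r[!r$value & r$end - r$start + 1L <= max_gap_frames &
              r$start > 1L & r$end < traj$n_frames, , drop = FALSE]
  if (nrow(gaps) == 0) return(traj)
  idx_valid <- which(traj$valid)
  fill <- unlist(mapply(seq, gaps$start, gaps$end, SIMPLIFY = FALSE))
  traj$x[fill] <- approx(idx_valid, traj$x[idx_valid], xout = fill)$y
  traj$y[fill] <- approx(idx_valid, traj$y[idx_valid], xout = fill)$y
  traj$valid[fill] <- TRUE
  traj
}

# steady-state filter state for a unit-step input (direct form II transposed),
# so that filtering a constant from state zi * x0 yields that constant exactly
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp_t <- t(rbind(-a[-1], cbind(diag(n - 2), 0))) # companion(a), transposed
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - comp_t, B)
}

# zero-phase (or single-pass) IIR filtering of one contiguous segment with
# odd-reflection padding and steady-state initial conditions
filt_segment <- function(b, a, x, zero_phase, padlen) {
  n <- length(x)
  p <- min(padlen, n - 1L)
  zi <- lfilter_zi(b, a)
  if (p > 0) {
    ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else ext <- x
  y <- filter_df2t(b, a, ext, zi * ext[1])
  if (zero_phase) {
    y <- rev(filter_df2t(b, a, rev(y), zi * y[length(y)]))
  }
  if (p > 0) y <- y[(p + 1):(p + n)]
  y
}

#' Low-pass Butterworth smoothing of a trajectory
#'
#' Smooths each coordinate of every contiguous valid segment with a low-pass
#' Butterworth filter (coefficients from [signal::butter()]). By default the
#' filter is applied forward then backward (zero phase): the output has no
#' time lag, at the cost of squaring the magnitude response, so the
#' effective amplitude gain at the cutoff is 1/2 rather than 1/sqrt(2).
#' Segments are padded by odd reflection (length `3 * (2 * order + 1)`) with
#' steady-state initial conditions to suppress edge transients; segments of
#' `3 * order` frames or fewer pass through unfiltered.
#'
#' @param traj a [trajectory()].
#' @param order filter order.
#' @param cutoff_hz cutoff frequency (Hz), strictly below Nyquist.
#' @param zero_phase forward-backward filtering (default) or single forward
#'   pass.
#' @return The smoothed [trajectory()]; invalid frames are untouched and the
#'   frame count is unchanged.
#' @export
butterworth_smooth <- function(traj, order = 2L, cutoff_hz = 6,
                               zero_phase = TRUE) {
  stopifnot(inherits(traj, "trajectory"), order >= 1, cutoff_hz > 0)
  if (cutoff_hz >= traj$fps / 2)
    stop(sprintf("filter cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, traj$fps / 2))
  bf <- signal::butter(order, cutoff_hz / (traj$fps / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  padlen <- 3L * (2L * as.integer(order) + 1L)
  segs <- runs_of(traj$valid)
  segs <- segs[segs$value, , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    i <- segs$start[k]:segs$end[k]
    if (length(i) <= 3 * order) next   # too short to filter; passes through
    traj$x[i] <- filt_segment(b, a, traj$x[i], zero_phase, padlen)
    traj$y[i] <- filt_segment(b, a, traj$y[i], zero_phase, padlen)
  }
  traj
}

#' Per-interval scalar speed
#'
#' Speed of interval i is the Euclidean distance between frames i and i+1
#' times the frame rate; the interval is valid only when both endpoint
#' frames are valid.
#'
#' @param traj a millimetre-unit [trajectory()].
#' @return An object of class `speed_series`: list with `speed_mm_s` and
#'   `valid`, both of length `n_frames - 1`, plus `fps`.
#' @export
compute_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), traj$n_frames >= 1)
  n <- traj$n_frames
  if (n < 2) {
    return(structure(list(speed_mm_s = numeric(0), valid = logical(0),
                          fps = traj$fps), class = "speed_series"))
  }
  dx <- diff(traj$x); dy <- diff(traj$y)
  sp <- sqrt(dx^2 + dy^2) * traj$fps
  ok <- traj$valid[-n] & traj$valid[-1] & is.finite(sp)
  sp[!ok] <- NA_real_
  structure(list(speed_mm_s = sp, valid = ok, fps = traj$fps),
            class = "speed_series")
}

#' Remove biologically impossible jumps
#'
#' Any interval whose speed strictly exceeds `max_speed_mm_s` is treated as
#' a tracking error and the *later* endpoint frame is invalidated. The gate
#' is a single pass over the input speeds: removal is not cascaded, matching
#' the one-shot frame-removal step of the processing chain. Intervals at
#' exactly the threshold are kept.
#'
#' @param traj a [trajectory()].
#' @param speeds the [compute_speed()] output for `traj`.
#' @param max_speed_mm_s gate threshold (mm/s); 230 mm/s is the recorded
#'   maximum moving speed of *Blaptica dubia*.
#' @return The gated [trajectory()] (same frame count).
#' @export
apply_speed_gate <- function(traj, speeds, max_speed_mm_s = 230) {
  stopifnot(inherits(traj, "trajectory"), inherits(speeds, "speed_series"),
            length(speeds$speed_mm_s) == traj$n_frames - 1)
  hot <- which(speeds$valid & speeds$speed_mm_s > max_speed_mm_s)
  if (length(hot)) {
    traj$valid[hot + 1L] <- FALSE
    traj$x[hot + 1L] <- NA_real_
    traj$y[hot + 1L] <- NA_real_
  }
  traj
}

#' Run the full kinematic processing chain
#'
#' Fixed order: confidence masking, centroid, metric calibration, gap
#' interpolation, Butterworth smoothing, speed computation, speed gate, and
#' a final speed recomputation on the gated trajectory (so downstream
#' metrics see interval validity consistent with the gated frames). Frame
#' count is preserved at every stage.
#'
#' @param series a raw [pose_series()].
#' @param arena an [arena_spec()].
#' @param config a [pipeline_config()].
#' @return A list of class `processed_trial`: `trajectory` (gated, mm),
#'   `speeds` (recomputed post-gate), and `log`, a named list of per-stage
#'   frame counts (frames masked by the cutoff, interpolated, gated, valid).
#' @export
process_trajectory <- function(series, arena = arena_spec(),
                               config = pipeline_config()) {
  stopifnot(inherits(series, "pose_series"))
  if (config$trim_start_s > 0) {
    drop <- seq_len(min(series$n_frames,
                        round(config$trim_start_s * series$fps)))
    series$x <- series$x[-drop, , drop = FALSE]
    series$y <- series$y[-drop, , drop = FALSE]
    series$likelihood <- series$likelihood[-drop, , drop = FALSE]
    series$n_frames <- nrow(series$x)
  }
  masked <- apply_pcutoff(series, config$p_cutoff)
  cent <- compute_centroid(masked, config$min_valid_landmarks)
  n_low_conf <- sum(!cent$valid)
  # calibration clamping is reported once here; post-filter re-clamp is silent
  mm <- withCallingHandlers(
    calibrate(cent, arena),
    warning = function(w) {
      message("calibration: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  filled <- interpolate_gaps(mm, config$max_gap_frames)
  n_interp <- sum(filled$valid) - sum(mm$valid)
  sm <- butterworth_smooth(filled, config$filter_order,
                           config$filter_cutoff_hz, config$zero_phase)
  sm$x <- pmin(pmax(sm$x, 0), arena$length_mm)
  sm$y <- pmin(pmax(sm$y, 0), arena$width_mm)
  sp <- compute_speed(sm)
  gated <- apply_speed_gate(sm, sp, config$max_speed_mm_s)
  n_gated <- sum(sm$valid) - sum(gated$valid)
  structure(list(
    trajectory = gated,
    speeds = compute_speed(gated),
    log = list(n_frames = gated$n_frames,
               n_low_confidence = n_low_conf,
               n_interpolated = n_interp,
               n_speed_gated = n_gated,
               n_valid = sum(gated$valid))
  ), class = "processed_trial")
}
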