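#' Construct a pose frame series
#'
#' Container for raw tracker output: per-frame, per-landmark pixel positions
#' with detection confidence. Positions of masked detections are `NA`;
#' likelihoods are always preserved.
#'
#' @param landmarks character vector of unique landmark names.
#' @param x,y numeric matrices (`n_frames x n_landmarks`) of pixel positions
#'   (image convention: y increases downward).
#' @param likelihood numeric matrix of the same shape with values in [0, 1].
#' @param fps recording frame rate (Hz).
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(landmarks, x, y, likelihood, fps) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (anyDuplicated(landmarks))
    stop("landmark names must be unique")
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(likelihood)))
    stop("x, y and likelihood must have identical dimensions")
  if (ncol(x) != length(landmarks))
    stop("number of landmark names must match the number of columns")
  lik <- likelihood[is.finite(likelihood)]
  if (length(lik) && (min(lik) < 0 || max(lik) > 1))
    stop("likelihood values must lie in [0, 1]")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  colnames(x) <- colnames(y) <- colnames(likelihood) <- landmarks
  structure(list(landmarks = as.character(landmarks),
                 x = x, y = y, likelihood = likelihood,
                 fps = as.numeric(fps), n_frames = nrow(x)),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("Pose series: %d frames at %g fps, %d landmarks (%s)\n",
              x$n_frames, x$fps, length(x$landmarks),
              paste(x$landmarks, collapse = ", ")))
  masked <- sum(is.na(x$x))
  cat(sprintf("  masked landmark observations: %d (%.2f%%)\n",
              masked, 100 * masked / max(1, length(x$x))))
  invisible(x)
}

#' Read a DeepLabCut-style pose table
#'
#' Parses the three-row-header CSV dialect emitted by markerless pose
#' trackers: row 1 the scorer/model name, row 2 the body part, row 3 the
#' coordinate type (`x`, `y` or `likelihood`). A leading frame-index column
#' (coordinate label not in x/y/likelihood, typically `coords`) is accepted
#' and dropped. Every declared body part must carry all three coordinate
#' columns.
#'
#' @param path CSV file path.
#' @param fps frame rate of the recording (Hz); not stored in the file.
#' @return A [pose_series()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' s <- pose_series("head", cbind(c(10, 11)), cbind(c(20, 21)),
#'                  cbind(c(0.9, 0.8)), fps = 30)
#' write_pose_table(s, f)
#' read_pose_table(f, fps = 30)
#' @export
read_pose_table <- function(path, fps = 30) {
  if (!file.exists(path)) stop("pose table not found: ", path)
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE)
  if (nrow(raw) < 3) stop("malformed pose table: fewer than 3 header rows")
  parts <- as.character(unlist(raw[2, ]))
  coords <- tolower(trimws(as.character(unlist(raw[3, ]))))
  keep <- coords %in% c("x", "y", "likelihood")
  if (!any(keep)) stop("malformed header: no x/y/likelihood columns found")
  parts <- parts[keep]; coords <- coords[keep]
  body <- raw[-(1:3), keep, drop = FALSE]
  landmarks <- unique(parts)
  # every landmark needs exactly the three coordinate columns
  for (lm in landmarks) {
    have <- sort(coords[parts == lm])
    if (!identical(have, c("likelihood", "x", "y")))
      stop(sprintf("malformed header: landmark '%s' has columns {%s}, needs x, y, likelihood",
                   lm, paste(coords[parts == lm], collapse = ", ")))
  }
  n <- nrow(body)
  num <- matrix(NA_real_, n, ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !(body[[j]] %in% c("", "NA", "NaN", "nan")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at data row %d, column %s/%s",
                   body[[j]][bad[1]], bad[1], parts[j], coords[j]))
    num[, j] <- v
  }
  pick <- function(coord) {
    m <- vapply(landmarks, function(lm) num[, parts == lm & coords == coord],
                numeric(n))
    matrix(m, nrow = n, ncol = length(landmarks),
           dimnames = list(NULL, landmarks))
  }
  pose_series(landmarks, pick("x"), pick("y"), pick("likelihood"), fps = fps)
}

#' Write a pose series as a DeepLabCut-style CSV
#'
#' Inverse of [read_pose_table()]: emits the three-row header (scorer, body
#' part, coordinate) followed by one row per frame with a leading frame-index
#' column. Finite values round-trip losslessly (17 significant digits).
#'
#' @param series a [pose_series()].
#' @param path output file path.
#' @param scorer scorer label written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(series, path, scorer = "tagtrax") {
  stopifnot(inherits(series, "pose_series"))
  lms <- series$landmarks
  h1 <- c("scorer", rep(scorer, 3 * length(lms)))
  h2 <- c("bodyparts", rep(lms, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(lms)))
  fmt <- function(m) {
    out <- formatC(m, format = "g", digits = 17)
    out[is.na(m)] <- ""
    out
  }
  cols <- vector("list", length(lms) * 3)
  for (i in seq_along(lms)) {
    cols[[3 * i - 2]] <- fmt(series$x[, i])
    cols[[3 * i - 1]] <- fmt(series$y[, i])
    cols[[3 * i]] <- fmt(series$likelihood[, i])
  }
  body <- do.call(cbind, c(list(as.character(seq_len(series$n_frames) - 1L)), cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Mask low-confidence landmark detections
#'
#' Applies the tracker's P-cutoff: landmark observations whose likelihood is
#' strictly below `p_cutoff` have their positions set to missing. A
#' likelihood exactly equal to the cutoff is kept (the cutoff is the minimum
#' confidence for inclusion). Likelihood values themselves are preserved, so
#' the operation is idempotent and monotone in the cutoff.
#'
#' @param series a [pose_series()].
#' @param p_cutoff confidence threshold in [0, 1].
#' @return The masked [pose_series()].
#' @export
apply_pcutoff <- function(series, p_cutoff = 0.6) {
  stopifnot(inherits(series, "pose_series"),
            p_cutoff >= 0, p_cutoff <= 1)
  drop <- !is.na(series$likelihood) & series$likelihood < p_cutoff
  series$x[drop] <- NA_real_
  series$y[drop] <- NA_real_
  series
}

#' Read a trial manifest
#'
#' A manifest lists one trial per row with columns `individual_id`,
#' `tag_group` (`tagged` or `untagged`), `tag_type` (`rfid`, `marker` or
#' `none`), `block`, and `pose_path` (path to the trial's pose table,
#' resolved relative to the manifest's directory when not absolute).
#'
#' @param path manifest CSV path.
#' @return A `data.frame` with one validated record per trial; `tag_group`
#'   is a factor with `untagged` as the reference level.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "tag_group", "tag_type", "block", "pose_path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(m) == 0) stop("manifest contains no trials")
  dup <- m$individual_id[duplicated(m$individual_id)]
  if (length(dup))
    stop("duplicated individual_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(m$tag_group), c("tagged", "untagged"))
  if (length(bad))
    stop("unknown tag_group level(s): ", paste(bad, collapse = ", "),
         " (allowed: tagged, untagged)")
  bad_t <- setdiff(unique(m$tag_type), c("rfid", "marker", "none"))
  if (length(bad_t))
    stop("unknown tag_type level(s): ", paste(bad_t, collapse = ", "),
         " (allowed: rfid, marker, none)")
  m$tag_group <- factor(m$tag_group, levels = c("untagged", "tagged"))
  m$block <- factor(m$block)
  # flag blocks lacking one of the two groups
  tab <- table(m$block, m$tag_group)
  one_sided <- rownames(tab)[apply(tab > 0, 1, sum) < 2]
  attr(m, "one_sided_blocks") <- one_sided
  if (length(one_sided))
    warning("block(s) with only one tag group: ",
            paste(one_sided, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$pose_path)
  m$pose_path[rel] <- file.path(dirname(path), m$pose_path[rel])
  m
}

#' Write / read a calibrated trajectory CSV
#'
#' Intermediate format with columns `frame` (0-based), `time_s`, `x_mm`,
#' `y_mm`, `valid`. Invalid frames carry empty coordinates.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  fmt <- function(v) {
    out <- formatC(v, format = "g", digits = 17)
    out[!traj$valid | is.na(v)] <- ""
    out
  }
  d <- data.frame(frame = seq_len(traj$n_frames) - 1L,
                  time_s = (seq_len(traj$n_frames) - 1L) / traj$fps,
                  x_mm = fmt(traj$x), y_mm = fmt(traj$y),
                  valid = as.integer(traj$valid))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param fps frame rate used when reading (the CSV stores time, not rate);
#'   defaults to the rate implied by the first two time stamps.
#' @export
read_trajectory <- function(path, fps = NULL) {
  d <- read.csv(path)
  if (is.null(fps)) {
    if (nrow(d) < 2) stop("cannot infer fps from a single-frame trajectory")
    fps <- 1 / diff(d$time_s[1:2])
  }
  trajectory(x = d$x_mm, y = d$y_mm, valid = as.logical(d$valid), fps = fps)
}
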