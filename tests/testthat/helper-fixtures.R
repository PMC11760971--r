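# Fixture builders and independent oracles shared across the suite.

# pose series with a single landmark following the given coordinates
single_landmark_series <- function(x, y, lik = rep(0.9, length(x)), fps = 30) {
  pose_series("centroid", cbind(x), cbind(y), cbind(lik), fps = fps)
}

# four-landmark series placed symmetrically around a moving centre
square_series <- function(cx, cy, half = 1, lik = 0.9, fps = 30) {
  n <- length(cx)
  mk <- function(dx, dy) list(x = cx + dx, y = cy + dy)
  pts <- list(mk(-half, -half), mk(-half, half), mk(half, -half), mk(half, half))
  pose_series(paste0("lm", 1:4),
              vapply(pts, `[[`, numeric(n), "x"),
              vapply(pts, `[[`, numeric(n), "y"),
              matrix(lik, n, 4), fps = fps)
}

# speed series wrapper for hand-built speeds
speed_fixture <- function(speed, valid = rep(TRUE, length(speed)), fps = 30) {
  valid <- valid & !is.na(speed)
  sp <- speed
  sp[!valid] <- NA_real_
  structure(list(speed_mm_s = sp, valid = valid, fps = fps),
            class = "speed_series")
}

# Independent walk-bout oracle: collects supra-threshold interval indices
# and groups maximal consecutive stretches, keeping those long enough.
# (The implementation uses run-length encoding; this path does not.)
oracle_walk_count <- function(speed, valid, thr, min_dur, fps) {
  ok <- which(valid & !is.na(speed) & speed > thr)
  if (!length(ok)) return(0L)
  groups <- split(ok, cumsum(c(1L, diff(ok) != 1L)))
  sum(vapply(groups, length, integer(1)) / fps >= min_dur)
}

# Quadratic-time oracle used on small fixtures: every window of intervals
# is inspected for being fully supra-threshold and maximal.
oracle_walk_count_bruteforce <- function(speed, valid, thr, min_dur, fps) {
  ok <- valid & !is.na(speed) & speed > thr
  n <- length(ok)
  count <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      maximal <- all(ok[i:j]) &&
        (i == 1 || !ok[i - 1]) && (j == n || !ok[j + 1])
      if (maximal && (j - i + 1) / fps >= min_dur) count <- count + 1L
    }
  }
  count
}

# Independent OLS + Type II F oracle: hand-built dummy design, normal
# equations, nested residual sums of squares.
oracle_tag_fit <- function(y, tag, block = NULL) {
  n <- length(y)
  X <- cbind(1, as.numeric(tag == "tagged"))
  if (!is.null(block)) {
    lv <- sort(unique(as.character(block)))
    for (l in lv[-1]) X <- cbind(X, as.numeric(block == l))
  }
  bhat <- solve(crossprod(X), crossprod(X, y))
  rss_full <- sum((y - X %*% bhat)^2)
  df_res <- n - ncol(X)
  X0 <- X[, -2, drop = FALSE]       # drop the tag column, keep the rest
  b0 <- solve(crossprod(X0), crossprod(X0, y))
  rss_red <- sum((y - X0 %*% b0)^2)
  f <- (rss_red - rss_full) / (rss_full / df_res)
  list(estimate = bhat[2],
       se = sqrt(solve(crossprod(X))[2, 2] * rss_full / df_res),
       f = f,
       p = pf(f, 1, df_res, lower.tail = FALSE),
       df_den = df_res)
}

# random metrics table for stats fixtures (possibly unbalanced blocks)
random_metrics_table <- function(n_per_group = 10, n_blocks = 3,
                                 effect = 0, unbalanced = FALSE) {
  n <- 2 * n_per_group
  tag <- rep(c("untagged", "tagged"), each = n_per_group)
  block <- if (unbalanced) {
    sample(paste0("b", seq_len(n_blocks)), n, replace = TRUE,
           prob = seq_len(n_blocks))
  } else {
    paste0("b", rep_len(seq_len(n_blocks), n))
  }
  # regenerate until every block holds both groups (oracle needs full rank)
  while (length(unique(paste(block, tag))) < 2 * length(unique(block))) {
    block <- sample(paste0("b", seq_len(n_blocks)), n, replace = TRUE)
  }
  data.frame(
    individual_id = sprintf("i%02d", seq_len(n)),
    tag_group = tag, block = block,
    avg_speed_mm_s = rnorm(n, 3, 1) + effect * (tag == "tagged"),
    n_walks = rpois(n, 5 + 3 * effect * (tag == "tagged")),
    n_zones_explored = pmin(18L, rpois(n, 9)),
    stringsAsFactors = FALSE
  )
}
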