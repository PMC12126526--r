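# Trajectory kinematics: preprocessing of tracked positions, path length,
# total turning angle, linear/angular velocity and acceleration series, and
# velocity-threshold locomotion segmentation.

ARENA_SIDE_CM <- 25.4  # 10 inch square open arena

#' Construct a trajectory
#'
#' A trajectory is one animal's tracked 2-D position over a session:
#' strictly increasing timestamps, x/y coordinates and an optional
#' per-sample tracking confidence in `[0, 1]`. Coordinates are in arena
#' centimetres once calibrated (see [preprocess_trajectory()]).
#'
#' @param time Timestamps in seconds, strictly increasing.
#' @param x,y Coordinates (pixels before calibration, cm after).
#' @param confidence Optional tracking likelihood in `[0, 1]`.
#' @param arena_size Arena side length in cm (default 25.4, a 10 in square).
#' @return A tibble with class `trajectory` and an `arena_size` attribute.
#' @export
trajectory <- function(time, x, y, confidence = NULL,
                       arena_size = ARENA_SIDE_CM) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n)
  if (is.null(confidence)) confidence <- rep(1, n)
  stopifnot(length(confidence) == n)
  if (n >= 2 && any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), x = as.numeric(x),
                        y = as.numeric(y),
                        confidence = as.numeric(confidence))
  attr(out, "arena_size") <- arena_size
  class(out) <- c("trajectory", class(out))
  out
}

wrap_angle <- function(theta) {
  # wrap to (-pi, pi]
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

moving_average <- function(v, window) {
  # centered moving average; window shrinks symmetrically at the edges
  if (window <= 1) return(v)
  n <- length(v)
  half <- window %/% 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Preprocess a raw tracked trajectory
#'
#' Replaces low-confidence samples by linear interpolation in time, converts
#' pixel coordinates to arena centimetres, and applies a centered
#' moving-average smoother.
#'
#' @param traj A [trajectory()] in pixel (or already-calibrated) coordinates.
#' @param px_per_cm Calibration factor; coordinates are divided by it.
#'   Use 1 for already-calibrated input.
#' @param confidence_floor Samples with confidence below this are treated as
#'   dropouts and interpolated (default 0.6).
#' @param smooth_window Odd moving-average window length in samples;
#'   1 disables smoothing.
#' @return A calibrated, smoothed [trajectory()] (confidence reset to 1 at
#'   interpolated samples is *not* done; original confidences are kept).
#' @export
preprocess_trajectory <- function(traj, px_per_cm = 1,
                                  confidence_floor = 0.6,
                                  smooth_window = 5) {
  stopifnot(inherits(traj, "trajectory"))
  if (px_per_cm <= 0) stop("px_per_cm must be > 0", call. = FALSE)
  if (smooth_window %% 2 == 0) {
    stop("smooth_window must be odd", call. = FALSE)
  }
  bad <- traj$confidence < confidence_floor
  if (all(bad)) {
    stop("all samples fall below the confidence floor", call. = FALSE)
  }
  if (mean(bad) > 0.5) {
    warning(sprintf("%.0f%% of samples below the confidence floor; %s",
                    100 * mean(bad), "interpolation may be unreliable"),
            call. = FALSE)
  }
  x <- traj$x
  y <- traj$y
  if (any(bad)) {
    ok <- !bad
    x[bad] <- stats::approx(traj$time[ok], x[ok], xout = traj$time[bad],
                            rule = 2)$y
    y[bad] <- stats::approx(traj$time[ok], y[ok], xout = traj$time[bad],
                            rule = 2)$y
  }
  x <- moving_average(x / px_per_cm, smooth_window)
  y <- moving_average(y / px_per_cm, smooth_window)
  trajectory(traj$time, x, y, traj$confidence,
             arena_size = attr(traj, "arena_size"))
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean step lengths between consecutive samples, in metres
#' (input coordinates are cm).
#'
#' @param traj A calibrated [trajectory()].
#' @return Path length in m.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2) {
    warning("fewer than 2 samples; path length is 0", call. = FALSE)
    return(0)
  }
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)) / 100
}

# Retain samples so consecutive retained points are >= min_step_cm apart;
# tracking jitter at near-zero displacement otherwise produces unbounded
# heading changes.
retain_steps <- function(x, y, min_step_cm) {
  n <- length(x)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1
  for (i in 2:n) {
    if (sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2) >= min_step_cm) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep
}

#' Total turning angle of a trajectory
#'
#' Headings are taken from consecutive displacement vectors after merging
#' steps shorter than `min_step_cm`; the total turning angle is the sum of
#' absolute heading changes, each wrapped to `(-pi, pi]`. Unsigned by
#' design: session totals are path curvature, not net rotation.
#'
#' @param traj A calibrated [trajectory()].
#' @param min_step_cm Minimum displacement between retained samples (cm).
#' @return Total turning in radians (>= 0).
#' @export
total_turning_angle <- function(traj, min_step_cm = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 3) {
    warning("fewer than 3 samples; turning angle is 0", call. = FALSE)
    return(0)
  }
  keep <- retain_steps(traj$x, traj$y, min_step_cm)
  x <- traj$x[keep]
  y <- traj$y[keep]
  if (length(x) < 3) {
    warning("fewer than 3 retained samples; turning angle is 0",
            call. = FALSE)
    return(0)
  }
  theta <- atan2(diff(y), diff(x))
  sum(abs(wrap_angle(diff(theta))))
}

#' Kinematic series of a trajectory
#'
#' Per-step linear speed (cm/s), unsigned angular speed (rad/s), and their
#' first-difference accelerations. Speeds are aligned to step midpoints;
#' the angular speed at the first step and both accelerations at their first
#' point are `NA` (no preceding estimate).
#'
#' @param traj A calibrated [trajectory()].
#' @param min_step_cm Minimum displacement for heading estimation; steps
#'   shorter than this contribute zero heading change (jitter guard).
#' @return A tibble with columns `time` (step midpoints), `linear_velocity`
#'   (cm/s), `angular_velocity` (rad/s), `linear_acceleration` (cm/s^2),
#'   `angular_acceleration` (rad/s^2), and a `dt` column of step durations.
#' @export
kinematic_series <- function(traj, min_step_cm = 0) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(traj$time)
  if (any(dt <= 0)) stop("non-positive time step", call. = FALSE)
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  step <- sqrt(dx^2 + dy^2)
  v <- step / dt
  tmid <- traj$time[-nrow(traj)] + dt / 2

  theta <- atan2(dy, dx)
  dtheta <- abs(wrap_angle(diff(theta)))
  # heading is meaningless for sub-jitter steps
  if (min_step_cm > 0) {
    tiny <- step < min_step_cm
    dtheta[tiny[-1] | tiny[-length(tiny)]] <- 0
  }
  w <- c(NA_real_, dtheta / diff(tmid))
  a_lin <- c(NA_real_, diff(v) / diff(tmid))
  a_ang <- c(NA_real_, diff(w) / diff(tmid))

  tibble::tibble(time = tmid, dt = dt,
                 linear_velocity = v,
                 angular_velocity = w,
                 linear_acceleration = a_lin,
                 angular_acceleration = a_ang)
}

#' Segment a session into walking and non-walking intervals
#'
#' Walking wherever linear speed is at or above `v_threshold`; bouts shorter
#' than `min_bout_s` are merged into the flanking label (shortest first)
#' so the result tiles the session with no overlaps.
#'
#' @param series Output of [kinematic_series()].
#' @param v_threshold Walking speed threshold (cm/s), default 2.
#' @param min_bout_s Minimum bout duration in seconds, default 0.5.
#' @return A tibble with columns `start`, `end`, `label`
#'   (`"walking"`/`"nonwalking"`), tiling `[first, last]` sample time.
#' @export
segment_locomotion <- function(series, v_threshold = 2, min_bout_s = 0.5) {
  stopifnot(is.data.frame(series), nrow(series) >= 1)
  # each step spans [time - dt/2, time + dt/2]
  starts <- series$time - series$dt / 2
  ends <- series$time + series$dt / 2
  walking <- series$linear_velocity >= v_threshold

  r <- rle(walking)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  seg <- data.frame(start = starts[idx_start], end = ends[idx_end],
                    walking = r$values)

  # merge sub-minimum bouts into flanking labels, shortest first
  repeat {
    if (nrow(seg) <= 1) break
    dur <- seg$end - seg$start
    small <- which(dur < min_bout_s)
    if (length(small) == 0) break
    i <- small[which.min(dur[small])]
    if (i == 1) {
      seg$start[2] <- seg$start[1]
      seg <- seg[-1, , drop = FALSE]
    } else if (i == nrow(seg)) {
      seg$end[i - 1] <- seg$end[i]
      seg <- seg[-i, , drop = FALSE]
    } else {
      # split the short bout between neighbours (same label on both sides)
      mid <- (seg$start[i] + seg$end[i]) / 2
      seg$end[i - 1] <- mid
      seg$start[i + 1] <- mid
      seg <- seg[-i, , drop = FALSE]
    }
    # coalesce equal-label neighbours
    j <- 1
    while (j < nrow(seg)) {
      if (seg$walking[j] == seg$walking[j + 1]) {
        seg$end[j] <- seg$end[j + 1]
        seg <- seg[-(j + 1), , drop = FALSE]
      } else j <- j + 1
    }
  }
  tibble::tibble(start = seg$start, end = seg$end,
                 label = ifelse(seg$walking, "walking", "nonwalking"))
}

#' Summarise one session
#'
#' Whole-session distance and turning plus walking-restricted mean linear
#' and angular speed and the fraction of time spent walking.
#'
#' @param traj A calibrated [trajectory()].
#' @param segmentation Output of [segment_locomotion()]; computed from
#'   `traj` with default parameters when omitted.
#' @param animal_id,condition,session_id Session metadata carried through.
#' @param min_step_cm Jitter guard for the turning-angle computation only;
#'   velocity series use the raw (smoothed) positions.
#' @return A one-row tibble: `animal_id`, `condition`, `session_id`,
#'   `distance_m`, `turning_rad`, `mean_walk_v` (cm/s), `mean_walk_w`
#'   (rad/s), `walking_fraction`. Walk means are `NA` when the session has
#'   no walking time.
#' @export
session_summary <- function(traj, segmentation = NULL,
                            animal_id = NA_character_,
                            condition = NA_character_,
                            session_id = NA_character_,
                            min_step_cm = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  series <- kinematic_series(traj)
  if (is.null(segmentation)) segmentation <- segment_locomotion(series)

  walk <- segmentation[segmentation$label == "walking", , drop = FALSE]
  total_time <- max(segmentation$end) - min(segmentation$start)
  walk_time <- sum(walk$end - walk$start)

  in_walk <- rep(FALSE, nrow(series))
  for (k in seq_len(nrow(walk))) {
    in_walk <- in_walk |
      (series$time >= walk$start[k] & series$time <= walk$end[k])
  }
  wmean <- function(v, w) {
    ok <- is.finite(v) & w
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * series$dt[ok]) / sum(series$dt[ok])
  }
  mean_v <- if (walk_time > 0) wmean(series$linear_velocity, in_walk)
            else NA_real_
  mean_w <- if (walk_time > 0) wmean(series$angular_velocity, in_walk)
            else NA_real_

  tibble::tibble(
    animal_id = animal_id, condition = condition, session_id = session_id,
    distance_m = path_length(traj),
    turning_rad = total_turning_angle(traj, min_step_cm = min_step_cm),
    mean_walk_v = mean_v,
    mean_walk_w = mean_w,
    walking_fraction = if (total_time > 0) walk_time / total_time else 0
  )
}
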