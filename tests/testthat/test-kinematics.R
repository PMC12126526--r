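# Trajectory kinematics: preprocessing, path length, turning angle,
# velocity series and locomotion segmentation.

test_that("preprocessing is the identity for clean calibrated input", {
  traj <- line_trajectory(speed = 3, duration = 5)
  out <- preprocess_trajectory(traj, px_per_cm = 1, smooth_window = 1)
  expect_equal(out$x, traj$x)
  expect_equal(out$y, traj$y)
})

test_that("low-confidence dropouts are linearly interpolated", {
  traj <- trajectory(0:2, c(0, 100, 2), c(0, -50, 2),
                     confidence = c(1, 0.1, 1))
  out <- preprocess_trajectory(traj, smooth_window = 1)
  expect_equal(out$x[2], 1)
  expect_equal(out$y[2], 1)
})

test_that("preprocessing scales pixels to cm and flags heavy dropout", {
  traj <- trajectory(0:9, (0:9) * 10, rep(0, 10))
  out <- preprocess_trajectory(traj, px_per_cm = 10, smooth_window = 1)
  expect_equal(out$x, 0:9)

  conf <- c(rep(0.1, 6), rep(1, 4))
  expect_warning(
    preprocess_trajectory(trajectory(0:9, 0:9, 0:9, conf),
                          smooth_window = 1),
    "confidence floor")
  expect_error(
    preprocess_trajectory(trajectory(0:9, 0:9, 0:9, rep(0.1, 10))),
    "all samples")
})

test_that("moving-average smoothing reduces noise variance about 5x", {
  set.seed(42)
  n <- 4000
  traj <- trajectory(seq_len(n), 10 + rnorm(n), 10 + rnorm(n))
  out <- preprocess_trajectory(traj, smooth_window = 5)
  interior <- 10:(n - 10)
  ratio <- stats::var(traj$x[interior]) / stats::var(out$x[interior])
  expect_equal(ratio, 5, tolerance = 0.15)
})

test_that("path length handles degenerate, collinear and circular paths", {
  expect_warning(d0 <- path_length(trajectory(0, 1, 1)), "fewer than 2")
  expect_equal(d0, 0)

  # stationary animal
  expect_equal(path_length(trajectory(0:9, rep(2, 10), rep(3, 10))), 0)

  # 3-4-5: (0,0) -> (300, 400) cm in collinear steps is 5 m
  s <- seq(0, 1, length.out = 17)
  expect_equal(path_length(trajectory(s, 300 * s, 400 * s)), 5)

  # dense circle of radius 10 cm: perimeter ~ 2 pi 0.1 m
  circ <- circle_trajectory(r = 10, n = 720)
  expect_equal(path_length(circ), 2 * pi * 0.1, tolerance = 1e-4)
})

test_that("turning angle matches right angles and full laps", {
  # straight line turns nowhere
  expect_equal(total_turning_angle(line_trajectory()), 0)

  # open square visiting 3 corners: 3 right angles
  expect_equal(total_turning_angle(square_trajectory()), 3 * pi / 2,
               tolerance = 1e-9)

  # one dense lap of a circle: sum of exterior angles ~ 2 pi
  circ <- circle_trajectory(r = 10, n = 720)
  expect_equal(total_turning_angle(circ, min_step_cm = 0.01), 2 * pi,
               tolerance = 1e-2)

  expect_warning(a <- total_turning_angle(trajectory(0:1, 0:1, 0:1)),
                 "fewer than 3")
  expect_equal(a, 0)
})

test_that("path length and turning are rigid-motion invariant", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 50
    traj <- trajectory(seq_len(n), cumsum(rnorm(n)), cumsum(rnorm(n)))
    phi <- runif(1, 0, 2 * pi)
    shift <- runif(2, -100, 100)
    xr <- cos(phi) * traj$x - sin(phi) * traj$y + shift[1]
    yr <- sin(phi) * traj$x + cos(phi) * traj$y + shift[2]
    moved <- trajectory(traj$time, xr, yr)
    expect_equal(path_length(moved), path_length(traj), tolerance = 1e-9)
    expect_equal(total_turning_angle(moved), total_turning_angle(traj),
                 tolerance = 1e-9)
  }
})

test_that("path length grows monotonically as samples are appended", {
  set.seed(8)
  n <- 40
  x <- cumsum(rnorm(n))
  y <- cumsum(rnorm(n))
  lens <- vapply(2:n, function(k) {
    path_length(trajectory(seq_len(k), x[seq_len(k)], y[seq_len(k)]))
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
  expect_gte(total_turning_angle(trajectory(seq_len(n), x, y)), 0)
})

test_that("kinematic series recovers analytic velocities", {
  # constant-speed straight line at 5 cm/s
  ser <- kinematic_series(line_trajectory(speed = 5, duration = 10))
  expect_equal(ser$linear_velocity, rep(5, nrow(ser)), tolerance = 1e-9)
  expect_equal(ser$angular_velocity[-1], rep(0, nrow(ser) - 1),
               tolerance = 1e-9)

  # circular motion: speed r*omega, angular speed omega
  r <- 10; omega <- 0.8
  ser <- kinematic_series(circle_trajectory(r = r, omega = omega, n = 3600))
  expect_equal(mean(ser$linear_velocity), r * omega, tolerance = 1e-3)
  expect_equal(mean(ser$angular_velocity, na.rm = TRUE), omega,
               tolerance = 1e-3)

  # linear speed ramp 0 -> 10 cm/s over 10 s: acceleration 1 cm/s^2
  t <- seq(0, 10, by = 0.05)
  ramp <- trajectory(t, 0.5 * t^2, rep(0, length(t)))
  ser <- kinematic_series(ramp)
  expect_equal(mean(ser$linear_acceleration, na.rm = TRUE), 1,
               tolerance = 1e-6)

  expect_error(kinematic_series(trajectory(c(0, 1), 0:1, 0:1)[c(1, 1), ]),
               "strictly increasing|time step")
})

test_that("velocity estimates are sampling-rate stable for smooth paths", {
  v_coarse <- mean(kinematic_series(
    line_trajectory(speed = 4, duration = 10, fps = 10))$linear_velocity)
  v_fine <- mean(kinematic_series(
    line_trajectory(speed = 4, duration = 10, fps = 100))$linear_velocity)
  expect_equal(v_coarse, v_fine, tolerance = 1e-9)
})

test_that("locomotion segmentation labels and tiles the session", {
  t <- seq(0, 40, by = 0.1)

  # all rest
  still <- trajectory(t, rep(0, length(t)), rep(0, length(t)))
  seg <- segment_locomotion(kinematic_series(still), v_threshold = 2)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "nonwalking")
  expect_equal(c(seg$start, seg$end), range(t))

  # all walking at twice the threshold
  seg <- segment_locomotion(kinematic_series(
    line_trajectory(speed = 4, duration = 40)), v_threshold = 2)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "walking")

  # alternating 10 s blocks at 0 and 2x threshold: exact boundaries
  dt <- 0.1
  block <- rep(c(0, 4), each = 100)        # cm/s per 0.1 s step
  speed <- rep(block, 2)
  x <- cumsum(c(0, speed * dt))
  alt <- trajectory(seq(0, by = dt, length.out = length(x)), x,
                    rep(0, length(x)))
  seg <- segment_locomotion(kinematic_series(alt), v_threshold = 2,
                            min_bout_s = 1)
  expect_equal(seg$label,
               rep(c("nonwalking", "walking"), 2))
  expect_equal(seg$start[2], 10, tolerance = dt)
  expect_equal(seg$start[3], 20, tolerance = dt)
  expect_equal(seg$start[4], 30, tolerance = dt)
})

test_that("segmentation always tiles the series without overlap", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 300
    x <- cumsum(rnorm(n, sd = runif(1, 0.01, 0.5)))
    traj <- trajectory(seq_len(n) * 0.1, x, rev(x) + rnorm(n, sd = 0.1))
    ser <- kinematic_series(traj)
    seg <- segment_locomotion(ser, v_threshold = 2,
                              min_bout_s = runif(1, 0, 2))
    expect_equal(seg$start[1], min(ser$time - ser$dt / 2))
    expect_equal(seg$end[nrow(seg)], max(ser$time + ser$dt / 2))
    if (nrow(seg) > 1) {
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
      expect_true(all(seg$label[-1] != seg$label[-nrow(seg)]))
    }
  }
})

test_that("session summary restricts means to walking intervals", {
  # all-walking constant-speed line
  s <- session_summary(line_trajectory(speed = 5, duration = 30))
  expect_equal(s$mean_walk_v, 5, tolerance = 1e-9)
  expect_equal(s$walking_fraction, 1)
  expect_equal(s$distance_m, 1.5, tolerance = 1e-9)

  # half at speed v, half at rest
  dt <- 0.1
  speed <- rep(c(6, 0), each = 200)
  x <- cumsum(c(0, speed * dt))
  traj <- trajectory(seq(0, by = dt, length.out = length(x)), x,
                     rep(0, length(x)))
  s <- session_summary(traj)
  expect_equal(s$walking_fraction, 0.5, tolerance = 0.01)
  expect_equal(s$mean_walk_v, 6, tolerance = 0.01)

  # no walking at all: walk means are flagged missing
  still <- trajectory(seq(0, 30, 0.1), rep(1, 301), rep(1, 301))
  expect_warning(s <- session_summary(still), "turning angle is 0")
  expect_true(is.na(s$mean_walk_v))
  expect_equal(s$walking_fraction, 0)
})
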