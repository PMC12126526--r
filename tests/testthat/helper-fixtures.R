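# Fixture builders used across test files. All fixtures are constructed in
# code; no data files.

# straight constant-speed path: speed cm/s, duration s
line_trajectory <- function(speed = 5, duration = 10, fps = 30,
                            angle = 0, origin = c(0, 0)) {
  t <- seq(0, duration, by = 1 / fps)
  trajectory(t, origin[1] + speed * t * cos(angle),
             origin[2] + speed * t * sin(angle))
}

# circle of radius r (cm) at angular rate omega (rad/s), n samples per lap
circle_trajectory <- function(r = 10, omega = 1, n_laps = 1, n = 720) {
  t <- seq(0, n_laps * 2 * pi / omega, length.out = n_laps * n + 1)
  trajectory(t, r * cos(omega * t), r * sin(omega * t))
}

# open square path visiting 3 corners (three right-angle turns)
square_trajectory <- function(side = 10, pts_per_side = 50) {
  s <- seq(0, side, length.out = pts_per_side)
  x <- c(s, rep(side, pts_per_side - 1), rev(s)[-1], rep(0, pts_per_side - 1))
  y <- c(rep(0, pts_per_side), s[-1], rep(side, pts_per_side - 1),
         rev(s)[-1])
  trajectory(seq_along(x) - 1, x, y)
}

# dF/F trace with a rectangular pulse (height h, duration dur_s) centred in
# a session of total_s seconds, zero elsewhere
rect_pulse_trace <- function(h = 0.8, dur_s = 2, total_s = 20, fps = 100) {
  t <- seq(0, total_s, by = 1 / fps)
  start <- (total_s - dur_s) / 2
  v <- ifelse(t >= start & t < start + dur_s, h, 0)
  list(trace = v, fps = fps)
}

# symmetric triangular pulse: peak h, base b seconds
tri_pulse_trace <- function(h = 1, b = 4, total_s = 20, fps = 100) {
  t <- seq(0, total_s, by = 1 / fps)
  c0 <- total_s / 2
  v <- pmax(0, h * (1 - abs(t - c0) / (b / 2)))
  list(trace = v, fps = fps)
}

# independent re-statement of the weight-sensitivity rule, used as the
# oracle against classify_weight_sensitivity()
oracle_classify <- function(r_p, r_bw, r_w, tol = 0.20) {
  if (abs(r_bw - r_p) >= tol * r_p) return("unclassified")
  if (r_p - r_w > tol * r_p && r_bw - r_w > tol * r_bw) return("suppressed")
  if (r_w - r_p > tol * r_p && r_w - r_bw > tol * r_bw) return("enhanced")
  "unclassified"
}

# balanced randomized-block responses: 5 animals x 3 conditions
block_data <- function(cond_effects = c(probe_only = 0, balloon_weight = 0,
                                        weight = 0),
                       animal_sd = 0, noise_sd = 1, n_animals = 5,
                       seed = 1) {
  set.seed(seed)
  animals <- paste0("m", seq_len(n_animals))
  a_eff <- stats::rnorm(n_animals, 0, animal_sd)
  g <- expand.grid(animal_id = animals, condition = names(cond_effects),
                   stringsAsFactors = FALSE)
  g$value <- cond_effects[g$condition] + a_eff[match(g$animal_id, animals)] +
    stats::rnorm(nrow(g), 0, noise_sd)
  tibble::as_tibble(g)
}
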