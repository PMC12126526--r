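# Synthetic session generator: open-field trajectories from a two-state
# (walk/rest) Markov model with diffusive heading, and dF/F calcium traces
# from Poisson event trains convolved with a double-exponential indicator
# kernel, with planted condition effects and a ground-truth manifest.
#
# Defaults emulate the study conditions: a 25.4 cm square arena, 167 s
# sessions, three conditions (probe_only, balloon_weight, weight) in which
# the uncompensated weight cuts walking distance to roughly 0.44 x control,
# and a population of neurons with planted weight-suppressed and
# weight-enhanced subsets (50% rate change).

#' Behavior simulation parameters
#'
#' Per-condition movement parameters for the two-state walk/rest simulator.
#' Defaults are calibrated so that expected total distance matches the
#' reported condition means (about 5.6 m under probe-only and
#' balloon+weight, about 2.4 m under weight, a 0.44 ratio) over a 167 s
#' session, with walking speeds well below 10 cm/s.
#'
#' @param conditions Named list (one entry per condition) of lists with
#'   `walk_rate` (rest-to-walk transitions per s), `rest_rate` (walk-to-rest
#'   per s), `mean_speed` and `speed_sd` (cm/s, walking speed is a Gaussian
#'   truncated at 0), `heading_diffusion` (rad^2/s of the heading random
#'   walk while walking).
#' @param session_length_s Session duration, default 167 s.
#' @param fps Tracking camera rate, default 30 frames/s.
#' @param arena_size Square arena side, cm; default 25.4 (10 in).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(
    conditions = list(
      probe_only = list(walk_rate = 0.20, rest_rate = 0.20,
                        mean_speed = 6.7, speed_sd = 2.0,
                        heading_diffusion = 0.01),
      balloon_weight = list(walk_rate = 0.20, rest_rate = 0.20,
                            mean_speed = 6.7, speed_sd = 2.0,
                            heading_diffusion = 0.01),
      weight = list(walk_rate = 0.12, rest_rate = 0.22,
                    mean_speed = 4.2, speed_sd = 1.5,
                    heading_diffusion = 0.01)),
    session_length_s = 167, fps = 30, arena_size = ARENA_SIDE_CM) {
  stopifnot(session_length_s > 0, fps > 0, arena_size > 0)
  for (cond in names(conditions)) {
    p <- conditions[[cond]]
    stopifnot(p$walk_rate >= 0, p$rest_rate >= 0,
              p$mean_speed >= 0, p$speed_sd >= 0,
              p$heading_diffusion >= 0)
  }
  structure(list(conditions = conditions,
                 session_length_s = session_length_s,
                 fps = fps, arena_size = arena_size),
            class = "behavior_params")
}

#' Calcium simulation parameters
#'
#' Parameters of the Poisson-event / double-exponential-kernel trace
#' simulator. Kernel time constants default to GCaMP6m-scale values
#' (0.1 s rise, 1.0 s decay). Planted weight-suppressed neurons have their
#' event rate and transient amplitude multiplied by
#' `suppressed_multiplier` under the weight condition (and enhanced
#' neurons by `enhanced_multiplier`), the documented 50% rate change.
#'
#' @param n_neurons Number of neurons, default 124.
#' @param event_rate Baseline calcium-event rate, events/s, default 0.12.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal transient peak
#'   amplitude (dF/F); defaults give a median of 0.8.
#' @param rise_tau,decay_tau Kernel time constants, s.
#' @param noise_sd Additive Gaussian noise SD (dF/F), default 0.05.
#' @param planted_suppressed,planted_enhanced Neuron indices (disjoint) with
#'   planted weight effects; defaults plant 25 and 15 of 124.
#' @param suppressed_multiplier,enhanced_multiplier Weight-condition rate
#'   and amplitude multipliers, defaults 0.5 and 1.5.
#' @param session_length_s Session duration, default 167 s.
#' @param frame_rate Imaging rate, default 3 frames/s (500 frames).
#' @return A list of class `calcium_params`.
#' @export
calcium_params <- function(n_neurons = 124,
                           event_rate = 0.12,
                           amplitude_meanlog = log(0.8),
                           amplitude_sdlog = 0.25,
                           rise_tau = 0.1, decay_tau = 1.0,
                           noise_sd = 0.05,
                           planted_suppressed = seq_len(25),
                           planted_enhanced = 26:40,
                           suppressed_multiplier = 0.5,
                           enhanced_multiplier = 1.5,
                           session_length_s = 167,
                           frame_rate = 3) {
  stopifnot(n_neurons >= 1, event_rate >= 0, rise_tau > 0, decay_tau > 0,
            decay_tau > rise_tau, noise_sd >= 0,
            suppressed_multiplier > 0, enhanced_multiplier > 0,
            session_length_s > 0, frame_rate > 0)
  planted_suppressed <- intersect(planted_suppressed, seq_len(n_neurons))
  planted_enhanced <- intersect(planted_enhanced, seq_len(n_neurons))
  if (length(intersect(planted_suppressed, planted_enhanced)) > 0) {
    stop("planted suppressed and enhanced sets must be disjoint",
         call. = FALSE)
  }
  structure(list(n_neurons = n_neurons, event_rate = event_rate,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 noise_sd = noise_sd,
                 planted_suppressed = planted_suppressed,
                 planted_enhanced = planted_enhanced,
                 suppressed_multiplier = suppressed_multiplier,
                 enhanced_multiplier = enhanced_multiplier,
                 session_length_s = session_length_s,
                 frame_rate = frame_rate),
            class = "calcium_params")
}

reflect_into <- function(p, size) {
  # reflect a coordinate into [0, size] (handles multiple bounces)
  p <- p %% (2 * size)
  ifelse(p > size, 2 * size - p, p)
}

#' Simulate one open-field trajectory
#'
#' Two-state walk/rest Markov chain sampled at the camera rate. While
#' walking, per-frame speed is Gaussian truncated at zero and heading
#' performs a random walk with variance `heading_diffusion * dt`; positions
#' reflect off the arena walls. Deterministic for a fixed seed.
#'
#' @param params A [behavior_params()].
#' @param condition Condition name, a key of `params$conditions`.
#' @param seed Integer seed.
#' @return A list: `traj` (a [trajectory()]) and `truth` (condition,
#'   parameters used, realized walking fraction and expected distance).
#' @export
simulate_trajectory <- function(params, condition, seed) {
  stopifnot(inherits(params, "behavior_params"),
            condition %in% names(params$conditions))
  set.seed(seed)
  p <- params$conditions[[condition]]
  dt <- 1 / params$fps
  n <- floor(params$session_length_s * params$fps) + 1
  p_start <- 1 - exp(-p$walk_rate * dt)
  p_stop <- 1 - exp(-p$rest_rate * dt)

  walking <- logical(n)
  wf0 <- if (p$walk_rate + p$rest_rate > 0)
    p$walk_rate / (p$walk_rate + p$rest_rate) else 0
  walking[1] <- stats::runif(1) < wf0
  u <- stats::runif(n - 1)
  for (i in 2:n) {
    walking[i] <- if (walking[i - 1]) u[i - 1] >= p_stop
                  else u[i - 1] < p_start
  }

  speed <- ifelse(walking,
                  pmax(0, stats::rnorm(n, p$mean_speed, p$speed_sd)), 0)
  heading <- cumsum(c(stats::runif(1, -pi, pi),
                      stats::rnorm(n - 1, 0,
                                   sqrt(p$heading_diffusion * dt))))
  x <- cumsum(c(params$arena_size / 2, speed[-n] * cos(heading[-n]) * dt))
  y <- cumsum(c(params$arena_size / 2, speed[-n] * sin(heading[-n]) * dt))
  x <- reflect_into(x, params$arena_size)
  y <- reflect_into(y, params$arena_size)

  traj <- trajectory((seq_len(n) - 1) * dt, x, y,
                     arena_size = params$arena_size)
  truth <- list(condition = condition, params = p,
                walking_fraction = mean(walking),
                expected_distance_m =
                  wf0 * params$session_length_s * p$mean_speed / 100)
  list(traj = traj, truth = truth)
}

#' Unit-peak calcium indicator kernel
#'
#' Double-exponential impulse response `exp(-t/decay) - exp(-t/rise)`,
#' normalized so its maximum is 1; zero for `t < 0`.
#'
#' @param t Time since the event, s (vectorized).
#' @param rise_tau,decay_tau Time constants, s, with `decay_tau > rise_tau`.
#' @return Kernel values.
#' @export
ca_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  ifelse(t < 0, 0, (exp(-t / decay_tau) - exp(-t / rise_tau)) / peak)
}

#' Integral of the unit-peak calcium kernel
#'
#' Closed form `(decay_tau - rise_tau) / peak_value`; an event of amplitude
#' `A` contributes `A` times this area to its trace.
#'
#' @param rise_tau,decay_tau Kernel time constants, s.
#' @return Kernel area in dF/F x s per unit amplitude.
#' @export
ca_kernel_area <- function(rise_tau, decay_tau) {
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  (decay_tau - rise_tau) / peak
}

condition_multiplier <- function(cp, condition) {
  mult <- rep(1, cp$n_neurons)
  if (condition == "weight") {
    mult[cp$planted_suppressed] <- cp$suppressed_multiplier
    mult[cp$planted_enhanced] <- cp$enhanced_multiplier
  }
  mult
}

#' Simulate a dF/F trace set
#'
#' Per neuron, a homogeneous Poisson train of calcium events at the
#' condition-adjusted rate; each event adds a double-exponential kernel
#' scaled by a log-normal amplitude (also condition-adjusted for planted
#' neurons), plus white Gaussian noise. Deterministic for a fixed seed.
#'
#' @param params A [calcium_params()].
#' @param condition Condition name.
#' @param seed Integer seed.
#' @param animal_id,experiment Metadata carried into the [trace_set()].
#' @return A list: `traces` (a [trace_set()]) and `truth` (per-neuron true
#'   event rate, amplitude multiplier and planted label).
#' @export
simulate_traces <- function(params, condition, seed,
                            animal_id = NA_character_,
                            experiment = NA_integer_) {
  stopifnot(inherits(params, "calcium_params"))
  set.seed(seed)
  n_frames <- round(params$session_length_s * params$frame_rate)
  times <- (seq_len(n_frames) - 1) / params$frame_rate
  mult <- condition_multiplier(params, condition)

  dff <- matrix(0, params$n_neurons, n_frames)
  for (i in seq_len(params$n_neurons)) {
    rate <- params$event_rate * mult[i]
    n_ev <- stats::rpois(1, rate * params$session_length_s)
    if (n_ev > 0) {
      ev_t <- sort(stats::runif(n_ev, 0, params$session_length_s))
      amp <- stats::rlnorm(n_ev, params$amplitude_meanlog,
                           params$amplitude_sdlog) * mult[i]
      for (k in seq_len(n_ev)) {
        dff[i, ] <- dff[i, ] +
          amp[k] * ca_kernel(times - ev_t[k], params$rise_tau,
                             params$decay_tau)
      }
    }
    if (params$noise_sd > 0) {
      dff[i, ] <- dff[i, ] + stats::rnorm(n_frames, 0, params$noise_sd)
    }
  }
  label <- rep("null", params$n_neurons)
  label[params$planted_suppressed] <- "suppressed"
  label[params$planted_enhanced] <- "enhanced"

  ts <- trace_set(dff, frame_rate = params$frame_rate,
                  neuron_ids = as.character(seq_len(params$n_neurons)),
                  animal_id = animal_id, condition = condition,
                  experiment = experiment)
  truth <- tibble::tibble(neuron_id = ts$neuron_ids,
                          true_event_rate = params$event_rate * mult,
                          multiplier = mult, planted = label)
  list(traces = ts, truth = truth)
}

# deterministic fan-out of a master seed into per-use seeds
split_seed <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# per-animal walking-speed multipliers (mild individual differences)
animal_multipliers <- function(n_animals, animal_speed_sd, seed) {
  set.seed(seed)
  exp(stats::rnorm(n_animals, 0, animal_speed_sd))
}

scale_condition_speed <- function(behavior, mult) {
  for (cond in names(behavior$conditions)) {
    behavior$conditions[[cond]]$mean_speed <-
      behavior$conditions[[cond]]$mean_speed * mult
  }
  behavior
}

#' Simulate a behavior-only cohort in memory
#'
#' Runs the trajectory simulator and the kinematics stage
#' (preprocess, segment, summarise) for `n_animals` animals under the three
#' conditions and returns the session-summary table, without touching disk.
#' Each animal gets a log-normal individual walking-speed multiplier of SD
#' `animal_speed_sd` (applied across all conditions), emulating mild
#' animal-to-animal differences.
#'
#' @param behavior A [behavior_params()].
#' @param n_animals Number of animals, default 5.
#' @param seed Master seed.
#' @param animal_speed_sd SD of the log individual speed multiplier,
#'   default 0.08; 0 for identical animals.
#' @return A session-summary tibble (see [session_summary()]).
#' @export
simulate_session_records <- function(behavior = behavior_params(),
                                     n_animals = 5, seed = 1,
                                     animal_speed_sd = 0.08) {
  conds <- names(behavior$conditions)
  seeds <- split_seed(seed, n_animals * length(conds))
  mult <- animal_multipliers(n_animals, animal_speed_sd, seed)
  rows <- list()
  k <- 0
  for (a in seq_len(n_animals)) {
    bp <- scale_condition_speed(behavior, mult[a])
    for (cond in conds) {
      k <- k + 1
      sim <- simulate_trajectory(bp, cond, seeds[k])
      traj <- preprocess_trajectory(sim$traj)
      rows[[k]] <- session_summary(traj, animal_id = paste0("m", a),
                                   condition = cond,
                                   session_id = sprintf("a%d_%s", a, cond))
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort on disk
#'
#' Emulates the study design: `n_animals` mice, each run under the three
#' conditions in each of `n_experiments` repeated experiments; the last
#' animal is additionally "imaged", producing dF/F trace files per
#' condition and experiment. Writes trajectory and trace files in the
#' dialects the pipeline reads, a session manifest and a ground-truth
#' manifest. Deterministic for a fixed master seed.
#'
#' @param out_dir Output directory (created; must not already exist unless
#'   `force = TRUE`).
#' @param behavior A [behavior_params()].
#' @param calcium A [calcium_params()], or `NULL` to skip traces.
#' @param n_animals Number of animals, default 5.
#' @param n_experiments Repeated experiments, default 1.
#' @param seed Master seed; per-session seeds are drawn from it by a fixed
#'   splitting rule.
#' @param animal_speed_sd SD of the log-normal per-animal walking-speed
#'   multiplier (individual differences), default 0.08.
#' @param force Overwrite an existing directory.
#' @return The manifest tibble (invisibly also written to
#'   `manifest.csv`; ground truth in `ground_truth.json`).
#' @export
make_cohort <- function(out_dir,
                        behavior = behavior_params(),
                        calcium = calcium_params(),
                        n_animals = 5, n_experiments = 1,
                        seed = 1, animal_speed_sd = 0.08, force = FALSE) {
  if (dir.exists(out_dir)) {
    if (!force) stop("output directory exists (use force = TRUE): ",
                     out_dir, call. = FALSE)
  } else {
    dir.create(out_dir, recursive = TRUE)
  }
  conds <- names(behavior$conditions)
  grid <- expand.grid(condition = conds,
                      animal = seq_len(n_animals),
                      experiment = seq_len(n_experiments),
                      stringsAsFactors = FALSE)
  seeds <- split_seed(seed, 2 * nrow(grid))
  mult <- animal_multipliers(n_animals, animal_speed_sd, seed)
  imaging_animal <- n_animals

  rows <- list()
  truth_traces <- list()
  truth_beh <- list()
  for (r in seq_len(nrow(grid))) {
    cond <- grid$condition[r]
    a <- grid$animal[r]
    e <- grid$experiment[r]
    sim <- simulate_trajectory(scale_condition_speed(behavior, mult[a]),
                               cond, seeds[2 * r - 1])
    traj_file <- sprintf("traj_a%d_e%d_%s.csv", a, e, cond)
    write_trajectory(sim$traj, file.path(out_dir, traj_file))
    truth_beh[[r]] <- c(list(animal_id = paste0("m", a), experiment = e),
                        sim$truth)

    trace_file <- NA_character_
    if (!is.null(calcium) && a == imaging_animal) {
      simc <- simulate_traces(calcium, cond, seeds[2 * r],
                              animal_id = paste0("m", a), experiment = e)
      trace_file <- sprintf("traces_a%d_e%d_%s.csv", a, e, cond)
      write_traces(simc$traces, file.path(out_dir, trace_file))
      key <- sprintf("e%d_%s", e, cond)
      truth_traces[[key]] <- simc$truth
    }
    rows[[r]] <- tibble::tibble(
      animal_id = paste0("m", a), condition = cond, experiment = e,
      session_id = sprintf("a%d_e%d_%s", a, e, cond),
      trajectory_file = traj_file, trace_file = trace_file,
      fps = behavior$fps,
      trace_fps = if (is.null(calcium)) NA_real_ else calcium$frame_rate,
      px_per_cm = 1, arena_size = behavior$arena_size)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  planted <- if (is.null(calcium)) NULL else list(
    suppressed = calcium$planted_suppressed,
    enhanced = calcium$planted_enhanced,
    suppressed_multiplier = calcium$suppressed_multiplier,
    enhanced_multiplier = calcium$enhanced_multiplier)
  gt <- list(seed = seed,
             behavior = lapply(behavior$conditions, function(p) p),
             planted = planted,
             sessions = truth_beh)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
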