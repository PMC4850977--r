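#' Per-location signal fidelity profile
#'
#' Describes how faithfully an IMU at one body location reproduces the common
#' roll motion: a multiplicative gain on the latent roll signal, independent
#' Gaussian measurement/soft-tissue noise, and an optional extra oscillation
#' emulating limb swing artifacts at arm and hand placements.
#'
#' @param location Body-location label, one of the 16 full-body placements
#'   (see [body_locations()]).
#' @param gain Unitless scale on the latent roll signal (>= 0).
#' @param artifact_noise_sd Independent per-sample noise, degrees (>= 0).
#' @param artifact_amplitude,artifact_freq_hz Amplitude (degrees) and
#'   frequency of an additive sinusoidal artifact; amplitude 0 disables it.
#' @return A list of class `location_profile`.
#' @export
location_profile <- function(location, gain = 1, artifact_noise_sd = 0,
                             artifact_amplitude = 0, artifact_freq_hz = 0) {
  if (gain < 0) stop("gain must be >= 0")
  if (artifact_noise_sd < 0) stop("artifact_noise_sd must be >= 0")
  structure(list(location = location, gain = gain,
                 artifact_noise_sd = artifact_noise_sd,
                 artifact_amplitude = artifact_amplitude,
                 artifact_freq_hz = artifact_freq_hz),
            class = "location_profile")
}

#' The 16 full-body IMU placement labels
#'
#' @return Character vector of location labels. Midline placements are
#'   `head`, `upper_spine`, `lower_spine` and `pelvis`; the rest are
#'   left/right pairs.
#' @export
body_locations <- function() {
  c("head", "upper_spine", "lower_spine", "pelvis",
    "upper_arm_L", "upper_arm_R", "forearm_L", "forearm_R",
    "hand_L", "hand_R", "thigh_L", "thigh_R",
    "shank_L", "shank_R", "foot_L", "foot_R")
}

#' Default location fidelity profiles
#'
#' Spine, pelvis and leg placements track the latent roll with unit gain;
#' their noise grows toward the snow (foot and shank carry the most
#' ski-transmitted vibration, the pelvis, close to the body's center of
#' mass, the least), so the pelvis attains the highest pattern correlation.
#' Arm and hand placements have reduced gain, heavy noise and a 2 Hz swing
#' artifact; the head sits in between. Absolute gains and noise levels are
#' free parameters of the simulation (the field reports only the resulting
#' correlation ordering).
#'
#' @return Named list of [location_profile()]s covering [body_locations()].
#' @export
default_location_profiles <- function() {
  prof <- list(
    head        = location_profile("head", gain = 0.8, artifact_noise_sd = 8),
    upper_spine = location_profile("upper_spine", gain = 1, artifact_noise_sd = 3),
    lower_spine = location_profile("lower_spine", gain = 1, artifact_noise_sd = 3),
    pelvis      = location_profile("pelvis", gain = 1, artifact_noise_sd = 1)
  )
  for (side in c("L", "R")) {
    prof[[paste0("upper_arm_", side)]] <- location_profile(
      paste0("upper_arm_", side), gain = 0.6, artifact_noise_sd = 8,
      artifact_amplitude = 8, artifact_freq_hz = 2)
    prof[[paste0("forearm_", side)]] <- location_profile(
      paste0("forearm_", side), gain = 0.6, artifact_noise_sd = 8,
      artifact_amplitude = 8, artifact_freq_hz = 2)
    prof[[paste0("hand_", side)]] <- location_profile(
      paste0("hand_", side), gain = 0.6, artifact_noise_sd = 12,
      artifact_amplitude = 12, artifact_freq_hz = 2)
    prof[[paste0("thigh_", side)]] <- location_profile(
      paste0("thigh_", side), gain = 1, artifact_noise_sd = 4)
    prof[[paste0("shank_", side)]] <- location_profile(
      paste0("shank_", side), gain = 1, artifact_noise_sd = 5)
    prof[[paste0("foot_", side)]] <- location_profile(
      paste0("foot_", side), gain = 1, artifact_noise_sd = 5)
  }
  prof[body_locations()]
}

#' Simulation configuration for synthetic skiing sessions
#'
#' Defines the statistical structure of a generated session: alternating
#' left/right turns expressed as a signed roll oscillation, an outer-foot
#' weight shift in the insole streams, per-location signal fidelity, a
#' left/right duration and loading asymmetry, and a linear adaptation trend
#' (turns speed up across attempts). Defaults reproduce the observed study
#' conditions: side mean durations 2.08 s (right) / 1.68 s (left), pooled
#' duration SD 0.32 s, outer-foot peak fractions 0.86 (left turns) / 0.81
#' (right turns) with SDs 0.05 / 0.09, and an adaptation slope of -0.047 s
#' per turn per attempt.
#'
#' @param n_trials Number of recorded trials (default 8).
#' @param turns_per_trial Turns per trial (default 6), alternating and
#'   starting with a right turn.
#' @param mean_duration_right_s,mean_duration_left_s Mean turn duration per
#'   side, seconds.
#' @param duration_sd_s SD of individual turn durations, seconds.
#' @param adaptation_slope_s_per_trial Change in every turn's mean duration
#'   per unit attempt index, seconds (negative = speeding up).
#' @param roll_amplitude_deg Peak latent roll angle, degrees.
#' @param outer_foot_peak_fraction_left_turns,outer_foot_peak_fraction_right_turns
#'   Mean peak fraction of total force on the outer foot, in (0.5, 1].
#' @param peak_fraction_sd_left_turns,peak_fraction_sd_right_turns Per-turn SD
#'   of the peak fraction.
#' @param location_profiles Named list of [location_profile()]s; locations to
#'   simulate. Default [default_location_profiles()].
#' @param imu_rate_hz IMU sampling rate (default 100).
#' @param pressure_rate_hz Insole sampling rate (default 50).
#' @param noise_sd Common roll measurement noise, degrees.
#' @param pressure_noise_sd Per-cell insole noise, N/cm^2.
#' @param total_force Two-foot total force, summed N/cm^2 across cells.
#' @param seed Integer seed for [simulate_session()].
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_trials = 8L,
                              turns_per_trial = 6L,
                              mean_duration_right_s = 2.08,
                              mean_duration_left_s = 1.68,
                              duration_sd_s = 0.32,
                              adaptation_slope_s_per_trial = -0.047,
                              roll_amplitude_deg = 30,
                              outer_foot_peak_fraction_left_turns = 0.86,
                              outer_foot_peak_fraction_right_turns = 0.81,
                              peak_fraction_sd_left_turns = 0.05,
                              peak_fraction_sd_right_turns = 0.09,
                              location_profiles = default_location_profiles(),
                              imu_rate_hz = 100,
                              pressure_rate_hz = 50,
                              noise_sd = 1,
                              pressure_noise_sd = 0.1,
                              total_force = 40,
                              seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials),
              turns_per_trial = as.integer(turns_per_trial),
              mean_duration_right_s = mean_duration_right_s,
              mean_duration_left_s = mean_duration_left_s,
              duration_sd_s = duration_sd_s,
              adaptation_slope_s_per_trial = adaptation_slope_s_per_trial,
              roll_amplitude_deg = roll_amplitude_deg,
              outer_foot_peak_fraction_left_turns = outer_foot_peak_fraction_left_turns,
              outer_foot_peak_fraction_right_turns = outer_foot_peak_fraction_right_turns,
              peak_fraction_sd_left_turns = peak_fraction_sd_left_turns,
              peak_fraction_sd_right_turns = peak_fraction_sd_right_turns,
              location_profiles = location_profiles,
              imu_rate_hz = imu_rate_hz,
              pressure_rate_hz = pressure_rate_hz,
              noise_sd = noise_sd,
              pressure_noise_sd = pressure_noise_sd,
              total_force = total_force,
              seed = as.integer(seed))
  if (cfg$n_trials < 1L) stop("n_trials must be >= 1")
  if (cfg$turns_per_trial < 1L) stop("turns_per_trial must be >= 1")
  if (cfg$imu_rate_hz <= 0 || cfg$pressure_rate_hz <= 0)
    stop("sampling rates must be positive")
  if (cfg$mean_duration_right_s <= 0 || cfg$mean_duration_left_s <= 0)
    stop("mean turn durations must be positive")
  if (cfg$duration_sd_s < 0 || cfg$noise_sd < 0 || cfg$pressure_noise_sd < 0)
    stop("standard deviations must be >= 0")
  for (fr in c(cfg$outer_foot_peak_fraction_left_turns,
               cfg$outer_foot_peak_fraction_right_turns))
    if (fr <= 0.5 || fr > 1)
      stop("outer-foot peak fractions must lie in (0.5, 1]")
  if (cfg$total_force <= 0) stop("total_force must be positive")
  if (is.null(names(cfg$location_profiles)) ||
      !all(vapply(cfg$location_profiles, inherits, TRUE, "location_profile")))
    stop("location_profiles must be a named list of location_profile objects")
  # the adaptation drift must not push any per-turn mean to zero within the session
  drift <- cfg$adaptation_slope_s_per_trial * (cfg$n_trials - 1L)
  if (min(cfg$mean_duration_right_s, cfg$mean_duration_left_s) + min(0, drift) <= 0)
    stop("adaptation slope drives mean turn durations non-positive ",
         "within the session; reduce |adaptation_slope_s_per_trial|")
  structure(cfg, class = "sim_config")
}

# sides of turns within a trial: alternating, first turn to the right
turn_sides <- function(n_turns) rep(c("R", "L"), length.out = n_turns)

# Draw per-turn durations and outer-foot peak fractions for one attempt.
# This is the generator's statistical core; waveform synthesis sits on top.
draw_turn_parameters <- function(config, attempt_index) {
  sides <- turn_sides(config$turns_per_trial)
  mu <- ifelse(sides == "R", config$mean_duration_right_s,
               config$mean_duration_left_s) +
    config$adaptation_slope_s_per_trial * (attempt_index - 1L)
  if (any(mu <= 0))
    stop("adaptation drift yields non-positive mean duration at attempt ",
         attempt_index)
  durations <- stats::rnorm(length(sides), mu, config$duration_sd_s)
  for (i in seq_len(100L)) {
    bad <- durations <= 0.1
    if (!any(bad)) break
    durations[bad] <- stats::rnorm(sum(bad), mu[bad], config$duration_sd_s)
  }
  if (any(durations <= 0.1))
    stop("could not draw positive turn durations; duration_sd_s too large")
  pk_mu <- ifelse(sides == "L", config$outer_foot_peak_fraction_left_turns,
                  config$outer_foot_peak_fraction_right_turns)
  pk_sd <- ifelse(sides == "L", config$peak_fraction_sd_left_turns,
                  config$peak_fraction_sd_right_turns)
  peaks <- pmin(pmax(stats::rnorm(length(sides), pk_mu, pk_sd), 0.505), 1)
  list(sides = sides, durations = durations, peak_fractions = peaks)
}

#' Simulate one trial (run) of alternating ski turns
#'
#' Builds a latent roll signal as one half-sine per turn (positive lobes for
#' right turns, negative for left), samples each configured location as
#' gain x latent + noise (+ optional artifact oscillation), and synthesizes
#' the paired insole streams with a raised-cosine outer-foot weight shift
#' that peaks mid-turn. Draws are taken from the current RNG state; seed the
#' session with [simulate_session()] for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param trial_index Attempt index >= 1; enters the adaptation drift.
#' @return A list of class `trial_recording` with elements `traces` (named
#'   list of [ski_ts()]), `insole_left`, `insole_right`, `meta`, and a
#'   `ground_truth` list (turn boundary sample indices, sides, true durations
#'   and peak fractions).
#' @export
simulate_trial <- function(config, trial_index) {
  stopifnot(inherits(config, "sim_config"))
  if (trial_index < 1L) stop("trial_index must be >= 1")
  par <- draw_turn_parameters(config, trial_index)
  rate <- config$imu_rate_hz

  # quantize durations to whole IMU samples so ground-truth boundaries are exact
  n_samp <- pmax(2L, as.integer(round(par$durations * rate)))
  durations <- n_samp / rate
  ends <- cumsum(n_samp)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  sign_of <- ifelse(par$sides == "R", 1, -1)

  latent <- numeric(sum(n_samp))
  for (k in seq_along(n_samp)) {
    j <- seq_len(n_samp[k])
    # half-offset sampling keeps every in-turn sample strictly off zero
    latent[starts[k]:ends[k]] <-
      sign_of[k] * config$roll_amplitude_deg * sin(pi * (j - 0.5) / n_samp[k])
  }
  t_imu <- (seq_along(latent) - 1L) / rate

  traces <- lapply(config$location_profiles, function(p) {
    v <- p$gain * latent
    if (p$artifact_amplitude > 0)
      v <- v + p$artifact_amplitude * sin(2 * pi * p$artifact_freq_hz * t_imu)
    sd_tot <- sqrt(config$noise_sd^2 + p$artifact_noise_sd^2)
    if (sd_tot > 0) v <- v + stats::rnorm(length(v), 0, sd_tot)
    ski_ts(v, rate, 0, p$location)
  })
  names(traces) <- vapply(config$location_profiles, `[[`, "", "location")

  # insole streams at the pressure rate over the same span
  total_dur <- sum(durations)
  n_p <- max(2L, floor(total_dur * config$pressure_rate_hz))
  t_p <- (seq_len(n_p) - 1L) / config$pressure_rate_hz
  turn_of <- findInterval(t_p, c(0, cumsum(durations)),
                          rightmost.closed = TRUE)
  turn_of <- pmin(pmax(turn_of, 1L), length(durations))
  t_start <- c(0, utils::head(cumsum(durations), -1L))
  u <- (t_p - t_start[turn_of]) / durations[turn_of]
  outer_frac <- 0.5 + (par$peak_fractions[turn_of] - 0.5) *
    (1 - cos(2 * pi * u)) / 2
  # right turn (positive roll) loads the left (outer) foot
  left_frac <- ifelse(par$sides[turn_of] == "R", outer_frac, 1 - outer_frac)
  make_cells <- function(frac) {
    m <- matrix(rep(frac * config$total_force / 13, 13L), ncol = 13L)
    if (config$pressure_noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, config$pressure_noise_sd),
                      ncol = 13L)
    pmax(m, 0)
  }
  insole_left <- insole_stream(make_cells(left_frac), "L",
                               config$pressure_rate_hz)
  insole_right <- insole_stream(make_cells(1 - left_frac), "R",
                                config$pressure_rate_hz)

  structure(list(
    traces = traces,
    insole_left = insole_left,
    insole_right = insole_right,
    meta = list(attempt = as.integer(trial_index),
                n_turns = config$turns_per_trial,
                imu_rate_hz = rate,
                pressure_rate_hz = config$pressure_rate_hz),
    ground_truth = list(boundaries = ends, sides = par$sides,
                        durations = durations,
                        peak_fractions = par$peak_fractions)
  ), class = "trial_recording")
}

#' Simulate a full session of trials with known ground truth
#'
#' Seeds a single RNG stream from `config$seed` and generates one
#' [simulate_trial()] per recorded attempt. Attempts listed in
#' `missing_attempts` are kept in the manifest (they count toward the
#' adaptation axis) but carry no recording, emulating a discarded run.
#'
#' @param config A [simulation_config()].
#' @param missing_attempts Integer attempt indices excluded from recording.
#' @return A list of class `ski_session`: `trials` (named list keyed
#'   `attempt_<i>`), `manifest` (data frame: attempt, status, n_turns),
#'   `ground_truth` and `config`.
#' @examples
#' cfg <- simulation_config(n_trials = 2, seed = 42)
#' s <- simulate_session(cfg)
#' s$manifest
#' @export
simulate_session <- function(config, missing_attempts = integer(0)) {
  stopifnot(inherits(config, "sim_config"))
  missing_attempts <- sort(unique(as.integer(missing_attempts)))
  n_attempts <- config$n_trials + length(missing_attempts)
  if (length(missing_attempts) && any(missing_attempts > n_attempts))
    stop("missing_attempts indices exceed the total attempt count")
  valid <- setdiff(seq_len(n_attempts), missing_attempts)
  set.seed(config$seed)
  trials <- lapply(valid, function(a) simulate_trial(config, a))
  names(trials) <- paste0("attempt_", valid)
  manifest <- data.frame(
    attempt = seq_len(n_attempts),
    status = ifelse(seq_len(n_attempts) %in% valid, "valid", "excluded"),
    n_turns = config$turns_per_trial)
  structure(list(trials = trials,
                 manifest = manifest,
                 ground_truth = lapply(trials, `[[`, "ground_truth"),
                 config = config),
            class = "ski_session")
}

#' @export
print.ski_session <- function(x, ...) {
  cat(sprintf("<ski_session> %d attempts (%d recorded), %d turns each, %d locations\n",
              nrow(x$manifest), sum(x$manifest$status == "valid"),
              x$manifest$n_turns[1], length(x$trials[[1]]$traces)))
  invisible(x)
}

#' Simulate a session's turn-level performance table directly
#'
#' Draws the same per-turn durations and outer-foot peak fractions as
#' [simulate_session()] but skips waveform synthesis, returning the turn
#' table the performance analyses consume. Used for Monte-Carlo studies
#' (power, type-I error, parameter recovery) where only the turn-level
#' statistics matter.
#'
#' @param config A [simulation_config()]. `config$seed` is NOT applied here;
#'   seed the RNG yourself so replicates differ.
#' @return A `turn_table` data frame (trial, turn, side, duration_s,
#'   max_pressure_ratio).
#' @export
simulate_turn_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(seq_len(config$n_trials), function(tr) {
    par <- draw_turn_parameters(config, tr)
    data.frame(trial = tr, turn = seq_along(par$sides), side = par$sides,
               duration_s = par$durations,
               max_pressure_ratio = par$peak_fractions)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("turn_table", "data.frame")
  out
}
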