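# Shared test helpers: published reference tables inlined for ranking tests,
# and compact generator configs.

# Median pattern correlations per body location (8-trial study, Table-2 style).
published_medians <- c(
  head = 0.77, upper_spine = 0.88, lower_spine = 0.87, pelvis = 0.88,
  upper_arm_L = 0.70, upper_arm_R = 0.61, forearm_L = 0.73, forearm_R = 0.56,
  hand_L = 0.31, hand_R = 0.52, thigh_L = 0.89, thigh_R = 0.84,
  shank_L = 0.84, shank_R = 0.87, foot_L = 0.86, foot_R = 0.87)

# Turn-detection percentages for the nine candidate locations (Table-3 style).
published_detection <- rbind(
  upper_spine = c(100, 100, 100, 129, 100, 100, 100, 100),
  lower_spine = c(100, 0, 100, 100, 100, 0, 100, 100),
  pelvis      = c(100, 100, 100, 100, 100, 100, 100, 100),
  thigh_L     = c(129, 100, 100, 100, 100, 100, 100, 100),
  thigh_R     = c(200, 129, 114, 100, 171, 114, 286, 171),
  shank_L     = c(86, 100, 100, 100, 100, 100, 100, 100),
  shank_R     = c(100, 100, 100, 100, 100, 100, 100, 100),
  foot_L      = c(100, 100, 100, 100, 100, 100, 100, 100),
  foot_R      = c(100, 100, 100, 100, 100, 100, 100, 100))

# Wrap the published summaries in the table classes rank_locations() expects.
published_cor_table <- function() {
  tab <- data.frame(location = names(published_medians),
                    mean = unname(published_medians),
                    median = unname(published_medians))
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

published_det_table <- function() {
  tab <- data.frame(location = rownames(published_detection),
                    published_detection)
  names(tab)[-1] <- paste0("attempt_", 1:8)
  tab$average <- rowMeans(published_detection)
  rownames(tab) <- NULL
  class(tab) <- c("detection_table", "data.frame")
  tab
}

# Pelvis-only profile set for cheap Monte-Carlo work.
pelvis_only_profiles <- function(noise = 1) {
  list(pelvis = location_profile("pelvis", gain = 1,
                                 artifact_noise_sd = noise))
}

# Fully deterministic config: no noise anywhere, fixed durations.
noiseless_config <- function(..., profiles = NULL) {
  if (is.null(profiles))
    profiles <- list(pelvis = location_profile("pelvis", 1, 0),
                     thigh_L = location_profile("thigh_L", 0.7, 0),
                     hand_R = location_profile("hand_R", 0.4, 0))
  simulation_config(noise_sd = 0, pressure_noise_sd = 0, duration_sd_s = 0,
                    adaptation_slope_s_per_trial = 0,
                    peak_fraction_sd_left_turns = 0,
                    peak_fraction_sd_right_turns = 0,
                    location_profiles = profiles, ...)
}
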