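# Generative specification of a synthetic deployment. The defaults emulate the
# study conditions: a 28-day, two-group adolescent cohort (17 intervention +
# 19 control), anchor-place weekday routines (home / school / evening
# tutoring), ~90% adherence, weak signed couplings between a latent daily
# distress state and the behavioural streams, and group-by-wave shifts on the
# questionnaire scores.

#' Build a simulation configuration
#'
#' @param n_intervention,n_control group sizes (defaults 17 and 19).
#' @param n_days deployment length in days (default 28).
#' @param seed root integer seed; all randomness flows from it through
#'   per-participant substreams.
#' @param start_date `Date` of day 0; the default is a Monday so that
#'   `day_index %% 7 < 5` are school days.
#' @param anchor_places data frame `lat`, `lon`, `label` of the daily-routine
#'   anchors; must contain labels `home`, `school` and `tutoring`.
#' @param coupling named list `construct -> named numeric vector
#'   feature -> coefficient`: signed coefficients (per SD of latent distress)
#'   linking the latent state to behavioural drivers. Supported feature names:
#'   `sleep_daytime_min`, `sleep_nighttime_min`, `sleep_total_min`,
#'   `usage_nighttime_min`, `usage_daytime_min`, `usage_total_min`,
#'   `unlock_count`, `location_variance`, `location_entropy`,
#'   `total_distance_km`.
#' @param group_time_effects named list `instrument -> list(control =
#'   c(b, m, p), intervention = c(b, m, p))` of target score means at the
#'   baseline / mid / post waves.
#' @param adherence_p probability that a prompt is answered and that a
#'   lifestyle cell is recorded.
#' @param gps_noise_m standard deviation (metres) of the GPS jitter.
#' @param ema_noise_sd SD of the rating noise on the latent z-scale.
#' @param gps_interval_min GPS sampling period in minutes.
#' @param ar1_phi day-to-day autocorrelation of the latent distress process.
#' @param latent_group_offset named list `construct -> c(control, intervention)`
#'   mean offsets of the latent state.
#' @param mauq_item_mean target per-item mean of the usability questionnaire
#'   (post wave, intervention group only).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_intervention = 17, n_control = 19, n_days = 28,
                       seed = 1, start_date = as.Date("2024-09-02"),
                       anchor_places = default_anchor_places(),
                       coupling = default_coupling(),
                       group_time_effects = default_group_time_effects(),
                       adherence_p = 0.9, gps_noise_m = 20,
                       ema_noise_sd = 0.6, gps_interval_min = 5,
                       ar1_phi = 0.5,
                       latent_group_offset = list(depression = c(0, 0.4),
                                                  anxiety = c(0, 0),
                                                  stress = c(0, 0.4)),
                       mauq_item_mean = 6.31) {
  if (n_days < 1) dp_stop("n_days must be >= 1")
  if (n_intervention < 0 || n_control < 0 || n_intervention + n_control < 1)
    dp_stop("group sizes must be non-negative and total >= 1")
  if (adherence_p < 0 || adherence_p > 1)
    dp_stop("adherence_p must lie in [0, 1]")
  if (gps_noise_m < 0 || ema_noise_sd < 0 || gps_interval_min <= 0)
    dp_stop("noise scales must be non-negative and gps_interval_min positive")
  if (ar1_phi < 0 || ar1_phi >= 1) dp_stop("ar1_phi must lie in [0, 1)")
  if (is.null(anchor_places) || nrow(anchor_places) == 0)
    dp_stop("anchor_places must be non-empty")
  if (!all(c("home", "school", "tutoring") %in% anchor_places$label))
    dp_stop("anchor_places must include home, school and tutoring")
  validate_coords(anchor_places$lat, anchor_places$lon)
  structure(list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    n_days = as.integer(n_days), seed = as.integer(seed),
    start_date = start_date, anchor_places = anchor_places,
    coupling = coupling, group_time_effects = group_time_effects,
    adherence_p = adherence_p, gps_noise_m = gps_noise_m,
    ema_noise_sd = ema_noise_sd, gps_interval_min = gps_interval_min,
    ar1_phi = ar1_phi, latent_group_offset = latent_group_offset,
    mauq_item_mean = mauq_item_mean
  ), class = "sim_config")
}

#' Default anchor places of the daily routine
#' @return data frame `lat`, `lon`, `label` (home, school, tutoring).
#' @export
default_anchor_places <- function() {
  data.frame(lat = c(37.5500, 37.5600, 37.5450),
             lon = c(127.0000, 127.0100, 127.0060),
             label = c("home", "school", "tutoring"))
}

#' Default latent-distress couplings
#'
#' Weak signed couplings chosen so the pooled feature-EMA correlations land in
#' the weak range typical of daily digital-phenotype data (|r| around
#' 0.1-0.2): more daytime sleep and less late-night phone use with higher
#' distress, and a small positive link between anxiety and spatial spread.
#' @return named list as accepted by [sim_config()].
#' @export
default_coupling <- function() {
  list(depression = c(sleep_daytime_min = 0.15, usage_nighttime_min = -0.15),
       anxiety = c(sleep_daytime_min = 0.13, location_variance = 0.12),
       stress = c(usage_nighttime_min = -0.12, sleep_nighttime_min = -0.10))
}

#' Default group-by-wave target means for the questionnaires
#'
#' Baseline levels and trajectories emulate a cohort in which the intervention
#' group starts with higher depression and stress and improves more by the
#' post wave, while anxiety changes similarly in both groups.
#' @return named list as accepted by [sim_config()].
#' @export
default_group_time_effects <- function() {
  list(dass_depression = list(control = c(10.2, 10.0, 9.8),
                              intervention = c(18.1, 15.5, 13.5)),
       dass_anxiety = list(control = c(11.0, 10.4, 10.1),
                           intervention = c(12.0, 11.3, 10.9)),
       dass_stress = list(control = c(12.0, 11.8, 11.6),
                          intervention = c(19.8, 16.8, 14.8)),
       self_efficacy = list(control = c(70, 70.5, 71),
                            intervention = c(68, 74, 80)),
       time_management = list(control = c(90, 91, 92),
                              intervention = c(88, 97, 105)))
}

# Sum of coupling coefficients times latent values for one feature.
coupling_shift <- function(coupling, z, feature) {
  s <- 0
  for (k in names(coupling)) {
    cf <- coupling[[k]]
    if (!is.null(cf) && feature %in% names(cf)) s <- s + cf[[feature]] * z[[k]]
  }
  s
}
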