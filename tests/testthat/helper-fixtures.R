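# Shared fixture builders; everything is generated in code.

gps_points <- function(t_min, lat, lon) {
  data.frame(t_min = t_min, lat = lat, lon = lon)
}

screen_events <- function(t_min, kind) {
  data.frame(t_min = t_min, kind = kind, stringsAsFactors = FALSE)
}

# alternating unlock/lock stream from episode (start, end) pairs
events_from_episodes <- function(starts, ends) {
  screen_events(as.vector(rbind(starts, ends)),
                rep(c("unlock", "lock"), length(starts)))
}

# a small cohort configuration used across tests (GPS left at a coarse
# 15-minute sampling so location features stay cheap)
tiny_config <- function(seed = 7, n_days = 5, ...) {
  sim_config(seed = seed, n_intervention = 2, n_control = 2, n_days = n_days,
             gps_interval_min = 15, ...)
}

# flat day context: awake 07:30-23:30, weekday school + tutoring
weekday_context <- function() {
  list(wake_min = 450, bed_min = 1410, school = c(510, 930),
       tutoring = c(1140, 1260),
       sleep_windows = data.frame(start = c(0, 1410), end = c(450, 1440)))
}

expect_partition <- function(day, night, total, tol = 1e-9) {
  expect_equal(day + night, total, tolerance = tol)
  expect_gte(day, 0)
  expect_gte(night, 0)
}
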