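# Daily aggregation: one row per participant-day joining the thirteen passive
# phenotypes with the daily-mean EMA ratings.

PASSIVE_FEATURES <- c(
  "total_distance_km", "total_travel_time_min", "location_variance",
  "location_entropy", "normalized_entropy",
  "sleep_total_min", "sleep_daytime_min", "sleep_nighttime_min",
  "usage_total_min", "usage_daytime_min", "usage_nighttime_min",
  "lock_duration_min", "unlock_count")

EMA_CONSTRUCTS <- c("depression", "anxiety", "stress")

#' Aggregate a cohort into daily records
#'
#' Produces one row per participant-day with the thirteen passive phenotypes
#' (five location, three sleep, five phone) and the daily mean of the answered
#' EMA ratings per construct. Days with insufficient data for a feature family
#' carry `NA` (never imputed).
#'
#' @param cohort a `cohort_dataset` (or any list with the same stream data
#'   frames and a `config`).
#' @param features which feature families to compute; dropping `"location"`
#'   skips the place clustering (useful in large simulation studies that do
#'   not involve GPS features).
#' @return data frame: `participant_id`, `day_index`, the feature columns,
#'   `ema_depression`, `ema_anxiety`, `ema_stress`.
#' @export
extract_daily_records <- function(cohort,
                                  features = c("location", "sleep", "phone")) {
  cfg <- cohort$config
  nd <- cfg$n_days
  ids <- cohort$participants$participant_id
  cols <- c(if ("location" %in% features) PASSIVE_FEATURES[1:5],
            if ("sleep" %in% features) PASSIVE_FEATURES[6:8],
            if ("phone" %in% features) PASSIVE_FEATURES[9:13],
            paste0("ema_", EMA_CONSTRUCTS))
  mat <- matrix(NA_real_, nrow = length(ids) * nd, ncol = length(cols),
                dimnames = list(NULL, cols))
  day_key <- function(t) pmin(pmax(floor(t / MINUTES_PER_DAY), 0), nd - 1)
  for (pi in seq_along(ids)) {
    id <- ids[pi]
    off <- (pi - 1) * nd
    gps_p <- if (!is.null(cohort$gps) && "location" %in% features)
      cohort$gps[cohort$gps$participant_id == id, ] else NULL
    gps_split <- if (!is.null(gps_p))
      split(seq_len(nrow(gps_p)), factor(floor(gps_p$t_min / MINUTES_PER_DAY),
                                         levels = 0:(nd - 1)))
    scr_p <- if (!is.null(cohort$screen) && "phone" %in% features)
      cohort$screen[cohort$screen$participant_id == id, ] else NULL
    sess_p <- if (!is.null(scr_p)) build_sessions(scr_p)
    unlock_t <- if (!is.null(scr_p)) scr_p$t_min[scr_p$kind == "unlock"]
    slp_p <- if (!is.null(cohort$sleep) && "sleep" %in% features)
      merge_intervals(cohort$sleep[cohort$sleep$participant_id == id,
                                   c("start", "end")]) else NULL
    ema_p <- if (!is.null(cohort$ema))
      cohort$ema[cohort$ema$participant_id == id & cohort$ema$answered, ] else NULL
    for (d0 in 0:(nd - 1)) {
      r <- off + d0 + 1
      lo <- d0 * MINUTES_PER_DAY; hi <- lo + MINUTES_PER_DAY
      if ("location" %in% features) {
        day_pts <- if (!is.null(gps_p)) gps_p[gps_split[[d0 + 1]], ] else NULL
        seed_d <- (cfg$seed %% 100000L) * 17L + pi * 1009L + d0
        lf <- compute_location_features(day_pts, seed = seed_d)
        mat[r, PASSIVE_FEATURES[1:5]] <- as.numeric(lf[1, ])
      }
      if ("sleep" %in% features) {
        s <- pmax(slp_p$start, lo); e <- pmin(slp_p$end, hi)
        keep <- e > s
        tot <- sum(e[keep] - s[keep])
        day <- sum(daytime_minutes(s[keep], e[keep]))
        mat[r, PASSIVE_FEATURES[6:8]] <- c(tot, day, tot - day)
      }
      if ("phone" %in% features) {
        s <- pmax(sess_p$start, lo); e <- pmin(sess_p$end, hi)
        keep <- e > s
        usage <- sum(e[keep] - s[keep])
        day_use <- sum(daytime_minutes(s[keep], e[keep]))
        n_unlock <- sum(unlock_t >= lo & unlock_t < hi)
        mat[r, PASSIVE_FEATURES[9:13]] <-
          c(usage, day_use, usage - day_use, MINUTES_PER_DAY - usage, n_unlock)
      }
    }
    if (!is.null(ema_p) && nrow(ema_p)) {
      for (k in EMA_CONSTRUCTS) {
        m <- tapply(ema_p[[k]], factor(ema_p$day_index, levels = 0:(nd - 1)),
                    mean)
        mat[off + seq_len(nd), paste0("ema_", k)] <- as.numeric(m)
      }
    }
  }
  out <- data.frame(participant_id = rep(ids, each = nd),
                    day_index = rep(0:(nd - 1), length(ids)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}
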