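# Phone-log phenotypes: usage episodes are unlock->lock pairs; per day the
# pipeline reports total, daytime and nighttime usage minutes, the lock
# duration (complement to the 1440-minute day) and the unlock count.

#' Build usage episodes from an alternating unlock/lock stream
#'
#' @param events data frame with `t_min` (strictly increasing) and `kind`
#'   (`"unlock"` or `"lock"`). A stream may start with a `lock` (episode open
#'   at the observation boundary: it is opened at the first timestamp's day
#'   start) and end with an `unlock` (closed at that day's end).
#' @return data frame of disjoint episodes (`start`, `end`), time-ordered.
#' @export
build_sessions <- function(events) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(start = numeric(), end = numeric()))
  if (is.unsorted(events$t_min, strictly = TRUE))
    dp_stop("screen events must be strictly time-ordered")
  bad <- which(events$kind[-1] == events$kind[-nrow(events)])
  if (length(bad))
    dp_stop(sprintf("screen events must alternate unlock/lock; two '%s' events around t=%.1f min",
                    events$kind[bad[1] + 1], events$t_min[bad[1] + 1]))
  t <- events$t_min; kind <- events$kind
  if (kind[1] == "lock") {
    t <- c(floor(t[1] / MINUTES_PER_DAY) * MINUTES_PER_DAY, t)
    kind <- c("unlock", kind)
  }
  if (kind[length(kind)] == "unlock") {
    t <- c(t, (floor(t[length(t)] / MINUTES_PER_DAY) + 1) * MINUTES_PER_DAY)
    kind <- c(kind, "lock")
  }
  data.frame(start = t[kind == "unlock"], end = t[kind == "lock"])
}

#' Phone-usage features for one calendar day
#'
#' @param events the participant's screen-event stream (`t_min`, `kind`);
#'   episodes are built, split at midnight and clipped to the day.
#' @param day_index 0-based study day.
#' @return one-row data frame `usage_total_min`, `usage_daytime_min`,
#'   `usage_nighttime_min`, `lock_duration_min`, `unlock_count`. Usage plus
#'   lock duration is 1440 by construction; the unlock count is the number of
#'   unlock events stamped on the day.
#' @export
compute_phone_features <- function(events, day_index) {
  lo <- day_index * MINUTES_PER_DAY
  hi <- lo + MINUTES_PER_DAY
  sessions <- build_sessions(events)
  clipped <- if (nrow(sessions)) clip_intervals_to_day(sessions, day_index)
             else sessions
  usage <- if (nrow(clipped)) sum(clipped$end - clipped$start) else 0
  day_use <- if (nrow(clipped)) sum(daytime_minutes(clipped$start, clipped$end)) else 0
  unlocks <- if (is.null(events) || nrow(events) == 0) 0L else
    sum(events$kind == "unlock" & events$t_min >= lo & events$t_min < hi)
  data.frame(usage_total_min = usage,
             usage_daytime_min = day_use,
             usage_nighttime_min = usage - day_use,
             lock_duration_min = MINUTES_PER_DAY - usage,
             unlock_count = as.integer(unlocks))
}
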