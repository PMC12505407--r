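# Sleep phenotypes: total, daytime and nighttime sleep minutes per calendar
# day. Daytime is 07:00-23:00, nighttime 23:00-07:00 (half-open windows, so
# daytime + nighttime = total exactly). Sleep crossing midnight is attributed
# per date by clipping. A screen-gap heuristic can stand in for sleep records
# when only the phone log is available.

#' Split a sleep interval into daytime and nighttime minutes
#'
#' @param start,end interval bounds in study minutes (may span midnight or the
#'   07:00/23:00 boundaries).
#' @return named numeric vector `c(daytime_min, nighttime_min)`.
#' @export
segment_day_night <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) || end <= start)
    dp_stop("sleep interval must have end > start")
  if (end - start > MINUTES_PER_DAY)
    dp_stop("sleep interval longer than 24 h")
  day <- daytime_minutes(start, end)
  c(daytime_min = day, nighttime_min = (end - start) - day)
}

#' Sleep features for one calendar day
#'
#' Intervals are clipped to the day, merged (overlaps collapse), then split at
#' the 07:00/23:00 boundaries and summed.
#'
#' @param intervals data frame with `start`, `end` in study minutes.
#' @param day_index 0-based study day.
#' @return one-row data frame `sleep_total_min`, `sleep_daytime_min`,
#'   `sleep_nighttime_min`.
#' @export
compute_sleep_features <- function(intervals, day_index) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(data.frame(sleep_total_min = 0, sleep_daytime_min = 0,
                      sleep_nighttime_min = 0))
  if (any(intervals$end <= intervals$start))
    dp_stop("sleep intervals must have end > start")
  clipped <- clip_intervals_to_day(intervals, day_index)
  if (nrow(clipped) == 0)
    return(data.frame(sleep_total_min = 0, sleep_daytime_min = 0,
                      sleep_nighttime_min = 0))
  merged <- merge_intervals(clipped)
  day <- sum(daytime_minutes(merged$start, merged$end))
  tot <- sum(merged$end - merged$start)
  data.frame(sleep_total_min = tot, sleep_daytime_min = day,
             sleep_nighttime_min = tot - day)
}

#' Infer sleep intervals from screen lock/unlock gaps
#'
#' Screen-off gaps of at least `min_gap_min` minutes are sleep candidates. For
#' each nightly rest window (21:00 to 11:00 the next day) the candidate with
#' the largest overlap is taken as that night's sleep, clipped to the window
#' --- the longest-gap-per-night convention of phone-log sleep estimation,
#' which keeps long daytime non-use stretches (e.g. school hours without the
#' phone) from masquerading as sleep. Gaps lying entirely inside 12:00-18:00
#' additionally become naps.
#'
#' @param events data frame with `t_min` and `kind` (`"unlock"`/`"lock"`),
#'   strictly time-ordered and alternating.
#' @param min_gap_min minimum screen-off gap considered sleep.
#' @return data frame of inferred intervals (`start`, `end`).
#' @export
infer_sleep_from_screen <- function(events, min_gap_min = 60) {
  none <- data.frame(start = numeric(), end = numeric())
  sessions <- build_sessions(events)
  if (nrow(sessions) < 2) return(none)
  gs <- sessions$end[-nrow(sessions)]
  ge <- sessions$start[-1]
  keep <- (ge - gs) >= min_gap_min
  gs <- gs[keep]; ge <- ge[keep]
  if (!length(gs)) return(none)
  res <- list()
  # nightly rest windows spanning the observed range
  d_lo <- floor(min(gs) / MINUTES_PER_DAY) - 1
  d_hi <- floor(max(ge) / MINUTES_PER_DAY)
  for (d in d_lo:d_hi) {
    w <- d * MINUTES_PER_DAY + c(21 * 60, 35 * 60)
    ov <- interval_overlap(gs, ge, w[1], w[2])
    if (!any(ov >= min_gap_min)) next
    i <- which.max(ov)
    res[[length(res) + 1]] <- c(max(gs[i], w[1]), min(ge[i], w[2]))
  }
  # daytime naps: gaps entirely inside 12:00-18:00
  day0 <- floor(gs / MINUTES_PER_DAY) * MINUTES_PER_DAY
  nap <- (gs - day0) >= 12 * 60 & (ge - day0) <= 18 * 60
  for (i in which(nap)) res[[length(res) + 1]] <- c(gs[i], ge[i])
  if (!length(res)) return(none)
  m <- unique(do.call(rbind, res))
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}
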