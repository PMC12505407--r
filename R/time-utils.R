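# Internal clock: all event times are numeric minutes since study day 0, 00:00
# local time. Day d is the half-open interval [d*1440, (d+1)*1440). Daytime is
# 07:00-23:00 local, nighttime the complementary 23:00-07:00 window.

MINUTES_PER_DAY <- 1440
DAY_START_MIN <- 7 * 60    # 07:00
DAY_END_MIN <- 23 * 60     # 23:00

#' Convert study minutes to ISO-8601 timestamps
#'
#' @param t_min numeric minutes since day 0, 00:00.
#' @param start_date `Date` of study day 0.
#' @return character vector of ISO-8601 timestamps (second resolution).
#' @keywords internal
minutes_to_iso <- function(t_min, start_date) {
  origin <- as.POSIXct(paste0(format(start_date), " 00:00:00"), tz = "UTC")
  format(origin + round(t_min * 60), "%Y-%m-%dT%H:%M:%S")
}

#' Convert ISO-8601 timestamps to study minutes
#' @keywords internal
iso_to_minutes <- function(ts, start_date) {
  origin <- as.POSIXct(paste0(format(start_date), " 00:00:00"), tz = "UTC")
  t <- as.POSIXct(ts, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  as.numeric(difftime(t, origin, units = "mins"))
}

#' Overlap length of two half-open intervals, in the interval units
#' @keywords internal
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Minutes of an absolute-time interval falling in daytime (07:00-23:00)
#'
#' Works across day boundaries via the closed-form cumulative daytime
#' function f(t) = 960 * floor(t/1440) + clamp(t mod 1440 - 420, 0, 960):
#' the daytime content of [s, e) is f(e) - f(s). Fully vectorised.
#' @keywords internal
daytime_minutes <- function(start_min, end_min) {
  stopifnot(length(start_min) == length(end_min))
  f <- function(t) {
    (DAY_END_MIN - DAY_START_MIN) * (t %/% MINUTES_PER_DAY) +
      pmin(pmax(t %% MINUTES_PER_DAY - DAY_START_MIN, 0),
           DAY_END_MIN - DAY_START_MIN)
  }
  out <- f(end_min) - f(start_min)
  out[!is.finite(out) | end_min <= start_min] <- 0
  out
}

#' Clip intervals to one study day
#'
#' @param intervals data frame with numeric `start`, `end` (study minutes).
#' @param day_index integer study day (0-based).
#' @return the clipped intervals (rows with zero overlap dropped).
#' @keywords internal
clip_intervals_to_day <- function(intervals, day_index) {
  lo <- day_index * MINUTES_PER_DAY
  hi <- lo + MINUTES_PER_DAY
  s <- pmax(intervals$start, lo)
  e <- pmin(intervals$end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# vector versions: intervals as parallel start/end vectors, no data frames
merge_iv <- function(s, e) {
  if (!length(s)) return(list(s = s, e = e))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[i]; me <- e[i]
    }
  }
  list(s = c(outs, ms), e = c(oute, me))
}

subtract_iv <- function(ws, we, xs, xe) {
  ps <- ws; pe <- we
  if (length(xs)) {
    ex <- merge_iv(xs, xe)
    for (j in seq_along(ex$s)) {
      ns <- numeric(0); ne <- numeric(0)
      for (i in seq_along(ps)) {
        if (ex$e[j] <= ps[i] || ex$s[j] >= pe[i]) {
          ns <- c(ns, ps[i]); ne <- c(ne, pe[i])
        } else {
          if (ex$s[j] > ps[i]) { ns <- c(ns, ps[i]); ne <- c(ne, ex$s[j]) }
          if (ex$e[j] < pe[i]) { ns <- c(ns, ex$e[j]); ne <- c(ne, pe[i]) }
        }
      }
      ps <- ns; pe <- ne
      if (!length(ps)) break
    }
  }
  keep <- pe > ps
  list(s = ps[keep], e = pe[keep])
}

#' Merge overlapping or touching intervals
#' @keywords internal
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("start", "end")])
  m <- merge_iv(intervals$start, intervals$end)
  data.frame(start = m$s, end = m$e)
}

#' Subtract a set of exclusion intervals from a window
#'
#' @param window numeric length-2 `c(start, end)`.
#' @param exclusions data frame with `start`, `end`.
#' @return data frame of the remaining sub-intervals (possibly 0 rows).
#' @keywords internal
subtract_intervals <- function(window, exclusions) {
  m <- subtract_iv(window[1], window[2], exclusions$start, exclusions$end)
  data.frame(start = m$s, end = m$e)
}

# Validation helper: config/validation failures carry a dedicated class so the
# command-line wrapper can map them to exit code 2.
dp_stop <- function(msg, class = "digiphen_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
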