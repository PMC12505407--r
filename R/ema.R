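# EMA engine: eight daily prompt contexts (waking, before school, lunchtime,
# after school, before/after private tutoring, before bedtime, and a
# conditional post-midnight-usage trigger). Prompts are drawn uniformly inside
# each slot's eligible window, never during school, tutoring or sleep.

#' The eight EMA prompt slots
#' @return character vector of the slot names, in canonical order.
#' @export
prompt_slots <- function() {
  c("waking", "before_school", "lunchtime", "after_school",
    "before_tutoring", "after_tutoring", "before_bedtime",
    "post_midnight_usage")
}

#' Schedule one day's EMA prompts
#'
#' Slot windows (minutes of day, defaults): waking = sleep end to +30;
#' before_school = waking end to school start; lunchtime = 12:00-13:00;
#' after_school = school end +60; before_tutoring = tutoring start -60;
#' after_tutoring = tutoring end +60; before_bedtime = bedtime -60. The
#' post-midnight slot fires at the moment cumulative screen usage since 00:00
#' first exceeds 30 minutes. School, tutoring and sleep windows are excluded
#' from every unconditional slot; slots whose eligible window is empty (or
#' whose anchor, e.g. school, is absent that day) are not sent.
#'
#' @param day_context list with elements `wake_min`, `bed_min` (minutes of
#'   day), optional `school` and `tutoring` (length-2 windows, minutes of
#'   day), and optional `sleep_windows` (data frame `start`, `end`, minutes of
#'   day) covering in-day sleep.
#' @param screen_sessions optional data frame (`start`, `end`, minutes of day)
#'   of the usage episodes that count toward the post-midnight trigger
#'   (callers normally pass the episodes between 00:00 and waking).
#' @param seed integer seed for the uniform draws.
#' @param postmidnight_trigger_min usage threshold for the conditional slot.
#' @return data frame `slot`, `sent_min` (minutes of day), at most one row per
#'   slot.
#' @export
schedule_prompts <- function(day_context, screen_sessions = NULL, seed = 1,
                             postmidnight_trigger_min = 30) {
  wake <- day_context$wake_min
  bed <- day_context$bed_min
  school <- day_context$school
  tutoring <- day_context$tutoring
  ex_s <- numeric(0); ex_e <- numeric(0)
  for (w in list(school, tutoring)) {
    if (!is.null(w)) { ex_s <- c(ex_s, w[1]); ex_e <- c(ex_e, w[2]) }
  }
  if (!is.null(day_context$sleep_windows) && nrow(day_context$sleep_windows)) {
    ex_s <- c(ex_s, day_context$sleep_windows$start)
    ex_e <- c(ex_e, day_context$sleep_windows$end)
  }

  windows <- list(
    waking = c(wake, wake + 30),
    before_school = if (!is.null(school)) c(wake + 30, school[1]),
    lunchtime = c(12 * 60, 13 * 60),
    after_school = if (!is.null(school)) c(school[2], school[2] + 60),
    before_tutoring = if (!is.null(tutoring)) c(tutoring[1] - 60, tutoring[1]),
    after_tutoring = if (!is.null(tutoring)) c(tutoring[2], tutoring[2] + 60),
    before_bedtime = c(max(wake, bed - 60), bed)
  )

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  slots <- character(0); times <- numeric(0)
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (is.null(w) || w[2] <= w[1]) next
    free <- subtract_iv(w[1], w[2], ex_s, ex_e)
    if (!length(free$s)) next
    len <- free$e - free$s
    pick <- if (length(len) == 1) 1L else sample.int(length(len), 1, prob = len)
    slots <- c(slots, nm)
    times <- c(times, stats::runif(1, free$s[pick], free$e[pick]))
  }
  # post-midnight trigger: cumulative usage in [00:00, t) exceeding threshold
  if (!is.null(screen_sessions) && nrow(screen_sessions)) {
    s <- screen_sessions[order(screen_sessions$start), , drop = FALSE]
    cum <- 0
    for (i in seq_len(nrow(s))) {
      dur <- s$end[i] - s$start[i]
      if (cum + dur > postmidnight_trigger_min) {
        slots <- c(slots, "post_midnight_usage")
        times <- c(times, s$start[i] + (postmidnight_trigger_min - cum))
        break
      }
      cum <- cum + dur
    }
  }
  out <- data.frame(slot = slots, sent_min = times)
  out[order(out$sent_min), , drop = FALSE]
}

#' Adherence to EMA prompts and lifestyle records
#'
#' Mood adherence is answered prompts / sent prompts x 100, lifestyle
#' adherence the per-day share of recorded cells out of 48, averaged across
#' days --- both per participant and as cohort means.
#'
#' @param prompts data frame with `participant_id`, `prompt_id`.
#' @param responses data frame with `participant_id`, `prompt_id` (answered
#'   prompts only). Every response must reference an existing prompt.
#' @param lifestyle data frame with `participant_id`, `day_index`, `recorded`
#'   (logical or 0/1), one row per cell; 48 cells per participant-day.
#' @return list with `per_participant` (data frame `participant_id`,
#'   `mood_adherence_pct`, `lifestyle_adherence_pct`) and cohort means
#'   `mood_mean_pct`, `lifestyle_mean_pct`.
#' @export
compute_adherence <- function(prompts, responses, lifestyle) {
  if (nrow(responses) && !all(responses$prompt_id %in% prompts$prompt_id))
    dp_stop("response references a prompt that was never sent",
            class = "digiphen_integrity_error")
  ids <- sort(unique(c(prompts$participant_id, lifestyle$participant_id)))
  mood <- vapply(ids, function(id) {
    sent <- sum(prompts$participant_id == id)
    if (sent == 0) return(NA_real_)
    100 * sum(responses$participant_id == id) / sent
  }, numeric(1))
  life <- vapply(ids, function(id) {
    rows <- lifestyle[lifestyle$participant_id == id, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    per_day <- tapply(as.numeric(rows$recorded), rows$day_index,
                      function(v) 100 * sum(v) / 48)
    mean(per_day)
  }, numeric(1))
  per <- data.frame(participant_id = ids, mood_adherence_pct = mood,
                    lifestyle_adherence_pct = life)
  list(per_participant = per,
       mood_mean_pct = mean(mood, na.rm = TRUE),
       lifestyle_mean_pct = mean(life, na.rm = TRUE))
}
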