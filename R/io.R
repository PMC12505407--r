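# Delimited-text interchange: one CSV per stream (RFC-4180 via the standard
# readers/writers, ISO-8601 timestamps) plus a JSON sidecar holding the full
# generative configuration and ground-truth couplings.

#' Write a cohort dataset to a directory of CSV files
#'
#' Files: `participants.csv`, `gps.csv` (participant_id, timestamp, lat, lon),
#' `screen_events.csv` (participant_id, timestamp, kind), `sleep.csv`
#' (participant_id, start, end), `ema.csv` (participant_id, prompt_id, slot,
#' sent_at, answered_at nullable, depression, anxiety, stress, adjectives),
#' `lifestyle.csv` (participant_id, day_index, cell, recorded, label),
#' `questionnaires.csv` (participant_id, wave, instrument, item, response) and
#' `ground_truth.json` (the full [sim_config()] including couplings).
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sd0 <- cohort$config$start_date
  w <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                           row.names = FALSE)
  w(cohort$participants, "participants.csv")
  if (!is.null(cohort$gps))
    w(data.frame(participant_id = cohort$gps$participant_id,
                 timestamp = minutes_to_iso(cohort$gps$t_min, sd0),
                 lat = cohort$gps$lat, lon = cohort$gps$lon), "gps.csv")
  if (!is.null(cohort$screen))
    w(data.frame(participant_id = cohort$screen$participant_id,
                 timestamp = minutes_to_iso(cohort$screen$t_min, sd0),
                 kind = cohort$screen$kind), "screen_events.csv")
  if (!is.null(cohort$sleep))
    w(data.frame(participant_id = cohort$sleep$participant_id,
                 start = minutes_to_iso(cohort$sleep$start, sd0),
                 end = minutes_to_iso(cohort$sleep$end, sd0)), "sleep.csv")
  if (!is.null(cohort$ema))
    w(data.frame(participant_id = cohort$ema$participant_id,
                 prompt_id = cohort$ema$prompt_id, slot = cohort$ema$slot,
                 sent_at = minutes_to_iso(cohort$ema$sent_min, sd0),
                 answered_at = ifelse(cohort$ema$answered,
                                      minutes_to_iso(cohort$ema$sent_min + 1, sd0),
                                      ""),
                 depression = cohort$ema$depression,
                 anxiety = cohort$ema$anxiety, stress = cohort$ema$stress,
                 adjectives = cohort$ema$adjectives), "ema.csv")
  if (!is.null(cohort$lifestyle)) w(cohort$lifestyle, "lifestyle.csv")
  if (!is.null(cohort$questionnaires)) w(cohort$questionnaires,
                                         "questionnaires.csv")
  cfg <- cohort$config
  cfg$start_date <- format(cfg$start_date)
  cfg$anchor_places <- as.list(cfg$anchor_places)
  # named numeric vectors would serialise as bare arrays; keep the names
  cfg$coupling <- lapply(cfg$coupling, as.list)
  jsonlite::write_json(unclass(cfg), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort dataset from a directory of CSV files
#'
#' Inverse of [write_cohort()]; the `ground_truth.json` sidecar restores the
#' configuration (timestamps are mapped back to study minutes through its
#' `start_date`).
#'
#' @param dir directory written by [write_cohort()] (or CSVs with the same
#'   schemas).
#' @return a `cohort_dataset` (without the latent ground-truth states, which
#'   are never serialised).
#' @export
read_cohort <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.json")
  if (!file.exists(gt_path)) dp_stop(sprintf("missing %s", gt_path))
  raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  cfg <- sim_config(
    n_intervention = raw$n_intervention, n_control = raw$n_control,
    n_days = raw$n_days, seed = raw$seed,
    start_date = as.Date(raw$start_date),
    anchor_places = as.data.frame(raw$anchor_places),
    coupling = lapply(raw$coupling, unlist),
    group_time_effects = raw$group_time_effects,
    adherence_p = raw$adherence_p, gps_noise_m = raw$gps_noise_m,
    ema_noise_sd = raw$ema_noise_sd, gps_interval_min = raw$gps_interval_min,
    ar1_phi = raw$ar1_phi,
    latent_group_offset = raw$latent_group_offset,
    mauq_item_mean = raw$mauq_item_mean)
  sd0 <- cfg$start_date
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  gps <- rd("gps.csv")
  if (!is.null(gps))
    gps <- data.frame(participant_id = gps$participant_id,
                      t_min = iso_to_minutes(gps$timestamp, sd0),
                      lat = gps$lat, lon = gps$lon)
  scr <- rd("screen_events.csv")
  if (!is.null(scr))
    scr <- data.frame(participant_id = scr$participant_id,
                      t_min = iso_to_minutes(scr$timestamp, sd0),
                      kind = scr$kind)
  slp <- rd("sleep.csv")
  if (!is.null(slp))
    slp <- data.frame(participant_id = slp$participant_id,
                      start = iso_to_minutes(slp$start, sd0),
                      end = iso_to_minutes(slp$end, sd0))
  ema <- rd("ema.csv")
  if (!is.null(ema)) {
    sent_min <- iso_to_minutes(ema$sent_at, sd0)
    ema <- data.frame(participant_id = ema$participant_id,
                      prompt_id = ema$prompt_id,
                      day_index = floor(sent_min / MINUTES_PER_DAY),
                      slot = ema$slot, sent_min = sent_min,
                      answered = !is.na(ema$answered_at) & ema$answered_at != "",
                      depression = ema$depression, anxiety = ema$anxiety,
                      stress = ema$stress,
                      adjectives = ifelse(is.na(ema$adjectives), "",
                                          ema$adjectives))
  }
  structure(list(participants = rd("participants.csv"), gps = gps,
                 screen = scr, sleep = slp, lifestyle = rd("lifestyle.csv"),
                 ema = ema, questionnaires = rd("questionnaires.csv"),
                 latent = NULL, config = cfg),
            class = "cohort_dataset")
}
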