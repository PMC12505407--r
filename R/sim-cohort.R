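# Synthetic deployment generator. Each participant-day has a latent distress
# state (AR(1) per construct); behavioural drivers --- night sleep duration,
# nap propensity, late-night phone use, daytime session rate/length, evening
# outing propensity --- shift linearly with the configured couplings, so the
# ground truth behind every downstream correlation is known. All randomness
# flows from the root seed through four per-participant substreams (behaviour,
# GPS jitter, EMA, questionnaires), which keeps shared streams byte-identical
# when only a subset of streams is materialised.

EMA_CUTPOINTS <- c(-1.5, -0.5, 0.5, 1.5)

ADJECTIVE_VOCAB <- list(
  low = c("calm", "happy", "relaxed", "content"),
  mid = c("okay", "tired", "bored"),
  high = c("down", "anxious", "stressed", "overwhelmed")
)

latent_to_rating <- function(z) {
  as.integer(findInterval(z, EMA_CUTPOINTS) + 1L)
}

#' Generate ordinal EMA responses from a latent daily state
#'
#' Each prompt is answered with probability `adherence_p`; answered prompts
#' carry 1-5 ratings obtained by adding Gaussian noise to the latent value and
#' discretising at fixed cut-points (-1.5, -0.5, 0.5, 1.5), plus one or two
#' mood adjectives keyed to the depression rating.
#'
#' @param latent named list/vector with `depression`, `anxiety`, `stress`
#'   (latent z-scale).
#' @param prompts data frame with a `prompt_id` column (one participant-day's
#'   prompts).
#' @param adherence_p response probability in `[0, 1]`.
#' @param noise_sd SD of the rating noise (>= 0).
#' @param seed integer seed.
#' @return data frame of answered prompts: `prompt_id`, `depression`,
#'   `anxiety`, `stress`, `adjectives` (semicolon-joined).
#' @export
generate_ema_responses <- function(latent, prompts, adherence_p, noise_sd,
                                   seed = 1) {
  if (noise_sd < 0) dp_stop("noise_sd must be >= 0")
  if (adherence_p < 0 || adherence_p > 1) dp_stop("adherence_p must lie in [0, 1]")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- nrow(prompts)
  if (n == 0) return(empty_response_df())
  answered <- stats::runif(n) < adherence_p
  if (!any(answered)) return(empty_response_df())
  idx <- which(answered)
  dep <- latent_to_rating(latent[["depression"]] + stats::rnorm(length(idx), 0, noise_sd))
  anx <- latent_to_rating(latent[["anxiety"]] + stats::rnorm(length(idx), 0, noise_sd))
  str <- latent_to_rating(latent[["stress"]] + stats::rnorm(length(idx), 0, noise_sd))
  adj <- vapply(dep, function(r) {
    pool <- if (r <= 2) ADJECTIVE_VOCAB$low else if (r == 3) ADJECTIVE_VOCAB$mid
            else ADJECTIVE_VOCAB$high
    paste(sample(pool, sample(1:2, 1)), collapse = ";")
  }, character(1))
  data.frame(prompt_id = prompts$prompt_id[idx], depression = dep,
             anxiety = anx, stress = str, adjectives = adj,
             stringsAsFactors = FALSE)
}

empty_response_df <- function() {
  data.frame(prompt_id = character(), depression = integer(),
             anxiety = integer(), stress = integer(), adjectives = character(),
             stringsAsFactors = FALSE)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# ---------------------------------------------------------------------------

#' Generate a full synthetic cohort
#'
#' @param config a [sim_config()].
#' @param streams which raw streams to materialise; dropping `"gps"` skips the
#'   (relatively expensive) GPS trace without changing any other stream.
#' @return object of class `cohort_dataset`: a list of data frames
#'   (`participants`, `gps`, `screen`, `sleep`, `lifestyle`, `ema`,
#'   `questionnaires`, `latent`) plus the `config`.
#' @export
generate_cohort <- function(config,
                            streams = c("gps", "screen", "sleep",
                                        "lifestyle", "ema", "questionnaires")) {
  if (!inherits(config, "sim_config")) dp_stop("config must be a sim_config")
  n_total <- config$n_control + config$n_intervention
  ids <- sprintf("P%02d", seq_len(n_total))
  groups <- c(rep("control", config$n_control),
              rep("intervention", config$n_intervention))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  pseeds <- sample.int(.Machine$integer.max - 1, n_total)
  parts <- lapply(seq_len(n_total), function(i) {
    generate_participant(config, ids[i], groups[i], pseeds[i], streams)
  })
  bind <- function(field) do.call(rbind, lapply(parts, `[[`, field))
  structure(list(
    participants = data.frame(participant_id = ids, group = groups,
                              stringsAsFactors = FALSE),
    gps = bind("gps"), screen = bind("screen"), sleep = bind("sleep"),
    lifestyle = bind("lifestyle"), ema = bind("ema"),
    questionnaires = bind("questionnaires"), latent = bind("latent"),
    config = config
  ), class = "cohort_dataset")
}

generate_participant <- function(config, id, group, pseed, streams) {
  set.seed(pseed)
  phase_seeds <- sample.int(.Machine$integer.max - 1, 4)
  nd <- config$n_days
  anchors <- config$anchor_places
  home <- anchors[anchors$label == "home", ]
  school_pl <- anchors[anchors$label == "school", ]
  tut_pl <- anchors[anchors$label == "tutoring", ]
  gi <- if (group == "intervention") 2 else 1

  ## --- behaviour phase -----------------------------------------------------
  set.seed(phase_seeds[1])
  # latent distress: participant intercept + stationary AR(1), marginal SD ~ 1
  z <- sapply(c("depression", "anxiety", "stress"), function(k) {
    off <- config$latent_group_offset[[k]][gi]
    u <- stats::rnorm(1, 0, 0.3)
    e <- numeric(nd)
    e[1] <- stats::rnorm(1)
    phi <- config$ar1_phi
    if (nd > 1) for (d in 2:nd)
      e[d] <- phi * e[d - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
    off + u + e
  })
  z <- matrix(z, nrow = nd,
              dimnames = list(NULL, c("depression", "anxiety", "stress")))
  zrow <- function(d) as.list(z[clamp(d, 1, nd), ])

  shift <- function(d, ...) {
    feats <- c(...)
    sum(vapply(feats, function(f) coupling_shift(config$coupling, zrow(d), f),
               numeric(1)))
  }

  # nights -1 .. nd-1 (night n runs from evening of day n into day n+1)
  nights <- lapply(seq(-1, nd - 1), function(n) {
    dnx <- n + 2  # 1-based day index of the morning after
    pm_shift <- shift(dnx, "usage_nighttime_min", "usage_total_min")
    u_pm <- max(0, stats::rnorm(1, 20 + 20 * pm_shift, 12))
    if (u_pm < 1) u_pm <- 0
    bed_planned <- (n + 1) * MINUTES_PER_DAY - 30 + stats::rnorm(1, 0, 10)
    scroll_start <- bed_planned - (10 + stats::rexp(1, 1 / 10))
    scroll_end <- bed_planned + u_pm
    onset <- scroll_end + 5
    dur <- 480 + 40 * shift(dnx, "sleep_nighttime_min", "sleep_total_min") +
      stats::rnorm(1, 0, 30)
    dur <- clamp(dur, 360, 620)
    wake <- onset + dur
    school_day <- ((n + 1) %% 7) < 5 && (n + 1) < nd
    if (school_day) wake <- min(wake, (n + 1) * MINUTES_PER_DAY + 500)
    check_start <- wake + 3
    check_end <- check_start + 5 + stats::rexp(1, 1 / 3)
    list(scroll = c(scroll_start, scroll_end), onset = onset, wake = wake,
         check = c(check_start, check_end), u_pm = u_pm)
  })
  night_of <- function(d) nights[[d + 2]]  # night starting evening of day d

  sleep_df <- do.call(rbind, lapply(nights, function(nn)
    data.frame(start = nn$onset, end = nn$wake)))

  # per-day schedules, naps, daytime phone sessions, lifestyle grid
  day_info <- vector("list", nd)
  sessions <- list()
  for (nn in nights) sessions[[length(sessions) + 1]] <- c(nn$scroll, 0)
  for (nn in nights) sessions[[length(sessions) + 1]] <- c(nn$check, 0)
  naps <- list()
  for (d0 in 0:(nd - 1)) {
    d1 <- d0 + 1
    base <- d0 * MINUTES_PER_DAY
    weekday <- (d0 %% 7) < 5
    wake <- night_of(d0 - 1)$wake
    bed <- night_of(d0)$onset
    loc_shift <- shift(d1, "location_variance", "location_entropy",
                       "total_distance_km")
    school <- if (weekday) base + c(510, 930) else NULL
    tutoring <- if (weekday &&
                    stats::runif(1) < stats::plogis(stats::qlogis(0.8) + 1.5 * loc_shift))
      base + c(1140, 1260) else NULL
    outing <- if (!weekday &&
                  stats::runif(1) < stats::plogis(stats::qlogis(0.6) + 1.5 * loc_shift))
      base + c(840, 960) else NULL
    nap <- NULL
    if (is.null(outing) &&
        stats::runif(1) < stats::plogis(stats::qlogis(0.3) +
                                        1.5 * shift(d1, "sleep_daytime_min"))) {
      nap_start <- base + stats::runif(1, if (weekday) 960 else 810,
                                       if (weekday) 1020 else 870)
      nap <- c(nap_start, nap_start + clamp(45 + stats::rnorm(1, 0, 10), 20, 90))
      naps[[length(naps) + 1]] <- nap
    }
    # daytime phone sessions in free awake windows
    ex_s <- numeric(0); ex_e <- numeric(0)
    for (w in list(school, tutoring, outing, nap))
      if (!is.null(w)) { ex_s <- c(ex_s, w[1]); ex_e <- c(ex_e, w[2]) }
    fv <- subtract_iv(wake + 15, min(bed - 25, base + 1415), ex_s, ex_e)
    free <- data.frame(start = fv$s, end = fv$e)
    if (nrow(free)) {
      cmult <- exp(0.3 * shift(d1, "unlock_count") +
                   0.15 * shift(d1, "usage_total_min"))
      dmult <- exp(0.2 * shift(d1, "usage_daytime_min") +
                   0.15 * shift(d1, "usage_total_min"))
      n_s <- stats::rpois(1, 22 * cmult)
      if (n_s > 0) {
        len <- free$end - free$start
        piece <- sample.int(nrow(free), n_s, replace = TRUE, prob = len)
        starts <- stats::runif(n_s, free$start[piece], free$end[piece])
        durs <- clamp(stats::rexp(n_s, 1 / 7) * dmult, 0.5, 45)
        ends <- pmin(starts + durs, free$end[piece])
        o <- order(starts)
        last_end <- -Inf
        for (i in o) {
          if (starts[i] > last_end + 1 && ends[i] > starts[i]) {
            sessions[[length(sessions) + 1]] <- c(starts[i], ends[i], 0)
            last_end <- ends[i]
          }
        }
      }
    }
    day_info[[d0 + 1]] <- list(school = school, tutoring = tutoring,
                               outing = outing, nap = nap, wake = wake,
                               bed = bed)
  }

  # consolidate sessions into a strictly alternating event stream
  sm <- do.call(rbind, sessions)
  # clip sessions to the observation window [0, end-of-last-morning]
  obs_end <- nd * MINUTES_PER_DAY + 720
  sm[, 1] <- pmax(sm[, 1], 0)
  sm[, 2] <- pmin(sm[, 2], obs_end)
  sm <- sm[sm[, 2] > sm[, 1], , drop = FALSE]
  sm <- sm[order(sm[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(sm))
  last_end <- -Inf
  for (i in seq_len(nrow(sm))) {
    if (sm[i, 1] <= last_end + 0.5) keep[i] <- FALSE else last_end <- sm[i, 2]
  }
  sm <- sm[keep, , drop = FALSE]
  screen_df <- data.frame(
    t_min = as.vector(t(sm[, 1:2])),
    kind = rep(c("unlock", "lock"), nrow(sm)),
    stringsAsFactors = FALSE)

  # naps are sleep records too
  nap_df <- if (length(naps)) {
    m <- do.call(rbind, naps); data.frame(start = m[, 1], end = m[, 2])
  } else data.frame(start = numeric(), end = numeric())
  sleep_df <- rbind(sleep_df, nap_df)
  all_sleep <- sleep_df
  set.seed(phase_seeds[1] %% 1000000 + 17)  # lifestyle recording substream
  mids <- rep(0:(nd - 1), each = 48) * MINUTES_PER_DAY +
    rep(seq(15, by = 30, length.out = 48), nd)
  lab <- rep("leisure", length(mids))
  for (d0 in 0:(nd - 1)) {
    di <- day_info[[d0 + 1]]
    for (w in list(di$school, di$tutoring))
      if (!is.null(w)) lab[mids >= w[1] & mids < w[2]] <- "study"
  }
  for (i in seq_len(nrow(all_sleep)))
    lab[mids >= all_sleep$start[i] & mids < all_sleep$end[i]] <- "sleep"
  lifestyle <- data.frame(day_index = rep(0:(nd - 1), each = 48),
                          cell = rep(0:47, nd),
                          recorded = stats::runif(length(mids)) < config$adherence_p,
                          label = lab, stringsAsFactors = FALSE)

  ## --- GPS phase -----------------------------------------------------------
  gps_df <- NULL
  if ("gps" %in% streams) {
    set.seed(phase_seeds[2])
    m_per_deg <- 2 * pi * EARTH_RADIUS_KM * 1000 / 360
    coslat <- cos(home$lat * pi / 180)
    pts <- vector("list", nd)
    for (d0 in 0:(nd - 1)) {
      base <- d0 * MINUTES_PER_DAY
      di <- day_info[[d0 + 1]]
      t_day <- base + seq(0, MINUTES_PER_DAY - 1, by = config$gps_interval_min)
      lat <- rep(home$lat, length(t_day))
      lon <- rep(home$lon, length(t_day))
      place <- function(win, pl, transit_min = 15) {
        if (is.null(win)) return()
        at <- t_day >= win[1] & t_day < win[2]
        lat[at] <<- pl$lat; lon[at] <<- pl$lon
        # linear transit legs before and after the visit
        f_in <- (t_day - (win[1] - transit_min)) / transit_min
        leg <- f_in > 0 & f_in < 1
        lat[leg] <<- home$lat + f_in[leg] * (pl$lat - home$lat)
        lon[leg] <<- home$lon + f_in[leg] * (pl$lon - home$lon)
        f_out <- (t_day - win[2]) / transit_min
        leg <- f_out > 0 & f_out < 1
        lat[leg] <<- pl$lat + f_out[leg] * (home$lat - pl$lat)
        lon[leg] <<- pl$lon + f_out[leg] * (home$lon - pl$lon)
      }
      place(di$school, school_pl)
      place(di$tutoring, tut_pl)
      place(di$outing, tut_pl)
      lat <- lat + stats::rnorm(length(t_day), 0, config$gps_noise_m) / m_per_deg
      lon <- lon + stats::rnorm(length(t_day), 0, config$gps_noise_m) /
        (m_per_deg * coslat)
      pts[[d0 + 1]] <- cbind(t_day, lat, lon)
    }
    pm <- do.call(rbind, pts)
    gps_df <- data.frame(t_min = pm[, 1], lat = pm[, 2], lon = pm[, 3])
  }

  ## --- EMA phase -----------------------------------------------------------
  set.seed(phase_seeds[3])
  sess_all <- build_sessions(screen_df)
  acc <- list(prompt_id = character(0), day_index = integer(0),
              slot = character(0), sent_min = numeric(0),
              answered = logical(0), depression = integer(0),
              anxiety = integer(0), stress = integer(0),
              adjectives = character(0))
  for (d0 in 0:(nd - 1)) {
    base <- d0 * MINUTES_PER_DAY
    di <- day_info[[d0 + 1]]
    ss <- pmax(sleep_df$start, base) - base
    se <- pmin(sleep_df$end, base + MINUTES_PER_DAY) - base
    sk <- se > ss
    cs <- pmax(sess_all$start, base) - base
    ce <- pmin(sess_all$end, base + MINUTES_PER_DAY) - base
    ck <- (ce > cs) & (cs < di$wake - base)   # pre-wake usage for the trigger
    night_sess <- data.frame(start = cs[ck],
                             end = pmin(ce[ck], di$wake - base))
    ctx <- list(wake_min = di$wake - base,
                bed_min = min(di$bed - base, MINUTES_PER_DAY - 1),
                school = if (!is.null(di$school)) di$school - base,
                tutoring = if (!is.null(di$tutoring)) di$tutoring - base,
                sleep_windows = data.frame(start = ss[sk], end = se[sk]))
    sp_seed <- sample.int(.Machine$integer.max - 1, 1)
    prompts <- schedule_prompts(ctx, night_sess, seed = sp_seed)
    resp_seed <- sample.int(.Machine$integer.max - 1, 1)
    if (!nrow(prompts)) next
    prompts$prompt_id <- sprintf("%s-d%02d-%s", id, d0, prompts$slot)
    resp <- generate_ema_responses(zrow(d0 + 1), prompts, config$adherence_p,
                                   config$ema_noise_sd, seed = resp_seed)
    hit <- match(prompts$prompt_id, resp$prompt_id)
    acc$prompt_id <- c(acc$prompt_id, prompts$prompt_id)
    acc$day_index <- c(acc$day_index, rep.int(d0, nrow(prompts)))
    acc$slot <- c(acc$slot, prompts$slot)
    acc$sent_min <- c(acc$sent_min, base + prompts$sent_min)
    acc$answered <- c(acc$answered, !is.na(hit))
    acc$depression <- c(acc$depression, resp$depression[hit])
    acc$anxiety <- c(acc$anxiety, resp$anxiety[hit])
    acc$stress <- c(acc$stress, resp$stress[hit])
    acc$adjectives <- c(acc$adjectives,
                        ifelse(is.na(hit), "", resp$adjectives[hit]))
  }
  ema_df <- if (length(acc$prompt_id)) as.data.frame(acc,
                                                     stringsAsFactors = FALSE)
            else NULL

  ## --- questionnaire phase -------------------------------------------------
  set.seed(phase_seeds[4])
  waves <- c(baseline = 0, mid = floor(nd / 2), post = nd)
  q_rows <- list()
  for (w in seq_along(waves)) {
    for (ins in names(config$group_time_effects)) {
      spec <- instrument_spec(ins)
      target <- config$group_time_effects[[ins]][[group]][w]
      p <- clamp((target / spec$n_items - spec$lo) / (spec$hi - spec$lo) +
                   stats::rnorm(1, 0, 0.05), 0.02, 0.98)
      items <- spec$lo + stats::rbinom(spec$n_items, spec$hi - spec$lo, p)
      q_rows[[length(q_rows) + 1]] <- data.frame(
        wave = names(waves)[w], wave_day = unname(waves[w]), instrument = ins,
        item = seq_len(spec$n_items), response = items,
        stringsAsFactors = FALSE)
    }
    if (names(waves)[w] == "post" && group == "intervention") {
      spec <- instrument_spec("mauq")
      p <- clamp((config$mauq_item_mean - spec$lo) / (spec$hi - spec$lo) +
                   stats::rnorm(1, 0, 0.04), 0.02, 0.98)
      items <- spec$lo + stats::rbinom(spec$n_items, spec$hi - spec$lo, p)
      q_rows[[length(q_rows) + 1]] <- data.frame(
        wave = "post", wave_day = unname(waves[w]), instrument = "mauq",
        item = seq_len(spec$n_items), response = items,
        stringsAsFactors = FALSE)
    }
  }
  quest_df <- do.call(rbind, q_rows)

  tag <- function(df) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$participant_id <- id
    rownames(df) <- NULL
    df[, c(ncol(df), seq_len(ncol(df) - 1))]
  }
  list(gps = tag(gps_df), screen = tag(screen_df), sleep = tag(sleep_df),
       lifestyle = tag(lifestyle), ema = tag(ema_df),
       questionnaires = tag(quest_df),
       latent = tag(data.frame(day_index = 0:(nd - 1),
                               depression = z[, "depression"],
                               anxiety = z[, "anxiety"],
                               stress = z[, "stress"])))
}

# Item counts and Likert ranges of the scored instruments.
instrument_spec <- function(instrument) {
  switch(instrument,
    dass_depression = ,
    dass_anxiety = ,
    dass_stress = list(n_items = 7L, lo = 0L, hi = 3L),
    dass = list(n_items = 21L, lo = 0L, hi = 3L),
    self_efficacy = list(n_items = 22L, lo = 1L, hi = 5L),
    time_management = list(n_items = 30L, lo = 1L, hi = 5L),
    mauq = list(n_items = 21L, lo = 1L, hi = 7L),
    dp_stop(sprintf("unknown instrument '%s'", instrument)))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic digital-phenotyping cohort\n")
  cat(sprintf("  participants: %d (%d control, %d intervention), %d days\n",
              nrow(x$participants), sum(x$participants$group == "control"),
              sum(x$participants$group == "intervention"), x$config$n_days))
  for (f in c("gps", "screen", "sleep", "lifestyle", "ema", "questionnaires"))
    if (!is.null(x[[f]])) cat(sprintf("  %-14s %d rows\n", f, nrow(x[[f]])))
  invisible(x)
}
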