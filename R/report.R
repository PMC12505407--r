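# Full analysis: daily aggregation -> IQR outlier exclusion -> pooled Pearson
# phenotype-EMA correlation grid (13 features x 3 constructs), baseline group
# comparisons, per-outcome 2x3 mixed ANOVA, adherence summary.

#' Score all questionnaire waves of a cohort
#'
#' @param cohort a `cohort_dataset`.
#' @return data frame with one row per participant-wave: `participant_id`,
#'   `group`, `wave`, and one column per scored outcome.
#' @export
score_waves <- function(cohort) {
  q <- cohort$questionnaires
  grp <- stats::setNames(cohort$participants$group,
                         cohort$participants$participant_id)
  keys <- unique(q[, c("participant_id", "wave")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    id <- keys$participant_id[i]; w <- keys$wave[i]
    sub <- q[q$participant_id == id & q$wave == w, ]
    out <- data.frame(participant_id = id, group = unname(grp[id]), wave = w,
                      stringsAsFactors = FALSE)
    for (ins in unique(sub$instrument)) {
      items <- sub[sub$instrument == ins, ]
      sc <- score_questionnaire(items$response[order(items$item)], ins)
      for (nm in names(sc)) out[[nm]] <- sc[[nm]]
    }
    out
  })
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA_real_
    r[nms]
  })
  do.call(rbind, rows)
}

#' Pearson correlation grid between passive features and EMA constructs
#'
#' For each feature x construct cell, participant-days with both values
#' present are pooled, the feature values are IQR-filtered (outliers dropped,
#' never imputed), and the Pearson r with its two-sided p is computed.
#'
#' @param daily daily-record table from [extract_daily_records()].
#' @param iqr_multiplier fence multiplier for the outlier exclusion.
#' @param within_person if `TRUE`, both variables are centred on participant
#'   means before pooling (off by default: the primary analysis pools raw
#'   participant-days).
#' @param bh_correct if `TRUE`, adds a Benjamini-Hochberg adjusted p column
#'   across the grid (off by default: alpha applies per cell).
#' @return data frame `feature`, `construct`, `r`, `p`, `n`, `n_excluded`
#'   (+ `p_adj` when requested).
#' @export
correlation_grid <- function(daily, iqr_multiplier = 1.5,
                             within_person = FALSE, bh_correct = FALSE) {
  feats <- intersect(PASSIVE_FEATURES, names(daily))
  out <- list()
  for (f in feats) for (k in EMA_CONSTRUCTS) {
    x <- daily[[f]]
    y <- daily[[paste0("ema_", k)]]
    ok <- is.finite(x) & is.finite(y)
    xi <- x[ok]; yi <- y[ok]; pid <- daily$participant_id[ok]
    n_excluded <- 0L
    if (length(xi) >= 4) {
      kept <- iqr_filter(xi, multiplier = iqr_multiplier)
      fences <- attr(kept, "fences")
      keep <- xi >= fences[1] & xi <= fences[2]
      n_excluded <- sum(!keep)
      xi <- xi[keep]; yi <- yi[keep]; pid <- pid[keep]
    }
    if (within_person && length(xi)) {
      xi <- xi - stats::ave(xi, pid)
      yi <- yi - stats::ave(yi, pid)
    }
    cell <- if (length(xi) >= 3 && stats::sd(xi) > 0 && stats::sd(yi) > 0)
      pearson_corr(xi, yi)
    else list(r = NA_real_, p = NA_real_, n = length(xi), defined = FALSE)
    out[[length(out) + 1]] <- data.frame(
      feature = f, construct = k, r = cell$r, p = cell$p, n = cell$n,
      n_excluded = n_excluded, stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  if (bh_correct) grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  grid
}

#' Run the complete analysis pathway on a cohort
#'
#' @param cohort a `cohort_dataset`.
#' @param features feature families forwarded to [extract_daily_records()].
#' @param iqr_multiplier,within_person,bh_correct forwarded to
#'   [correlation_grid()].
#' @param alpha significance level for the ANOVA post hoc decisions.
#' @return object of class `digiphen_report`: list with `daily` (records
#'   table), `correlations` (the feature x construct grid), `baseline`
#'   (per-outcome t and Mann-Whitney group comparisons at baseline), `anova`
#'   (per-outcome [mixed_anova_2x3()] results plus a flat summary table),
#'   `adherence`, `waves` (scored questionnaires), `manifest`.
#' @export
run_full_analysis <- function(cohort, features = c("location", "sleep", "phone"),
                              iqr_multiplier = 1.5, within_person = FALSE,
                              bh_correct = FALSE, alpha = 0.05) {
  daily <- extract_daily_records(cohort, features = features)
  grid <- correlation_grid(daily, iqr_multiplier = iqr_multiplier,
                           within_person = within_person,
                           bh_correct = bh_correct)
  waves <- score_waves(cohort)
  outcomes <- intersect(c("dass_depression", "dass_anxiety", "dass_stress",
                          "self_efficacy", "time_management"), names(waves))

  base <- waves[waves$wave == "baseline", ]
  baseline <- do.call(rbind, lapply(outcomes, function(oc) {
    a <- base[[oc]][base$group == "control"]
    b <- base[[oc]][base$group == "intervention"]
    if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NULL)
    tt <- independent_t(a[is.finite(a)], b[is.finite(b)])
    mw <- mann_whitney_u(a[is.finite(a)], b[is.finite(b)])
    data.frame(outcome = oc, mean_control = mean(a, na.rm = TRUE),
               sd_control = stats::sd(a, na.rm = TRUE),
               mean_intervention = mean(b, na.rm = TRUE),
               sd_intervention = stats::sd(b, na.rm = TRUE),
               t = tt$t, df = tt$df, p_t = tt$p, U = mw$U, p_u = mw$p,
               stringsAsFactors = FALSE)
  }))

  anovas <- lapply(outcomes, function(oc)
    suppressWarnings(mixed_anova_2x3(waves, oc, alpha = alpha)))
  names(anovas) <- outcomes
  anova_tab <- do.call(rbind, lapply(outcomes, function(oc) {
    tb <- anovas[[oc]]$table
    tb$outcome <- oc
    tb$cohens_d <- anovas[[oc]]$cohens_d
    tb[, c("outcome", "effect", "df1", "df2", "ss", "ms", "F", "p", "cohens_d")]
  }))

  prompts <- cohort$ema
  adherence <- if (!is.null(prompts) && nrow(prompts)) {
    compute_adherence(prompts, prompts[prompts$answered, , drop = FALSE],
                      cohort$lifestyle)
  } else NULL

  mauq_mean <- if ("mauq" %in% names(waves))
    mean(waves$mauq[waves$wave == "post" & waves$group == "intervention"],
         na.rm = TRUE) else NA_real_

  manifest <- list(
    seed = cohort$config$seed,
    n_participants = nrow(cohort$participants),
    n_days = cohort$config$n_days,
    features = features,
    iqr_multiplier = iqr_multiplier,
    within_person = within_person, bh_correct = bh_correct,
    n_outliers_excluded = sum(grid$n_excluded),
    package_version = as.character(utils::packageVersion("digiphen")))

  structure(list(daily = daily, correlations = grid, baseline = baseline,
                 anova = anova_tab, anova_fits = anovas,
                 adherence = adherence, waves = waves, mauq_mean = mauq_mean,
                 manifest = manifest),
            class = "digiphen_report")
}

#' @export
print.digiphen_report <- function(x, ...) {
  cat("Digital-phenotyping analysis report\n")
  cat(sprintf("  daily records: %d rows, %d outliers excluded\n",
              nrow(x$daily), x$manifest$n_outliers_excluded))
  sig <- sum(x$correlations$p < 0.05, na.rm = TRUE)
  cat(sprintf("  correlation grid: %d cells, %d with p < .05\n",
              nrow(x$correlations), sig))
  if (!is.null(x$adherence))
    cat(sprintf("  adherence: mood %.2f%%, lifestyle %.2f%%\n",
                x$adherence$mood_mean_pct, x$adherence$lifestyle_mean_pct))
  if (is.finite(x$mauq_mean))
    cat(sprintf("  usability (post, intervention): %.2f / 7\n", x$mauq_mean))
  invisible(x)
}

#' Serialise a report bundle to CSV + JSON
#'
#' Writes `correlations.csv`, `anova.csv`, `baseline.csv`, `adherence.csv`,
#' `daily_records.csv` and `manifest.json` under `dir`.
#'
#' @param report a `digiphen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$anova, file.path(dir, "anova.csv"), row.names = FALSE)
  if (!is.null(report$baseline))
    utils::write.csv(report$baseline, file.path(dir, "baseline.csv"),
                     row.names = FALSE)
  if (!is.null(report$adherence))
    utils::write.csv(report$adherence$per_participant,
                     file.path(dir, "adherence.csv"), row.names = FALSE)
  utils::write.csv(report$daily, file.path(dir, "daily_records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
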