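# Statistical pathway: questionnaire scoring, IQR outlier exclusion, pooled
# Pearson correlations, baseline group tests, the 2x3 mixed repeated-measures
# ANOVA with Scheffe post hoc contrasts and Cohen's d on change scores, and a
# noncentral-F power / sample-size calculator for repeated-measures designs.

#' Score a questionnaire from item-level responses
#'
#' DASS-21 subscales are raw sums of their 7 items (0-3 each; canonical item
#' assignment: depression 3,5,10,13,16,17,21; anxiety 2,4,7,9,15,19,20; stress
#' the remainder). Self-efficacy (22 items, 1-5) and time management (30
#' items, 1-5) are item sums. The usability questionnaire (21 items, 1-7)
#' reports the overall item mean plus its three subfactor means (ease of
#' use/satisfaction items 1-8, information arrangement 9-14, usefulness
#' 15-21).
#'
#' @param responses integer vector of item responses, in item order.
#' @param instrument one of `"dass"`, `"dass_depression"`, `"dass_anxiety"`,
#'   `"dass_stress"`, `"self_efficacy"`, `"time_management"`, `"mauq"`.
#' @return named numeric vector of scores.
#' @export
score_questionnaire <- function(responses, instrument) {
  spec <- instrument_spec(instrument)
  if (length(responses) != spec$n_items)
    dp_stop(sprintf("%s expects %d items, got %d", instrument, spec$n_items,
                    length(responses)))
  if (any(is.na(responses)) || any(responses < spec$lo | responses > spec$hi))
    dp_stop(sprintf("%s responses must lie in [%d, %d]", instrument, spec$lo,
                    spec$hi))
  switch(instrument,
    dass = {
      dep <- c(3, 5, 10, 13, 16, 17, 21)
      anx <- c(2, 4, 7, 9, 15, 19, 20)
      str <- setdiff(1:21, c(dep, anx))
      c(dass_depression = sum(responses[dep]),
        dass_anxiety = sum(responses[anx]),
        dass_stress = sum(responses[str]))
    },
    dass_depression = c(dass_depression = sum(responses)),
    dass_anxiety = c(dass_anxiety = sum(responses)),
    dass_stress = c(dass_stress = sum(responses)),
    self_efficacy = c(self_efficacy = sum(responses)),
    time_management = c(time_management = sum(responses)),
    mauq = c(mauq = mean(responses),
             mauq_ease = mean(responses[1:8]),
             mauq_arrangement = mean(responses[9:14]),
             mauq_usefulness = mean(responses[15:21])))
}

#' Exclude values outside the 1.5 x IQR fences
#'
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile(type = 7)`); values below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR` are dropped, never imputed. With fewer than 4 finite values
#' the input is passed through with a warning.
#'
#' @param values numeric vector (`NA`s are dropped first).
#' @param multiplier fence multiplier, default 1.5.
#' @return the kept values, with attribute `excluded` holding the dropped ones.
#' @export
iqr_filter <- function(values, multiplier = 1.5) {
  x <- values[is.finite(values)]
  if (length(x) < 4) {
    warning("fewer than 4 finite values: IQR filter passed through")
    return(structure(x, excluded = numeric(0), fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - multiplier * iqr, q[2] + multiplier * iqr)
  keep <- x >= fences[1] & x <= fences[2]
  structure(x[keep], excluded = x[!keep], fences = fences)
}

#' Pearson correlation with two-sided p from the t transform
#'
#' @param x,y paired numeric vectors; pairs with any `NA` are dropped.
#' @return list `r`, `p`, `n`, `defined`. Zero variance in either variable
#'   yields the undefined-correlation sentinel (`defined = FALSE`, `r = NA`).
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) dp_stop("pearson_corr needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Independent-samples t test (pooled variance)
#' @param a,b numeric samples with at least 2 values each.
#' @return list `t`, `df`, `p`.
#' @export
independent_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) dp_stop("each sample needs >= 2 values")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Reports `U = min(U1, U2)`; the two-sided p-value uses the large-sample
#' normal approximation with the tie-corrected variance (no continuity
#' correction).
#'
#' @param a,b numeric samples.
#' @return list `U`, `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) dp_stop("samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)])
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(a, b))
  sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sig2 <= 0) return(list(U = u, p = 1))
  z <- (u1 - mu) / sqrt(sig2)
  list(U = u, p = 2 * stats::pnorm(-abs(z)))
}

# ---------------------------------------------------------------------------

#' Mixed 2 x m repeated-measures ANOVA (split-plot)
#'
#' One between-subjects factor (group) and one within-subjects factor (time),
#' complete data after listwise deletion, sphericity assumed (uncorrected
#' integer degrees of freedom). Sums of squares follow the classical
#' split-plot decomposition; with unbalanced groups the observed (weighted)
#' marginal means are used, matching `aov` with an `Error(id)` stratum.
#'
#' @param data data frame with columns `participant_id`, `group`, `wave`, and
#'   the outcome named by `outcome`.
#' @param outcome name of the outcome column.
#' @param alpha significance level used to decide which effects get Scheffe
#'   post hoc contrasts.
#' @return object of class `mixed_anova`: list with `table` (effect, df1, df2,
#'   ss, ms, F, p), `post_hoc` (Scheffe pairwise contrasts on the time means,
#'   only when the omnibus time effect is significant), `cohens_d`
#'   (baseline-to-post change-score d), `excluded` (participants dropped for
#'   missing waves), `n_per_group`.
#' @export
mixed_anova_2x3 <- function(data, outcome, alpha = 0.05) {
  d <- data.frame(id = data$participant_id, group = data$group,
                  time = data$wave, y = data[[outcome]],
                  stringsAsFactors = FALSE)
  d <- d[is.finite(d$y), ]
  m_levels <- unique(d$time)
  m <- length(m_levels)
  counts <- table(d$id)
  complete <- names(counts)[counts == m]
  excluded <- setdiff(unique(data$participant_id), complete)
  if (length(excluded))
    warning(sprintf("excluding %d participant(s) with missing waves: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  d <- d[d$id %in% complete, ]
  N <- length(complete)
  g_of <- tapply(d$group, d$id, `[`, 1)
  g_levels <- unique(d$group)
  g <- length(g_levels)
  if (N < g + 1 || m < 2) dp_stop("not enough complete participants for the ANOVA")

  grand <- mean(d$y)
  subj_mean <- tapply(d$y, d$id, mean)
  grp_mean <- tapply(d$y, d$group, mean)
  time_mean <- tapply(d$y, d$time, mean)
  cell_mean <- tapply(d$y, list(d$group, d$time), mean)
  n_g <- table(g_of)[g_levels]

  ss_subj <- m * sum((subj_mean - grand)^2)
  ss_group <- m * sum(n_g * (grp_mean[g_levels] - grand)^2)
  ss_err_b <- ss_subj - ss_group
  ss_time <- N * sum((time_mean - grand)^2)
  ss_cells <- sum(outer(as.numeric(n_g), rep(1, m)) *
                    (cell_mean[g_levels, , drop = FALSE] - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((d$y - grand)^2)
  ss_err_w <- ss_tot - ss_subj - ss_time - ss_int

  df_g <- g - 1; df_eb <- N - g
  df_t <- m - 1; df_i <- (g - 1) * (m - 1); df_ew <- (N - g) * (m - 1)
  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_eb <- ms(ss_err_b, df_eb); ms_ew <- ms(ss_err_w, df_ew)
  f_of <- function(ss, df, mse) if (mse > 0) (ss / df) / mse else 0
  F_g <- f_of(ss_group, df_g, ms_eb)
  F_t <- f_of(ss_time, df_t, ms_ew)
  F_i <- f_of(ss_int, df_i, ms_ew)
  tab <- data.frame(
    effect = c("group", "time", "group:time"),
    df1 = c(df_g, df_t, df_i), df2 = c(df_eb, df_ew, df_ew),
    ss = c(ss_group, ss_time, ss_int),
    ms = c(ms(ss_group, df_g), ms(ss_time, df_t), ms(ss_int, df_i)),
    F = c(F_g, F_t, F_i),
    p = c(stats::pf(F_g, df_g, df_eb, lower.tail = FALSE),
          stats::pf(F_t, df_t, df_ew, lower.tail = FALSE),
          stats::pf(F_i, df_i, df_ew, lower.tail = FALSE)))

  post <- NULL
  if (is.finite(tab$p[2]) && tab$p[2] < alpha) {
    post <- scheffe_pairwise(time_mean, rep(N, m), ms_ew, df_ew, k = m,
                             alpha = alpha)
  }

  # Cohen's d on baseline-to-post change scores between groups
  d_cohen <- NA_real_
  waves_ord <- intersect(c("baseline", "mid", "post"), m_levels)
  if (all(c("baseline", "post") %in% waves_ord) && g == 2) {
    wide_b <- d$y[d$time == "baseline"][match(complete, d$id[d$time == "baseline"])]
    wide_p <- d$y[d$time == "post"][match(complete, d$id[d$time == "post"])]
    change <- wide_p - wide_b
    grp <- g_of[complete]
    cl <- split(change, grp)
    if (length(cl) == 2 && all(lengths(cl) >= 2)) {
      n1 <- length(cl[[1]]); n2 <- length(cl[[2]])
      sp <- sqrt(((n1 - 1) * stats::var(cl[[1]]) +
                    (n2 - 1) * stats::var(cl[[2]])) / (n1 + n2 - 2))
      d_cohen <- if (sp > 0) abs(mean(cl[[2]]) - mean(cl[[1]])) / sp else NA_real_
    }
  }

  structure(list(table = tab, post_hoc = post, cohens_d = d_cohen,
                 excluded = excluded, n_per_group = as.list(n_g),
                 outcome = outcome),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed 2x%d repeated-measures ANOVA: %s\n",
              x$table$df1[2] + 1, x$outcome))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$post_hoc)) {
    cat("Scheffe post hoc (time):\n")
    print(x$post_hoc, row.names = FALSE, digits = 4)
  }
  if (is.finite(x$cohens_d))
    cat(sprintf("Cohen's d (baseline-to-post change): %.3f\n", x$cohens_d))
  invisible(x)
}

#' Scheffe pairwise contrasts
#'
#' For each pair of level means the contrast F is
#' `(m_i - m_j)^2 / (MS_err (1/n_i + 1/n_j)) / (k - 1)` compared against
#' `F(k - 1, df_err)`. By construction no pairwise contrast is significant
#' when the omnibus F is not.
#'
#' @param means named vector of level means.
#' @param ns observations per level.
#' @param ms_error,df_error error mean square and its df.
#' @param k number of levels in the family.
#' @param alpha significance level.
#' @return data frame `level_1`, `level_2`, `diff`, `F`, `p`, `significant`.
#' @export
scheffe_pairwise <- function(means, ns, ms_error, df_error, k = length(means),
                             alpha = 0.05) {
  lv <- names(means)
  if (is.null(lv)) lv <- as.character(seq_along(means))
  out <- list()
  for (i in seq_along(means)) for (j in seq_along(means)) {
    if (j <= i) next
    diff <- means[i] - means[j]
    Fc <- diff^2 / (ms_error * (1 / ns[i] + 1 / ns[j])) / (k - 1)
    p <- stats::pf(Fc, k - 1, df_error, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      level_1 = lv[i], level_2 = lv[j], diff = unname(diff), F = unname(Fc),
      p = unname(p), significant = unname(p < alpha),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Sample size for a repeated-measures design by noncentral-F power
#'
#' Finds the smallest per-group n whose power reaches the target for the
#' chosen effect family, using the standard repeated-measures noncentrality
#' parameters (effect size Cohen's f, m measures, correlation `rho` among
#' them): between `lambda = f^2 N m / (1 + (m-1) rho)` with df `(g-1, N-g)`;
#' within and interaction `lambda = f^2 N m / (1 - rho)` with df `(m-1,
#' (N-g)(m-1))` and `((g-1)(m-1), (N-g)(m-1))`.
#'
#' @param effect_size_f Cohen's f of the tested effect.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param groups,measures design dimensions.
#' @param rho correlation among the repeated measures, `0 <= rho < 1`.
#' @param family effect family: `"between"`, `"within"` or `"interaction"`.
#' @param n_max search bound.
#' @return list `n_per_group`, `power_achieved`, `family`.
#' @export
rm_power_sample_size <- function(effect_size_f, alpha = 0.05, power = 0.80,
                                 groups = 2, measures = 3, rho = 0.5,
                                 family = c("between", "within", "interaction"),
                                 n_max = 10000) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    dp_stop("alpha and power must lie in (0, 1)")
  if (rho < 0 || rho >= 1) dp_stop("rho must lie in [0, 1)")
  if (effect_size_f <= 0) dp_stop("effect_size_f must be positive")
  for (n in 2:n_max) {
    pw <- rm_power(n, effect_size_f, alpha, groups, measures, rho, family)
    if (is.finite(pw) && pw >= power)
      return(list(n_per_group = n, power_achieved = pw, family = family))
  }
  dp_stop(sprintf("power %.2f unattainable within n_max = %d", power, n_max))
}

#' Power of a repeated-measures effect at a given per-group n
#' @inheritParams rm_power_sample_size
#' @param n per-group sample size.
#' @return achieved power (NA when the error df is not positive).
#' @export
rm_power <- function(n, effect_size_f, alpha = 0.05, groups = 2, measures = 3,
                     rho = 0.5,
                     family = c("between", "within", "interaction")) {
  family <- match.arg(family)
  N <- n * groups
  g <- groups; m <- measures
  if (family == "between") {
    df1 <- g - 1; df2 <- N - g
    lambda <- effect_size_f^2 * N * m / (1 + (m - 1) * rho)
  } else {
    df1 <- if (family == "within") m - 1 else (g - 1) * (m - 1)
    df2 <- (N - g) * (m - 1)
    lambda <- effect_size_f^2 * N * m / (1 - rho)
  }
  if (df2 < 1) return(NA_real_)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
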