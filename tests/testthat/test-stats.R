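# Statistical pathway: scoring, IQR fences, correlations, t / Mann-Whitney,
# the mixed ANOVA vs independent oracles, Scheffe, and the power calculator.

test_that("questionnaire scoring follows the instruments' definitions", {
  expect_equal(unname(score_questionnaire(rep(0L, 21), "dass")), c(0, 0, 0))
  expect_equal(unname(score_questionnaire(rep(3L, 21), "dass")), c(21, 21, 21))
  expect_equal(unname(score_questionnaire(rep(7L, 21), "mauq"))[1], 7)
  expect_equal(unname(score_questionnaire(rep(1L, 22), "self_efficacy")), 22)
  expect_equal(unname(score_questionnaire(rep(5L, 30), "time_management")), 150)
  # subscales pick the right items: put 3s on the depression items only
  r <- rep(0L, 21); r[c(3, 5, 10, 13, 16, 17, 21)] <- 3L
  expect_equal(unname(score_questionnaire(r, "dass")), c(21, 0, 0))
  expect_error(score_questionnaire(rep(1, 20), "dass"), "21 items")
  expect_error(score_questionnaire(rep(9L, 21), "dass"), "lie in")
})

test_that("IQR filter reproduces the interpolated-quartile fences", {
  x <- c(1:9, 100)
  kept <- iqr_filter(x)
  expect_equal(as.numeric(kept), 1:9)          # fences -3.5 and 14.5
  expect_equal(attr(kept, "excluded"), 100)
  expect_equal(attr(kept, "fences"), c(-3.5, 14.5))
  # all-equal input is untouched (IQR 0 keeps the common value)
  expect_equal(as.numeric(iqr_filter(rep(4, 6))), rep(4, 6))
  # idempotence on the worked example
  expect_equal(as.numeric(iqr_filter(as.numeric(kept))), 1:9)
  expect_warning(iqr_filter(c(1, 2, 3)), "fewer than 4")
})

test_that("pearson correlation matches the product-moment formula", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(c(1, 2, 3), c(6, 5, 4))$r, -1)
  pc <- pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(pc$r, 0.6)
  expect_equal(pc$n, 4)
  # zero variance -> undefined sentinel
  expect_false(pearson_corr(rep(1, 5), 1:5)$defined)
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("baseline tests match their definitions and brute-force pair counts", {
  ident <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$df, 4)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  # exhaustive pair-counting oracle (ties count half), n <= 8 per sample
  brute_u <- function(a, b) {
    u1 <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    min(u1, length(a) * length(b) - u1)
  }
  set.seed(17)
  for (i in 1:50) {
    a <- sample(1:6, sample(2:8, 1), replace = TRUE)
    b <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, brute_u(a, b))
  }
  # p agrees with the reference normal approximation
  set.seed(18)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mann_whitney_u(a, b)$p, ref$p.value, tolerance = 1e-10)
})

make_waves <- function(n1, n2, means, sd = 1, seed = 1) {
  # means: 2 x 3 matrix of group x wave cell means
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n1 + n2))
  grp <- rep(c("control", "intervention"), c(n1, n2))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    g <- if (grp[i] == "control") 1 else 2
    data.frame(participant_id = ids[i], group = grp[i],
               wave = c("baseline", "mid", "post"),
               y = rnorm(3, means[g, ], sd), stringsAsFactors = FALSE)
  }))
}

test_that("mixed ANOVA reproduces the split-plot decomposition of aov", {
  for (case in list(c(3, 3, 31), c(4, 3, 32), c(19, 17, 33))) {
    w <- make_waves(case[1], case[2], rbind(c(10, 9, 8), c(12, 10, 7)),
                    seed = case[3])
    fit <- mixed_anova_2x3(w, "y")
    # oracle: base aov with an Error(id) stratum
    d <- transform(w, id = factor(participant_id), time = factor(wave),
                   grp = factor(group))
    a <- summary(stats::aov(y ~ grp * time + Error(id), data = d))
    between <- a[["Error: id"]][[1]]
    within <- a[["Error: Within"]][[1]]
    expect_equal(fit$table$ss, c(between["grp", "Sum Sq"],
                                 within["time", "Sum Sq"],
                                 within["grp:time", "Sum Sq"]),
                 tolerance = 1e-8)
    expect_equal(fit$table$F, c(between["grp", "F value"],
                                within["time", "F value"],
                                within["grp:time", "F value"]),
                 tolerance = 1e-8)
    N <- case[1] + case[2]
    expect_equal(fit$table$df1, c(1, 2, 2))
    expect_equal(fit$table$df2, c(N - 2, 2 * (N - 2), 2 * (N - 2)))
  }
})

test_that("a 19 + 17 cohort yields the (2, 68) within-subject df", {
  w <- make_waves(19, 17, rbind(c(10, 9, 8), c(18, 14, 12)), seed = 4)
  fit <- mixed_anova_2x3(w, "y")
  expect_equal(fit$table$df1[fit$table$effect == "group:time"], 2)
  expect_equal(fit$table$df2[fit$table$effect == "group:time"], 68)
})

test_that("constant outcomes give F = 0 and sums of squares always add up", {
  w <- make_waves(4, 4, rbind(c(5, 5, 5), c(5, 5, 5)), sd = 0, seed = 9)
  fit <- mixed_anova_2x3(w, "y")
  expect_equal(fit$table$F, c(0, 0, 0))
  # SS decomposition identity on random unbalanced data
  set.seed(10)
  for (i in 1:10) {
    w <- make_waves(sample(3:8, 1), sample(3:8, 1),
                    matrix(rnorm(6, 10, 3), 2, 3), seed = 100 + i)
    fit <- mixed_anova_2x3(w, "y")
    ss_tot <- sum((w$y - mean(w$y))^2)
    subj <- tapply(w$y, w$participant_id, mean)
    ss_between_subj <- 3 * sum((subj - mean(w$y))^2)
    # between-subjects stratum contains the group effect
    expect_lte(fit$table$ss[1], ss_between_subj + 1e-8)
    # within stratum: time + interaction + within error = total - between-subj
    err_w <- ss_tot - ss_between_subj - fit$table$ss[2] - fit$table$ss[3]
    expect_gte(err_w, -1e-8)
    # the reported F uses exactly that within error mean square
    expect_equal((fit$table$ss[2] / fit$table$df1[2]) / (err_w / fit$table$df2[2]),
                 fit$table$F[2], tolerance = 1e-6)
  }
})

test_that("participants with missing waves are excluded with a warning", {
  w <- make_waves(3, 3, rbind(c(10, 9, 8), c(12, 10, 7)), seed = 2)
  w <- w[!(w$participant_id == "S01" & w$wave == "post"), ]
  expect_warning(fit <- mixed_anova_2x3(w, "y"), "S01")
  expect_equal(fit$excluded, "S01")
  expect_equal(fit$table$df2[1], 3)   # 5 complete subjects, 2 groups
})

test_that("Scheffe contrasts never beat an insignificant omnibus F", {
  set.seed(30)
  for (i in 1:30) {
    w <- make_waves(5, 5, matrix(rnorm(6, 10, 0.2), 2, 3), seed = 200 + i)
    fit <- mixed_anova_2x3(w, "y", alpha = 0.05)
    t_row <- fit$table[fit$table$effect == "time", ]
    tm <- tapply(w$y, w$wave, mean)
    ms_ew <- t_row$ms / t_row$F
    ph <- scheffe_pairwise(tm, rep(10, 3), ms_ew, t_row$df2, k = 3)
    # every pairwise contrast F is bounded by the omnibus F (shared error term)
    expect_true(all(ph$F <= t_row$F + 1e-9))
    if (t_row$p >= 0.05) {
      expect_null(fit$post_hoc)
      expect_false(any(ph$significant))
    }
  }
})

test_that("power calculator is monotone and self-consistent, and matches the
           26-per-group repeated-measures design", {
  # the printed design: alpha .05, power 80%, 2 groups, 3 measures, effect .33
  res <- rm_power_sample_size(effect_size_f = 0.33, alpha = 0.05, power = 0.80,
                              groups = 2, measures = 3, rho = 0.5,
                              family = "between")
  expect_equal(res$n_per_group, 26)
  expect_gte(res$power_achieved, 0.80)
  expect_lt(rm_power(25, 0.33, family = "between"), 0.80)
  # doubling the effect size never increases the required n
  n_small <- rm_power_sample_size(0.2, family = "within")$n_per_group
  n_big <- rm_power_sample_size(0.4, family = "within")$n_per_group
  expect_lte(n_big, n_small)
  # saturation: a huge effect needs the minimal group size
  expect_lte(rm_power_sample_size(100, family = "interaction")$n_per_group, 3)
  # power is monotone increasing in n
  pws <- vapply(3:40, rm_power, numeric(1), effect_size_f = 0.25,
                family = "within")
  expect_true(all(diff(pws) > -1e-12))
  expect_error(rm_power_sample_size(1e-4, n_max = 50), "unattainable")
})
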