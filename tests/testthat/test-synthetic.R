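# Synthetic cohort generator: shape, determinism, stream well-formedness,
# the ordinal response model, and ground-truth parameter recovery.

test_that("the default deployment has 36 participants x 28 days", {
  cfg <- sim_config(seed = 1, gps_interval_min = 60)
  expect_equal(cfg$n_control + cfg$n_intervention, 36)
  expect_equal(cfg$n_days, 28)
  co <- generate_cohort(cfg, streams = c("screen", "sleep", "lifestyle",
                                         "ema", "questionnaires"))
  expect_equal(nrow(co$participants), 36)
  expect_equal(sum(co$participants$group == "control"), 19)
  expect_equal(sum(co$participants$group == "intervention"), 17)
  expect_equal(nrow(co$latent), 36 * 28)
  # 3 questionnaire waves per participant
  expect_setequal(unique(co$questionnaires$wave), c("baseline", "mid", "post"))
  # usability items only at post, intervention only
  mq <- co$questionnaires[co$questionnaires$instrument == "mauq", ]
  expect_setequal(unique(mq$wave), "post")
  expect_true(all(mq$participant_id %in%
                    co$participants$participant_id[co$participants$group == "intervention"]))
})

test_that("identical configurations give byte-identical datasets", {
  cfg <- tiny_config(seed = 13, n_days = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(sim_config(seed = 13, n_intervention = 2, n_control = 2,
                                  n_days = 3, gps_interval_min = 15))
  expect_identical(a$gps, b$gps)
  expect_identical(a$screen, b$screen)
  expect_identical(a$ema, b$ema)
  expect_identical(a$questionnaires, b$questionnaires)
  # dropping a stream leaves the others untouched
  c2 <- generate_cohort(cfg, streams = c("screen", "sleep", "lifestyle",
                                         "ema", "questionnaires"))
  expect_null(c2$gps)
  expect_identical(a$screen, c2$screen)
  expect_identical(a$ema, c2$ema)
})

test_that("generated streams satisfy their well-formedness invariants", {
  set.seed(41)
  for (i in 1:12) {
    cfg <- sim_config(seed = sample.int(1e6, 1),
                      n_intervention = sample(1:3, 1),
                      n_control = sample(1:3, 1),
                      n_days = sample(2:6, 1),
                      adherence_p = runif(1, 0.5, 1),
                      gps_interval_min = 30)
    co <- generate_cohort(cfg)
    for (id in co$participants$participant_id) {
      g <- co$gps[co$gps$participant_id == id, ]
      expect_false(is.unsorted(g$t_min, strictly = TRUE))
      s <- co$screen[co$screen$participant_id == id, ]
      expect_false(is.unsorted(s$t_min, strictly = TRUE))
      expect_true(all(s$kind[c(TRUE, FALSE)] == "unlock"))
      expect_true(all(s$kind[c(FALSE, TRUE)] == "lock"))
      slp <- co$sleep[co$sleep$participant_id == id, ]
      expect_true(all(slp$end > slp$start))
      lf <- co$lifestyle[co$lifestyle$participant_id == id, ]
      expect_equal(nrow(lf), 48 * cfg$n_days)
      expect_true(all(table(lf$day_index) == 48))
    }
    expect_true(all(co$ema$slot %in% prompt_slots()))
    ans <- co$ema[co$ema$answered, ]
    expect_true(all(ans$depression %in% 1:5))
    expect_true(all(ans$anxiety %in% 1:5))
    expect_true(all(ans$stress %in% 1:5))
  }
})

test_that("ordinal responses saturate, vanish at zero adherence, and obey the null", {
  prompts <- data.frame(prompt_id = sprintf("p%d", 1:8))
  hi <- generate_ema_responses(list(depression = Inf, anxiety = 0, stress = -Inf),
                               prompts, adherence_p = 1, noise_sd = 0.5, seed = 1)
  expect_equal(nrow(hi), 8)
  expect_true(all(hi$depression == 5))
  expect_true(all(hi$stress == 1))
  none <- generate_ema_responses(list(depression = 0, anxiety = 0, stress = 0),
                                 prompts, adherence_p = 0, noise_sd = 0.5, seed = 1)
  expect_equal(nrow(none), 0)
  expect_error(generate_ema_responses(list(depression = 0, anxiety = 0, stress = 0),
                                      prompts, 0.5, noise_sd = -1), "noise_sd")
  # null coupling: an independent feature is uncorrelated with the ratings
  # across 10^4 simulated days
  set.seed(2)
  z <- rnorm(1e4)
  feature <- rnorm(1e4)
  ratings <- vapply(seq_along(z), function(i) {
    generate_ema_responses(list(depression = z[i], anxiety = 0, stress = 0),
                           data.frame(prompt_id = "p"), 1, 0.6, seed = i)$depression
  }, integer(1))
  expect_lt(abs(cor(feature, ratings)), 0.03)
})

test_that("full adherence means every prompt is answered and every cell recorded", {
  cfg <- tiny_config(seed = 23, n_days = 4, adherence_p = 1)
  co <- generate_cohort(cfg, streams = c("screen", "sleep", "lifestyle",
                                         "ema", "questionnaires"))
  expect_true(all(co$ema$answered))
  expect_true(all(co$lifestyle$recorded))
})

test_that("a strong daytime-sleep coupling is recovered by the pipeline", {
  # coupling +0.5 on daytime sleep vs depression, 30 participants x 28 days:
  # the pooled Pearson r must be positive with p < .05 in at least 95% of
  # 100 seeded replicates
  hits <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = 5000 + s, n_intervention = 15, n_control = 15,
                      n_days = 28,
                      coupling = list(depression = c(sleep_daytime_min = 0.5)))
    co <- generate_cohort(cfg, streams = c("screen", "sleep", "lifestyle",
                                           "ema", "questionnaires"))
    d <- extract_daily_records(co, features = "sleep")
    g <- correlation_grid(d)
    cell <- g[g$feature == "sleep_daytime_min" & g$construct == "depression", ]
    if (is.finite(cell$r) && cell$r > 0 && cell$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})
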