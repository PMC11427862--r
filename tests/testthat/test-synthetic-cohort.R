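test_that("cohort generation is reproducible, clipped and matches marginals", {
  a <- generate_participants(43, seed = 7)
  b <- generate_participants(43, seed = 7)
  expect_identical(a, b)

  # growing the cohort preserves earlier participants
  big <- generate_participants(60, seed = 7)
  expect_identical(a$cognitive_reappraisal, big$cognitive_reappraisal[1:43])

  one <- generate_participants(1, seed = 2)
  cfg <- default_config()
  for (nm in names(cfg$cohort$traits)) {
    tr <- cfg$cohort$traits[[nm]]
    expect_true(one[[nm]] >= tr$lo && one[[nm]] <= tr$hi)
  }

  pool <- generate_participants(6000, seed = 5)
  expect_equal(mean(pool$gender == "woman"), 14 / 43, tolerance = 0.05)
  expect_equal(unname(prop.table(table(pool$age_group))[c("18-35", "36-45", ">46")]),
               c(14, 18, 11) / 43, tolerance = 0.06, ignore_attr = TRUE)
  for (nm in names(cfg$cohort$traits)) {
    tr <- cfg$cohort$traits[[nm]]
    expect_true(all(pool[[nm]] >= tr$lo & pool[[nm]] <= tr$hi))
  }

  # the study-sized draw sits near the deployment's 29 men / 14 women split
  expect_lt(abs(sum(a$gender == "man") - 29), 9)
})

test_that("invalid cohort configuration is rejected with the field named", {
  cfg <- default_config()
  cfg$cohort$traits$resilience$mean <- 9
  expect_error(generate_participants(5, cfg, seed = 1),
               "resilience")
  cfg2 <- default_config()
  cfg2$context$meeting_rate <- -1
  expect_error(generate_participants(5, cfg2, seed = 1), "meetings")
})

test_that("telemetry generation respects rates, caps and the zero-rate case", {
  cfg <- default_config()
  profile <- generate_participants(1, cfg, seed = 4)

  zero <- cfg
  zero$context$meeting_rate <- 0
  zero$context$self_event_rate <- 0
  zero$context$ad_hoc_call_rate <- 0
  zero$context$email_sent$mu <- 0
  zero$context$email_read$mu <- 0
  zero$context$chat$mu <- 0
  zero$context$attention$mu <- 0
  set.seed(1)
  day <- generate_context_day(profile, as.Date("2023-01-02"), zero)
  expect_equal(nrow(day$windows), 16)  # one per half hour of the 8-h day
  for (nm in c("meeting_counts", "self_event_counts", "email_messages_sent",
               "email_messages_read", "chat_messages_count",
               "ad_hoc_call_count", "attention_raw")) {
    expect_true(all(day$windows[[nm]] == 0))
  }

  set.seed(2)
  days <- do.call(rbind, lapply(1:120, function(i) {
    generate_context_day(profile, as.Date("2023-01-02") + i, cfg)$windows
  }))
  expect_true(all(days$attention_raw <= cfg$context$attention$cap))
  expect_equal(mean(days$meeting_counts), 0.30, tolerance = 0.30)
  expect_equal(mean(days$email_messages_read), 3.22, tolerance = 0.30)
  expect_true(all(days$no_meeting_minutes >= 0 &
                    days$no_meeting_minutes <= 50))

  sens <- generate_context_day(profile, as.Date("2023-01-02"), cfg)$sensed
  expect_true(all(sens$fraction_of_day >= 0 & sens$fraction_of_day <= 1))
  expect_true(all(sens$heart_rate > 0))
  expect_true(all(diff(sens$emails_received) >= 0))
})

test_that("behavioral draws follow their generating inverse-logit", {
  truth <- default_truth_models()

  # all-zero coefficients: engagement probability is exactly 1/2
  zero <- truth$engagement_coefs * 0
  feats <- encode_features(draw_nudge_covariates(50))
  expect_equal(unique(plogis(truth_lp(zero, feats))), 0.5)

  # published intercept with every covariate at its reference/zero level
  ref <- feats[1, , drop = FALSE]
  ref[1, ] <- 0
  expect_equal(plogis(truth_lp(truth$engagement_coefs, ref)),
               0.1 / 1.1, tolerance = 1e-12)

  # a covariate named by the truth model but absent raises a named error
  expect_error(truth_lp(truth$engagement_coefs, feats[, 1:5, drop = FALSE]),
               "meeting_counts")

  # marginal consistency at scale: empirical engagement rate within 3 SE
  # of the analytic mean inverse-logit over the same records
  rec <- simulate_nudge_records(100000, truth, seed = 21)
  p <- plogis(truth_lp(truth$engagement_coefs, encode_features(rec)))
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(rec$engaged) - mean(p)), 3 * se)

  # and per-record at fixed covariates through the sequential path
  profile <- generate_participants(1, seed = 6)
  record <- rec[1, ]
  record$nudge_source <- "rescheduled"  # postponement path disabled
  p_fix <- plogis(truth_lp(truth$engagement_coefs, encode_features(record)))
  truth2 <- calibrate_truth_intercept(truth)
  set.seed(77)
  draws <- replicate(2000, {
    simulate_response(record, profile, truth2)$action == "engage"
  })
  expect_lt(abs(mean(draws) - p_fix),
            3 * sqrt(p_fix * (1 - p_fix) / 2000))
})

test_that("simulated completed records respect the stress scale and labels", {
  truth <- calibrate_truth_intercept(default_truth_models())
  profile <- generate_participants(1, seed = 8)
  rec <- draw_completed_covariates(1)
  rec$nudge_source <- "rescheduled"
  set.seed(31)
  outs <- lapply(1:300, function(i) simulate_response(rec, profile, truth))
  engaged <- Filter(function(o) o$action == "engage", outs)
  done <- Filter(function(o) isTRUE(o$completed), engaged)
  expect_gt(length(done), 0)
  for (o in done) {
    expect_true(o$stress_before %in% 1:5)
    expect_true(o$stress_after %in% 1:5)
    expect_true(o$rating %in% 1:5)
    expect_true((o$stress_before - o$stress_after) %in% -1:3)
  }
})

test_that("deployment runs are deterministic and gated end to end", {
  cfg <- default_config()
  cohort <- generate_participants(2, cfg, seed = 99)
  truth <- calibrate_truth_intercept(default_truth_models(cfg), cfg)
  log1 <- run_deployment(cohort, truth, weeks = 2, seed = 99, config = cfg)
  log2 <- run_deployment(cohort, truth, weeks = 2, seed = 99, config = cfg)
  expect_identical(log1, log2)

  expect_error(run_deployment(cohort, truth, weeks = 1, seed = 1, cfg),
               "weeks")

  # replaying the emitted log reproduces every gating decision
  sd <- small_deployment()
  dec <- replay_gating(sd$log, sd$cfg)
  expect_identical(dec$sent_replayed, dec$sent_logged)
})

test_that("a week-two stress level below baseline yields zero week-two nudges", {
  cfg <- default_config()
  # freeze every stress input so the score is constant: never above its own
  # week-one mean, and EMAs constant at their own mean
  cfg$context$meeting_rate <- 0
  cfg$sensed$emails_received_per_day <- 0
  cfg$sensed$heart_rate$sd <- 0
  cfg$sensed$facial$sd <- 0
  cfg$engine$normalizers$fraction_of_day <- c(-1, 0)  # pin the ramp at 1
  cfg$response$postponement_prob <- 0
  cohort <- generate_participants(1, cfg, seed = 17)
  truth <- calibrate_truth_intercept(default_truth_models(cfg), cfg)
  log <- run_deployment(cohort, truth, weeks = 2, seed = 17, config = cfg)
  nudges <- log[log$event_type == "nudge_sent", ]
  week2 <- nudges[as.Date(nudges$timestamp) >= as.Date("2023-01-09"), ]
  expect_equal(nrow(week2), 0)
})
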