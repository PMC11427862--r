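unit_norm <- list(emails_received = c(0, 1), meetings_today = c(0, 1),
                  fraction_of_day = c(0, 1), facial = c(0, 1),
                  heart_rate = c(0, 1))

raw <- function(e, m, f, fa, h) {
  list(emails_received = e, meetings_today = m, fraction_of_day = f,
       facial = fa, heart_rate = h)
}

test_that("composite stress score is the mean of five clipped components", {
  expect_equal(compute_stress_score(raw(0, 0, 0, 0, 0), unit_norm)$value, 0)
  expect_equal(compute_stress_score(raw(1, 1, 1, 1, 1), unit_norm)$value, 1)
  expect_equal(
    compute_stress_score(raw(0.2, 0.4, 0.6, 0.8, 1.0), unit_norm)$value, 0.6)
  # clipping keeps out-of-range raw signals inside [0, 1]
  s <- compute_stress_score(raw(-5, 9, 2, 0.5, 1), unit_norm)
  expect_true(all(s$components >= 0 & s$components <= 1))
  expect_equal(s$value, mean(s$components))
  expect_error(
    compute_stress_score(list(emails_received = 1), unit_norm),
    "missing stress component")
  expect_error(
    compute_stress_score(raw(0, 0, 0, 0, 0), unit_norm[-3]),
    "fraction_of_day")
})

test_that("stress score is monotone nondecreasing in each raw signal", {
  set.seed(42)
  for (i in 1:25) {
    base <- as.list(runif(5))
    names(base) <- names(unit_norm)
    bumped <- base
    j <- sample(5, 1)
    bumped[[j]] <- bumped[[j]] + runif(1)
    expect_gte(compute_stress_score(bumped, unit_norm)$value,
               compute_stress_score(base, unit_norm)$value)
  }
})

test_that("baselines default to range midpoints and otherwise average week one", {
  b <- learn_baseline()
  expect_equal(b$score_threshold, 0.5)
  expect_equal(b$ema_threshold, 3)
  expect_equal(b$source, "default")

  b2 <- learn_baseline(c(0.2, 0.4), c(1, 2, 3))
  expect_equal(b2$score_threshold, 0.3)
  expect_equal(b2$ema_threshold, 2)
  expect_equal(b2$source, "learned")

  b3 <- learn_baseline(0.5, numeric())
  expect_equal(b3$score_threshold, 0.5)
  expect_equal(b3$ema_threshold, 3)
  expect_equal(b3$score_source, "learned")
  expect_equal(b3$ema_source, "default")

  expect_error(learn_baseline(numeric(), c(2, 6)), "1-5")
})

test_that("gating rules block in their documented order", {
  bl <- learn_baseline()  # thresholds 0.5 / 3
  hs <- high_stress()
  h <- clear_history()
  now <- h$work_start + 4 * 3600  # 13:00

  # default AND trigger: a fresh high EMA accompanies the high score
  expect_true(gate_nudge(now, hs, 5, bl, h)$send)

  # outside working hours precedes everything else
  g <- gate_nudge(h$work_start - 60, hs, 5, bl, h)
  expect_false(g$send); expect_equal(g$reason, "outside_working_hours")

  h2 <- h; h2$scheduled_pending <- now + 3600
  expect_equal(gate_nudge(now, hs, 5, bl, h2)$reason, "scheduled_pending")

  h3 <- h; h3$last_completion <- now - 30 * 60
  expect_equal(gate_nudge(now, hs, 5, bl, h3)$reason,
               "completion_cooldown")

  h4 <- h; h4$last_nudge <- now - 90 * 60
  h4$nudge_times_today <- h4$last_nudge
  expect_equal(gate_nudge(now, hs, 5, bl, h4)$reason, "nudge_cooldown")

  h5 <- h
  h5$nudge_times_today <- h$work_start + c(0, 30, 60, 90) * 60
  h5$last_nudge <- max(h5$nudge_times_today)
  expect_equal(gate_nudge(now, hs, 5, bl, h5)$reason, "daily_cap")

  # completion cooldown is checked before the nudge cooldown
  h6 <- h; h6$last_completion <- now - 10 * 60; h6$last_nudge <- now - 10 * 60
  h6$nudge_times_today <- h6$last_nudge
  expect_equal(gate_nudge(now, hs, 5, bl, h6)$reason,
               "completion_cooldown")

  expect_error(
    gate_nudge(now, hs, 5, bl,
               within(h, nudge_times_today <- now - c(60, 7200))),
    "time-ordered")
})

test_that("the stress trigger honors its configured combination rule", {
  bl <- learn_baseline(0.5, 3)
  h <- clear_history(); now <- h$work_start + 4 * 3600
  low <- compute_stress_score(raw(0, 0, 0, 0, 0), unit_norm)
  hi <- high_stress()

  and_rules <- gating_rules(trigger = "and")
  expect_false(gate_nudge(now, hi, NULL, bl, h, and_rules)$send)
  expect_false(gate_nudge(now, low, 5, bl, h, and_rules)$send)
  expect_true(gate_nudge(now, hi, 5, bl, h, and_rules)$send)

  or_rules <- gating_rules(trigger = "or")
  expect_true(gate_nudge(now, hi, NULL, bl, h, or_rules)$send)
  expect_true(gate_nudge(now, low, 5, bl, h, or_rules)$send)
  g <- gate_nudge(now, low, 2, bl, h, or_rules)
  expect_false(g$send); expect_equal(g$reason, "no_trigger")

  # user-scheduled fires bypass the trigger and (by default) the cooldowns,
  # but never working hours or the daily cap
  h7 <- h; h7$last_nudge <- now - 40 * 60; h7$nudge_times_today <- h7$last_nudge
  expect_true(gate_nudge(now, low, NULL, bl, h7, and_rules,
                         trigger_required = FALSE)$send)
  h8 <- h7
  h8$nudge_times_today <- h$work_start + c(0, 30, 60, 90) * 60
  expect_false(gate_nudge(now, low, NULL, bl, h8, and_rules,
                          trigger_required = FALSE)$send)
  strict <- gating_rules(trigger = "and", honor_user_schedule = FALSE)
  expect_equal(gate_nudge(now, low, NULL, bl, h7, strict,
                          trigger_required = FALSE)$reason,
               "nudge_cooldown")
})

test_that("EMA scheduling yields five spaced prompts within working hours", {
  ws <- as.POSIXct("2023-01-02 09:00:00", tz = "UTC")
  we <- ws + 8 * 3600
  set.seed(9)
  for (i in 1:20) {
    times <- schedule_emas(ws, we)
    expect_length(times, 5)
    expect_true(all(times >= ws & times < we))
    expect_true(all(diff(as.numeric(times)) >= 30 * 60))
  }
  set.seed(1); a <- schedule_emas(ws, we)
  set.seed(1); b <- schedule_emas(ws, we)
  expect_identical(a, b)
  expect_error(schedule_emas(ws, ws + 3600, n = 5, min_spacing_min = 30),
               "cannot hold")
})

test_that("the engagement flow follows its transition graph", {
  t0 <- as.POSIXct("2023-01-02 10:00:00", tz = "UTC")
  f <- new_flow("n1", "JIT", t0)
  expect_equal(f$state, "nudged")

  # postponement registers the rescheduled time
  fp <- step_flow(f, "postpone", t0 + 60, t0 + 3600)
  expect_equal(fp$state, "postponed")
  expect_equal(fp$postponed_until, t0 + 3600)

  # expiry requires 30 minutes of inactivity, no less
  expect_error(step_flow(f, "timeout", t0 + 29 * 60), "30 minutes")
  fe <- step_flow(f, "timeout", t0 + 30 * 60)
  expect_equal(fe$state, "expired")
  expect_false(flow_engaged(fe))

  # the full engagement path
  f <- step_flow(f, "choose_category", t0 + 120, "calm")
  f <- step_flow(f, "report_stress", t0 + 180, 3)
  f <- step_flow(f, "start_intervention", t0 + 240,
                 intervention_catalog()[19, ])
  expect_false(flow_engaged(f))
  f <- step_flow(f, "done", t0 + 500)
  expect_true(flow_engaged(f))   # engaged regardless of what follows
  f <- step_flow(f, "rate", t0 + 560, 4)
  f <- step_flow(f, "report_stress", t0 + 620, 2)
  expect_equal(f$state, "post_stress_reported")
  expect_equal(f$stress_before, 3L)
  expect_equal(f$stress_after, 2L)

  # illegal transitions are named
  expect_error(step_flow(new_flow("n2", "JIT", t0), "rate", t0, 4),
               "state 'nudged' does not accept event 'rate'")
  expect_error(step_flow(new_flow("n3", "JIT", t0), "choose_category",
                         t0, "yoga"), "unknown intervention category")
})

test_that("intervention selection is uniform without replacement, then resets", {
  cat <- intervention_catalog()
  expect_equal(nrow(cat), 54)
  expect_equal(unname(table(cat$category)[c("distract", "calm", "address")]),
               rep(18L, 3), ignore_attr = TRUE)

  set.seed(11)
  served <- character()
  seen <- character()
  for (i in 1:18) {
    sel <- select_intervention("calm", served)
    expect_equal(sel$item$category, "calm")
    expect_false(sel$item$intervention_id %in% seen)
    seen <- c(seen, sel$item$intervention_id)
    served <- sel$served
  }
  expect_setequal(seen, cat$intervention_id[cat$category == "calm"])
  # 17 served: the remaining item is forced
  forced <- select_intervention("calm", served[1:17])
  expect_equal(forced$item$intervention_id, served[18])
  # all 18 served: the served set resets and any calm item may come back
  again <- select_intervention("calm", served)
  expect_true(again$item$intervention_id %in%
                cat$intervention_id[cat$category == "calm"])
  expect_length(intersect(again$served,
                          cat$intervention_id[cat$category == "calm"]), 1)
  # serving history in other categories is untouched by the reset
  mixed <- c(served, "distract_05")
  reset <- select_intervention("calm", mixed)
  expect_true("distract_05" %in% reset$served)
})

test_that("the engine sends only on five-minute ticks aligned to the workday", {
  log <- small_deployment()$log
  nudges <- log[log$event_type == "nudge_sent", ]
  day_start <- as.POSIXct(paste(as.Date(nudges$timestamp), "09:00:00"),
                          tz = "UTC")
  offsets <- as.numeric(difftime(nudges$timestamp, day_start, units = "secs"))
  expect_true(all(offsets %% 300 == 0))
})
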