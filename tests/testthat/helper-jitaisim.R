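# Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small deployment: 4 participants, 2 weeks.
small_deployment <- function() {
  memo("small_deployment", {
    cfg <- default_config()
    cohort <- generate_participants(4, cfg, seed = 303)
    truth <- calibrate_truth_intercept(default_truth_models(cfg), cfg)
    log <- run_deployment(cohort, truth, weeks = 2, seed = 303, config = cfg)
    list(cfg = cfg, cohort = cohort, truth = truth, log = log,
         tables = build_model_tables(log))
  })
}

# The full study-sized pipeline: 43 participants, 4 weeks, all models.
full_report <- function() {
  memo("full_report", run_pipeline(seed = 1))
}

# Balanced 2x2 fixture: exposed 20 events / 10 non-events,
# unexposed 10 / 20; closed-form odds ratio ad/bc = 4.
two_by_two <- data.frame(
  y = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)),
  x = rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
)

# Independent direct-moment skewness oracle.
direct_g1 <- function(x) {
  m2 <- sum((x - mean(x))^2) / length(x)
  m3 <- sum((x - mean(x))^3) / length(x)
  m3 / m2^(3 / 2)
}

# Gating history where every rule passes.
clear_history <- function(day = "2023-01-02") {
  ws <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC")
  list(work_start = ws, work_end = ws + 8 * 3600,
       nudge_times_today = ws[0], last_nudge = NULL,
       last_completion = NULL, scheduled_pending = NULL)
}

high_stress <- function() {
  compute_stress_score(
    list(emails_received = 100, meetings_today = 20, fraction_of_day = 1,
         facial = 10, heart_rate = 200))
}

# One-participant toy event log with three nudges: engaged+completed,
# expired, and chosen-then-abandoned. Values chosen for hand computation.
toy_log <- function() {
  ts <- function(x) as.POSIXct(paste("2023-01-02", x), tz = "UTC")
  rows <- list(
    data.frame(timestamp = ts("09:00:00"), participant_id = "T01",
               event_type = "enrollment", age_group = "36-45",
               gender = "woman", cognitive_reappraisal = 4,
               expressive_suppression = 3, resilience = 3.5,
               agreeableness = 4, conscientiousness = 4, extraversion = 3,
               neuroticism = 2, openness = 3, engagement_tendency = 0,
               work_start = "09:00", work_end = "17:00",
               stringsAsFactors = FALSE),
    data.frame(timestamp = ts(c("10:00:00", "11:30:00", "14:00:00")),
               participant_id = "T01", event_type = "context_window",
               slot_start = ts(c("10:00:00", "11:30:00", "14:00:00")),
               meeting_counts = c(1, 0, 2), no_meeting_minutes = c(0, 30, 5),
               self_event_counts = c(0, 0, 1),
               email_messages_sent = c(0, 2, 1),
               email_messages_read = c(3, 0, 7),
               chat_messages_count = c(5, 0, 2),
               ad_hoc_call_count = c(0, 0, 1),
               attention_raw = c(2800, 1000, 400),
               stringsAsFactors = FALSE),
    data.frame(timestamp = ts(c("10:14:59", "11:59:00", "14:20:00")),
               participant_id = "T01", event_type = "nudge_sent",
               nudge_id = c("T01_n1", "T01_n2", "T01_n3"),
               source = c("JIT", "JIT", "rescheduled"),
               value = c(2, NA, 3), stringsAsFactors = FALSE),
    # n1: full engagement with rating and both stress reports
    data.frame(timestamp = ts(c("10:17:00", "10:18:00", "10:19:00",
                                "10:24:00", "10:25:00", "10:26:00")),
               participant_id = "T01",
               event_type = c("category_chosen", "pre_stress",
                              "intervention_started", "intervention_done",
                              "intervention_rated", "post_stress"),
               nudge_id = "T01_n1",
               value = c(NA, 3, NA, NA, 4, 2),
               category = c("calm", NA, "calm", NA, NA, NA),
               modality = c("prompt", NA, "prompt", NA, NA, NA),
               location = c("at_desk", NA, "at_desk", NA, NA, NA),
               intervention_id = c("calm_01", NA, "calm_01", NA, NA, NA),
               stringsAsFactors = FALSE),
    # n2: expired
    data.frame(timestamp = ts("12:29:00"), participant_id = "T01",
               event_type = "nudge_expired", nudge_id = "T01_n2",
               stringsAsFactors = FALSE),
    # n3: category chosen, then abandoned
    data.frame(timestamp = ts(c("14:22:00", "14:25:00")),
               participant_id = "T01",
               event_type = c("category_chosen", "flow_abandoned"),
               nudge_id = "T01_n3",
               category = c("distract", NA), modality = c("video", NA),
               location = c("inside", NA),
               intervention_id = c("distract_02", NA),
               stringsAsFactors = FALSE)
  )
  log <- do.call(rbind, lapply(rows, jitaisim:::conform_events))
  log <- log[order(log$timestamp), ]
  class(log) <- c("jitai_event_log", "data.frame")
  log
}
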