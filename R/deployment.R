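event_columns <- function() {
  list(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    participant_id = character(), event_type = character(),
    value = numeric(), nudge_id = character(), source = character(),
    category = character(), modality = character(), location = character(),
    intervention_id = character(),
    until = as.POSIXct(character(), tz = "UTC"),
    slot_start = as.POSIXct(character(), tz = "UTC"),
    meeting_counts = numeric(), no_meeting_minutes = numeric(),
    self_event_counts = numeric(), email_messages_sent = numeric(),
    email_messages_read = numeric(), chat_messages_count = numeric(),
    ad_hoc_call_count = numeric(), attention_raw = numeric(),
    age_group = character(), gender = character(),
    cognitive_reappraisal = numeric(), expressive_suppression = numeric(),
    resilience = numeric(), agreeableness = numeric(),
    conscientiousness = numeric(), extraversion = numeric(),
    neuroticism = numeric(), openness = numeric(),
    engagement_tendency = numeric(),
    work_start = character(), work_end = character()
  )
}

conform_events <- function(df) {
  template <- event_columns()
  for (nm in names(template)) {
    if (is.null(df[[nm]])) {
      proto <- template[[nm]]
      df[[nm]] <- if (inherits(proto, "POSIXct")) {
        as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
      } else if (is.numeric(proto)) NA_real_ else NA_character_
    }
  }
  df[names(template)]
}

study_workdays <- function(start_date, weeks) {
  start <- as.Date(start_date)
  all_days <- seq(start, by = "1 day", length.out = weeks * 7)
  wd <- all_days[!format(all_days, "%u") %in% c("6", "7")]
  head(wd, weeks * 5)
}

#' Simulate a full study deployment and emit its event log
#'
#' Runs the nudge-gating engine over every participant workday of the
#' study: telemetry and sensed signals are generated per day, the composite
#' stress score is evaluated on the engine's five-minute tick, EMAs are
#' prompted at scheduled times, and nudges are sent whenever the gating
#' rules allow. Week-one scores and EMA answers feed the individualized
#' baselines used from week two on (the default midpoint baselines apply
#' during week one). Every behavioral outcome is drawn by
#' [simulate_response()] and driven through the engagement-flow state
#' machine, so the emitted log satisfies both the gating invariants and
#' the flow's transition rules by construction.
#'
#' @param cohort Output of [generate_participants()].
#' @param truth A `truth_models` object.
#' @param weeks Study length in weeks (at least 2: week one is the
#'   baseline-learning period).
#' @param seed Integer seed; combined with the per-participant substream
#'   seeds stored in the cohort.
#' @param config Simulation configuration.
#' @return A time-ordered data frame of class `jitai_event_log` with one
#'   event per row (enrollment, stress-score ticks, context windows, EMA
#'   prompts/responses, nudges, and flow transitions).
#' @export
run_deployment <- function(cohort, truth = default_truth_models(),
                           weeks = 4, seed = 1,
                           config = default_config()) {
  if (weeks < 2) {
    stop("weeks must be >= 2: week one is needed to learn baselines")
  }
  set.seed(seed)
  if (is.na(truth$improved_coefs[["intercept"]]) &&
      is.null(attr(truth, "improved_intercept"))) {
    truth <- calibrate_truth_intercept(truth, config)
  }
  catalog <- intervention_catalog()
  days <- study_workdays(config$cohort$start_date, weeks)
  rules <- config$engine$rules
  normalizers <- config$engine$normalizers
  ema_cfg <- config$ema
  freshness <- ema_cfg$freshness_min * 60

  all_events <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    profile <- cohort[i, , drop = FALSE]
    set.seed(profile$seed %% .Machine$integer.max)
    pid <- profile$participant_id
    ev <- list()

    enroll <- data.frame(timestamp = workday_bounds(profile, days[1])$start,
                         participant_id = pid, event_type = "enrollment",
                         stringsAsFactors = FALSE)
    for (nm in c("age_group", "gender", names(config$cohort$traits),
                 "engagement_tendency", "work_start", "work_end")) {
      enroll[[nm]] <- profile[[nm]]
    }
    ev[[length(ev) + 1]] <- conform_events(enroll)

    baseline <- learn_baseline()
    week1_scores <- numeric()
    week1_emas <- integer()
    served <- character()
    nudge_counter <- 0L

    for (d in seq_along(days)) {
      if (d == 6) baseline <- learn_baseline(week1_scores, week1_emas)
      wd <- workday_bounds(profile, days[d])
      ctx <- generate_context_day(profile, days[d], config)
      scores <- stress_score_series(ctx$sensed, normalizers)
      ticks <- ctx$sensed$timestamp
      win <- ctx$windows

      ema_times <- schedule_emas(wd$start, wd$end, ema_cfg$per_day,
                                 ema_cfg$min_spacing_min)
      answered <- runif(length(ema_times)) < ema_cfg$response_prob
      idx <- findInterval(as.numeric(ema_times), as.numeric(ticks))
      ema_vals <- 1L + rbinom(length(ema_times), 4,
                              clip01(0.4 * scores[pmax(1, idx)]))
      ema_vals[!answered] <- NA_integer_
      if (d <= 5) {
        week1_scores <- c(week1_scores, scores)
        week1_emas <- c(week1_emas, ema_vals[answered])
      }

      ev[[length(ev) + 1]] <- conform_events(data.frame(
        timestamp = ticks, participant_id = pid,
        event_type = "stress_score", value = scores,
        stringsAsFactors = FALSE))
      ev[[length(ev) + 1]] <- conform_events(cbind(
        data.frame(timestamp = win$slot_start, participant_id = pid,
                   event_type = "context_window", stringsAsFactors = FALSE),
        win[c("meeting_counts", "no_meeting_minutes", "self_event_counts",
              "email_messages_sent", "email_messages_read",
              "chat_messages_count", "ad_hoc_call_count", "attention_raw")],
        data.frame(slot_start = win$slot_start)))
      ema_df <- data.frame(timestamp = rep(ema_times, 2),
                           participant_id = pid,
                           event_type = rep(c("ema_prompt", "ema_response"),
                                            each = length(ema_times)),
                           value = c(rep(NA_real_, length(ema_times)),
                                     as.numeric(ema_vals)),
                           stringsAsFactors = FALSE)
      ema_df <- ema_df[!(ema_df$event_type == "ema_response" &
                           is.na(ema_df$value)), ]
      ev[[length(ev) + 1]] <- conform_events(ema_df)

      nudge_times <- as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC")
      last_nudge <- NULL
      last_completion <- NULL
      scheduled_pending <- NULL

      for (k in seq_along(ticks)) {
        t <- ticks[k]
        hist <- list(work_start = wd$start, work_end = wd$end,
                     nudge_times_today = nudge_times,
                     last_nudge = last_nudge,
                     last_completion = last_completion,
                     scheduled_pending = scheduled_pending)
        send_source <- NULL
        latest_ema <- NA
        if (!is.null(scheduled_pending) && t >= scheduled_pending) {
          hist$scheduled_pending <- NULL
          scheduled_pending <- NULL
          g <- gate_nudge(t, scores[k], NULL, baseline, hist, rules,
                          trigger_required = FALSE)
          if (g$send) send_source <- "rescheduled"
        } else {
          fresh <- which(answered & as.numeric(ema_times) <= as.numeric(t) &
                           as.numeric(t) - as.numeric(ema_times) <= freshness)
          latest_ema <- if (length(fresh)) ema_vals[max(fresh)] else NA
          g <- gate_nudge(t, scores[k],
                          if (is.na(latest_ema)) NULL else latest_ema,
                          baseline, hist, rules, trigger_required = TRUE)
          if (g$send) send_source <- "JIT"
        }
        if (is.null(send_source)) next

        nudge_counter <- nudge_counter + 1L
        nudge_id <- sprintf("%s_n%04d", pid, nudge_counter)
        nudge_times <- c(nudge_times, t)
        last_nudge <- t
        slot_idx <- findInterval(as.numeric(t), as.numeric(win$slot_start))
        record <- data.frame(
          age_group = profile$age_group, gender = profile$gender,
          stringsAsFactors = FALSE)
        for (nm in names(config$cohort$traits)) record[[nm]] <- profile[[nm]]
        record$engagement_skewness <- profile$engagement_tendency
        record$nudge_probability <- config$response$nudge_probability_covariate
        for (nm in c("meeting_counts", "no_meeting_minutes",
                     "self_event_counts", "email_messages_sent",
                     "email_messages_read", "ad_hoc_call_count")) {
          record[[nm]] <- win[[nm]][slot_idx]
        }
        record$attention_signals <- win$attention_raw[slot_idx] / 2000
        record$nudge_source <- send_source

        ev[[length(ev) + 1]] <- conform_events(data.frame(
          timestamp = t, participant_id = pid, event_type = "nudge_sent",
          value = as.numeric(latest_ema), nudge_id = nudge_id,
          source = send_source, stringsAsFactors = FALSE))

        resp <- simulate_response(record, profile, truth, served, catalog)
        served <- resp$served
        flow <- new_flow(nudge_id, send_source, t)

        if (resp$action == "postpone") {
          remaining <- as.numeric(difftime(wd$end, t, units = "secs"))
          if (remaining > 35 * 60) {
            until <- t + runif(1, 30 * 60, remaining - 60)
            flow <- step_flow(flow, "postpone", t + 60, until)
            scheduled_pending <- until
            ev[[length(ev) + 1]] <- conform_events(data.frame(
              timestamp = t + 60, participant_id = pid,
              event_type = "nudge_postponed", nudge_id = nudge_id,
              until = until, stringsAsFactors = FALSE))
          } else {
            resp$action <- "ignore"
          }
        }
        if (resp$action == "ignore") {
          t_exp <- t + config$engine$expiry_min * 60
          flow <- step_flow(flow, "timeout", t_exp)
          ev[[length(ev) + 1]] <- conform_events(data.frame(
            timestamp = t_exp, participant_id = pid,
            event_type = "nudge_expired", nudge_id = nudge_id,
            stringsAsFactors = FALSE))
        }
        if (resp$action == "choose_abandon") {
          flow <- step_flow(flow, "choose_category", t + 120, resp$category)
          flow <- step_flow(flow, "abandon", t + 300)
          ev[[length(ev) + 1]] <- conform_events(data.frame(
            timestamp = c(t + 120, t + 300), participant_id = pid,
            event_type = c("category_chosen", "flow_abandoned"),
            nudge_id = nudge_id, category = c(resp$category, NA),
            modality = c(resp$intervention$modality, NA),
            location = c(resp$intervention$location, NA),
            intervention_id = c(resp$intervention$intervention_id, NA),
            stringsAsFactors = FALSE))
        }
        if (resp$action == "engage") {
          t_cat <- t + 120; t_pre <- t + 180; t_start <- t + 240
          t_done <- t_start + runif(1, 2, 5) * 60
          flow <- step_flow(flow, "choose_category", t_cat, resp$category)
          flow <- step_flow(flow, "report_stress", t_pre, resp$stress_before)
          flow <- step_flow(flow, "start_intervention", t_start,
                            resp$intervention)
          flow <- step_flow(flow, "done", t_done)
          last_completion <- t_done
          ev[[length(ev) + 1]] <- conform_events(data.frame(
            timestamp = c(t_cat, t_pre, t_start, t_done),
            participant_id = pid,
            event_type = c("category_chosen", "pre_stress",
                           "intervention_started", "intervention_done"),
            value = c(NA, resp$stress_before, NA, NA),
            nudge_id = nudge_id,
            category = c(resp$category, NA, resp$intervention$category, NA),
            modality = c(resp$intervention$modality, NA,
                         resp$intervention$modality, NA),
            location = c(resp$intervention$location, NA,
                         resp$intervention$location, NA),
            intervention_id = c(resp$intervention$intervention_id, NA,
                                resp$intervention$intervention_id, NA),
            stringsAsFactors = FALSE))
          if (isTRUE(resp$completed)) {
            flow <- step_flow(flow, "rate", t_done + 60, resp$rating)
            flow <- step_flow(flow, "report_stress", t_done + 120,
                              resp$stress_after)
            ev[[length(ev) + 1]] <- conform_events(data.frame(
              timestamp = c(t_done + 60, t_done + 120),
              participant_id = pid,
              event_type = c("intervention_rated", "post_stress"),
              value = c(resp$rating, resp$stress_after),
              nudge_id = nudge_id, stringsAsFactors = FALSE))
          }
        }
      }
    }
    all_events[[i]] <- do.call(rbind, ev)
  }
  log <- do.call(rbind, all_events)
  log <- log[order(log$timestamp, log$participant_id), ]
  rownames(log) <- NULL
  class(log) <- c("jitai_event_log", "data.frame")
  log
}

#' Replay an event log through the gating engine
#'
#' Reconstructs, for every participant and heuristic tick in the log, the
#' scheduling history visible to the engine at that tick (nudges, pending
#' rescheduled times, completions, fresh EMAs, the learned baselines) and
#' re-evaluates [gate_nudge()]. Serves as an independent check that every
#' logged nudge -- and no unlogged one -- passes the gating rules.
#'
#' @param log A `jitai_event_log`.
#' @param config The configuration the log was generated under.
#' @return Data frame with one row per tick: `participant_id`, `timestamp`,
#'   `sent_logged`, `sent_replayed`.
#' @export
replay_gating <- function(log, config = default_config()) {
  rules <- config$engine$rules
  freshness <- config$ema$freshness_min * 60
  out <- list()
  for (pid in unique(log$participant_id)) {
    pl <- log[log$participant_id == pid, ]
    enroll <- pl[pl$event_type == "enrollment", ][1, ]
    ticks_all <- pl[pl$event_type == "stress_score", ]
    emas <- pl[pl$event_type == "ema_response", ]
    nudges <- pl[pl$event_type == "nudge_sent", ]
    postponed <- pl[pl$event_type == "nudge_postponed", ]
    dones <- pl[pl$event_type == "intervention_done", ]

    dates <- sort(unique(as.Date(ticks_all$timestamp)))
    week1 <- dates[seq_len(min(5, length(dates)))]
    in_w1 <- as.Date(ticks_all$timestamp) %in% week1
    baseline_w1 <- learn_baseline()
    baseline_rest <- learn_baseline(
      ticks_all$value[in_w1],
      emas$value[as.Date(emas$timestamp) %in% week1])

    for (d in dates) {
      day <- as.Date(d, origin = "1970-01-01")
      baseline <- if (day %in% week1) baseline_w1 else baseline_rest
      wd <- workday_bounds(enroll, day)
      day_sel <- as.Date(ticks_all$timestamp) == day
      ticks <- ticks_all$timestamp[day_sel]
      scores <- ticks_all$value[day_sel]
      day_emas <- emas[as.Date(emas$timestamp) == day, ]
      day_nudges <- nudges[as.Date(nudges$timestamp) == day, ]
      day_post <- postponed[as.Date(postponed$timestamp) == day, ]
      day_done <- dones[as.Date(dones$timestamp) == day, ]

      pending <- NULL
      decisions <- data.frame(
        participant_id = pid, timestamp = ticks,
        sent_logged = FALSE, sent_replayed = FALSE)
      for (k in seq_along(ticks)) {
        t <- ticks[k]
        prior_nudges <- day_nudges$timestamp[day_nudges$timestamp < t]
        prior_done <- day_done$timestamp[day_done$timestamp < t]
        # pending rescheduled time as of t
        pend_rows <- day_post[day_post$timestamp < t, ]
        pending <- NULL
        if (nrow(pend_rows)) {
          last_until <- pend_rows$until[which.max(pend_rows$timestamp)]
          if (last_until > t) {
            pending <- last_until
          } else {
            # pending consumed at first tick >= until before t
            consumed <- any(ticks >= last_until & ticks < t)
            if (!consumed) pending <- last_until
          }
        }
        hist <- list(
          work_start = wd$start, work_end = wd$end,
          nudge_times_today = prior_nudges,
          last_nudge = if (length(prior_nudges)) max(prior_nudges) else NULL,
          last_completion = if (length(prior_done)) max(prior_done) else NULL,
          scheduled_pending = pending)
        due <- !is.null(pending) && t >= pending
        if (due) {
          hist$scheduled_pending <- NULL
          g <- gate_nudge(t, scores[k], NULL, baseline, hist, rules,
                          trigger_required = FALSE)
        } else {
          fresh <- day_emas[day_emas$timestamp <= t &
                              as.numeric(t) - as.numeric(day_emas$timestamp) <=
                                freshness, ]
          le <- if (nrow(fresh)) fresh$value[which.max(fresh$timestamp)]
                else NULL
          g <- gate_nudge(t, scores[k], le, baseline, hist, rules,
                          trigger_required = TRUE)
        }
        decisions$sent_replayed[k] <- g$send
        decisions$sent_logged[k] <- any(day_nudges$timestamp == t)
      }
      out[[length(out) + 1]] <- decisions
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
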