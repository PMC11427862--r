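rnb <- function(n, mu, size) {
  if (mu <= 0) return(integer(n))
  rnbinom(n, mu = mu, size = size)
}

#' Generate one workday of telemetry and sensed signals
#'
#' Produces (a) one context window per half hour of the workday with the
#' telemetry aggregates the analysis consumes (meeting counts, no-meeting
#' minutes, self-event counts, emails sent/read, chats, ad hoc calls, and
#' attention signals capped at the configured maximum), and (b) a sensed
#' sample per heuristic tick carrying the five raw stress-score inputs:
#' the running count of emails received, the day's total meetings, the
#' fraction of the workday elapsed, a facial-expression score, and an
#' autocorrelated positive heart-rate series.
#'
#' Uses the current RNG stream; callers control reproducibility with
#' `set.seed()`.
#'
#' @param profile One row of [generate_participants()] output.
#' @param date Date of the workday.
#' @param config Simulation configuration.
#' @return List with data frames `windows` (one row per half-hour slot) and
#'   `sensed` (one row per tick).
#' @export
generate_context_day <- function(profile, date, config = default_config()) {
  wd <- workday_bounds(profile, date)
  slot_starts <- seq(wd$start, wd$end - 1, by = 30 * 60)
  n_slots <- length(slot_starts)
  ctx <- config$context

  meeting_counts <- rpois(n_slots, ctx$meeting_rate)
  busy <- runif(n_slots) >= ctx$no_meeting$p_zero
  no_meeting_minutes <- ifelse(
    busy,
    pmin(ctx$no_meeting$cap, round(rexp(n_slots, 1 / ctx$no_meeting$mean_when_busy))),
    0)
  windows <- data.frame(
    slot_start = slot_starts,
    meeting_counts = meeting_counts,
    no_meeting_minutes = no_meeting_minutes,
    self_event_counts = rpois(n_slots, ctx$self_event_rate),
    email_messages_sent = rnb(n_slots, ctx$email_sent$mu, ctx$email_sent$size),
    email_messages_read = rnb(n_slots, ctx$email_read$mu, ctx$email_read$size),
    chat_messages_count = rnb(n_slots, ctx$chat$mu, ctx$chat$size),
    ad_hoc_call_count = rpois(n_slots, ctx$ad_hoc_call_rate),
    attention_raw = pmin(ctx$attention$cap,
                         rnb(n_slots, ctx$attention$mu, ctx$attention$size))
  )

  tick_sec <- config$engine$tick_min * 60
  ticks <- seq(wd$start, wd$end - 1, by = tick_sec)
  n_ticks <- length(ticks)
  day_len <- as.numeric(difftime(wd$end, wd$start, units = "secs"))

  arrivals <- rpois(n_ticks, config$sensed$emails_received_per_day / n_ticks)
  hr_par <- config$sensed$heart_rate
  innov <- rnorm(n_ticks, 0, hr_par$sd)
  hr <- hr_par$mean +
    as.numeric(stats::filter(innov, hr_par$ar, method = "recursive"))
  sensed <- data.frame(
    timestamp = ticks,
    emails_received = cumsum(arrivals),
    meetings_today = sum(meeting_counts),
    fraction_of_day = as.numeric(difftime(ticks, wd$start, units = "secs")) /
      day_len,
    facial = rnorm(n_ticks, 0, config$sensed$facial$sd),
    heart_rate = pmax(40, hr)
  )
  list(windows = windows, sensed = sensed)
}
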