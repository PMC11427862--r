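#' Nudge-gating rule parameters
#'
#' The deployed heuristic evaluated, every five minutes, whether to send a
#' nudge. A nudge goes out only if all of the following hold, checked in
#' this order:
#' \enumerate{
#'   \item the current time is within the participant's stated working hours;
#'   \item no user-scheduled (postponed) intervention is pending later today;
#'   \item no intervention was completed in the past 60 minutes;
#'   \item no nudge was sent in the past 120 minutes;
#'   \item fewer than 4 nudges have been sent today;
#'   \item the stress trigger fires: composite score above its baseline
#'     threshold, or the latest fresh EMA above its baseline threshold.
#' }
#'
#' @param daily_cap Maximum nudges per participant per day.
#' @param nudge_cooldown_min Minutes that must elapse since the previous
#'   nudge.
#' @param completion_cooldown_min Minutes that must elapse since the last
#'   completed intervention.
#' @param trigger One of `"and"`, `"or"`, `"score_only"`: how the score and
#'   EMA thresholds combine into the stress trigger. The default `"and"`
#'   requires both a high computed score and a fresh high self-report,
#'   which concentrates nudges shortly after EMAs.
#' @param honor_user_schedule When `TRUE` (default), a nudge fired at a
#'   user-chosen rescheduled time is exempt from the completion and nudge
#'   cooldowns (the user explicitly asked for that time); it still respects
#'   working hours and counts toward the daily cap.
#' @return List of gating parameters.
#' @export
gating_rules <- function(daily_cap = 4, nudge_cooldown_min = 120,
                         completion_cooldown_min = 60,
                         trigger = c("and", "or", "score_only"),
                         honor_user_schedule = TRUE) {
  trigger <- match.arg(trigger)
  list(daily_cap = daily_cap,
       nudge_cooldown_min = nudge_cooldown_min,
       completion_cooldown_min = completion_cooldown_min,
       trigger = trigger,
       honor_user_schedule = honor_user_schedule)
}

#' Decide whether a nudge may be sent now
#'
#' Applies the gating rules in their fixed order and returns either a send
#' decision or the first failing rule as the blocking reason (one of
#' `outside_working_hours`, `scheduled_pending`, `completion_cooldown`,
#' `nudge_cooldown`, `daily_cap`, `no_trigger`).
#'
#' @param now POSIXct evaluation time.
#' @param stress A `stress_score` object (or a bare numeric score) at `now`,
#'   or `NULL` when unavailable.
#' @param latest_ema Latest fresh EMA stress rating (1-5), or `NULL` when
#'   none applies.
#' @param baseline A `jitai_baseline` object.
#' @param history List describing the participant's scheduling state:
#'   `work_start`/`work_end` (POSIXct bounds of today's workday, compared
#'   half-open `[start, end)`), `nudge_times_today` (sorted POSIXct vector),
#'   `last_nudge`, `last_completion`, `scheduled_pending` (each POSIXct or
#'   `NULL`).
#' @param rules Output of [gating_rules()].
#' @param trigger_required Set `FALSE` for nudges fired at a user-chosen
#'   rescheduled time, which bypass the stress trigger but still respect
#'   working hours, cooldowns and the daily cap.
#' @return List with `send` (logical) and `reason` (`NA` when sending).
#' @export
gate_nudge <- function(now, stress = NULL, latest_ema = NULL, baseline,
                       history, rules = gating_rules(),
                       trigger_required = TRUE) {
  nt <- history$nudge_times_today
  if (!is.null(nt) && length(nt) > 1 && is.unsorted(as.numeric(nt))) {
    stop("nudge_times_today must be time-ordered")
  }
  block <- function(reason) list(send = FALSE, reason = reason)

  user_scheduled <- !trigger_required &&
    isTRUE(rules$honor_user_schedule)

  if (now < history$work_start || now >= history$work_end) {
    return(block("outside_working_hours"))
  }
  if (!is.null(history$scheduled_pending) &&
      history$scheduled_pending > now) {
    return(block("scheduled_pending"))
  }
  if (!user_scheduled && !is.null(history$last_completion) &&
      difftime(now, history$last_completion, units = "mins") <
        rules$completion_cooldown_min) {
    return(block("completion_cooldown"))
  }
  if (!user_scheduled && !is.null(history$last_nudge) &&
      difftime(now, history$last_nudge, units = "mins") <
        rules$nudge_cooldown_min) {
    return(block("nudge_cooldown"))
  }
  if (length(nt) >= rules$daily_cap) {
    return(block("daily_cap"))
  }
  if (trigger_required) {
    score_val <- if (inherits(stress, "stress_score")) stress$value
                 else if (is.null(stress)) NULL else as.numeric(stress)
    score_hit <- !is.null(score_val) &&
      score_val > baseline$score_threshold
    ema_hit <- !is.null(latest_ema) &&
      latest_ema > baseline$ema_threshold
    fired <- switch(rules$trigger,
      or = score_hit || ema_hit,
      and = score_hit && ema_hit,
      score_only = score_hit)
    if (!fired) return(block("no_trigger"))
  }
  list(send = TRUE, reason = NA_character_)
}

#' Draw EMA prompt times over a workday
#'
#' Schedules the daily self-report prompts (five by default) uniformly at
#' random within the participant's working hours, subject to a minimum
#' spacing. Times are strictly increasing and lie in `[work_start,
#' work_end)`.
#'
#' @param work_start,work_end POSIXct workday bounds.
#' @param n Number of EMA prompts per day.
#' @param min_spacing_min Minimum spacing between prompts, minutes.
#' @return POSIXct vector of length `n`.
#' @export
schedule_emas <- function(work_start, work_end, n = 5,
                          min_spacing_min = 30) {
  len_min <- as.numeric(difftime(work_end, work_start, units = "mins"))
  if (len_min < n * min_spacing_min) {
    stop(sprintf(
      "workday of %.0f min cannot hold %d EMAs at %.0f-min spacing",
      len_min, n, min_spacing_min))
  }
  # Uniform placement with a hard minimum gap: shrink the day by the total
  # spacing, drop n sorted uniforms in, then re-insert the gaps.
  slack <- len_min - (n - 1) * min_spacing_min
  u <- sort(runif(n, 0, slack))
  offsets <- u + (seq_len(n) - 1) * min_spacing_min
  offsets <- pmin(offsets, len_min - 1e-6)
  work_start + offsets * 60
}
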