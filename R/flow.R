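#' Create a fresh engagement flow for one nudge
#'
#' The engagement flow tracks a user's interaction with a single nudge:
#' the system sends a nudge; the user may postpone it to a later time the
#' same day, ignore it (the nudge expires after 30 minutes of inactivity),
#' or engage by choosing one of three intervention categories, reporting
#' their current stress, performing the intervention, marking it done, and
#' optionally rating it and reporting their stress again. A flow counts as
#' *engaged* as soon as `done` is reached, regardless of whether the rating
#' or post-stress report follow.
#'
#' @param nudge_id Identifier of the nudge that opened this flow.
#' @param source `"JIT"` for algorithm-triggered nudges, `"rescheduled"` for
#'   nudges fired at a user-postponed time.
#' @param now POSIXct time the nudge was sent.
#' @return Object of class `flow_state`.
#' @export
new_flow <- function(nudge_id, source = c("JIT", "rescheduled"), now) {
  source <- match.arg(source)
  structure(list(
    state = "nudged",
    nudge_id = nudge_id,
    nudge_source = source,
    last_activity = now,
    postponed_until = NULL,
    category = NULL,
    intervention = NULL,
    stress_before = NULL,
    stress_after = NULL,
    rating = NULL,
    timestamps = list(nudged = now)
  ), class = "flow_state")
}

flow_expiry_min <- 30

# Legal (state, event) -> next state transitions of the engagement flow.
flow_transitions <- list(
  nudged = c(postpone = "postponed", choose_category = "category_chosen",
             timeout = "expired"),
  category_chosen = c(report_stress = "pre_stress_reported",
                      abandon = "abandoned"),
  pre_stress_reported = c(start_intervention = "intervention_active",
                          abandon = "abandoned"),
  intervention_active = c(done = "done", abandon = "abandoned"),
  done = c(rate = "rated"),
  rated = c(report_stress = "post_stress_reported")
)

#' Advance an engagement flow by one event
#'
#' @param flow A `flow_state`.
#' @param event Event type: one of `"postpone"`, `"choose_category"`,
#'   `"timeout"`, `"report_stress"`, `"start_intervention"`, `"done"`,
#'   `"rate"`, `"abandon"`.
#' @param now POSIXct time of the event.
#' @param value Event payload: the postpone-until time, category, stress
#'   rating (1-5), intervention record, or intervention rating (1-5).
#' @return The updated `flow_state`.
#' @export
step_flow <- function(flow, event, now, value = NULL) {
  stopifnot(inherits(flow, "flow_state"))
  legal <- flow_transitions[[flow$state]]
  if (is.null(legal) || !event %in% names(legal)) {
    stop(sprintf("illegal flow transition: state '%s' does not accept event '%s'",
                 flow$state, event))
  }
  if (event == "timeout") {
    if (difftime(now, flow$last_activity, units = "mins") < flow_expiry_min) {
      stop(sprintf("timeout before %d minutes of inactivity", flow_expiry_min))
    }
  }
  new_state <- unname(legal[[event]])
  if (event == "postpone") {
    if (is.null(value) || value <= now) {
      stop("postpone requires a future time the same day")
    }
    flow$postponed_until <- value
  } else if (event == "choose_category") {
    if (!value %in% c("distract", "calm", "address")) {
      stop("unknown intervention category: ", value)
    }
    flow$category <- value
  } else if (event == "report_stress") {
    check_rating(value, "stress rating")
    if (flow$state == "category_chosen") flow$stress_before <- as.integer(value)
    else flow$stress_after <- as.integer(value)
  } else if (event == "start_intervention") {
    flow$intervention <- value
  } else if (event == "rate") {
    check_rating(value, "intervention rating")
    flow$rating <- as.integer(value)
  }
  flow$state <- new_state
  if (event != "timeout") flow$last_activity <- now
  flow$timestamps[[new_state]] <- now
  flow
}

check_rating <- function(value, what) {
  if (is.null(value) || is.na(value) || value < 1 || value > 5) {
    stop(what, " must lie on the 1-5 scale")
  }
  invisible(TRUE)
}

#' Has this flow been engaged?
#'
#' Engaged means the user explicitly marked the intervention done, whether
#' or not the subsequent rating/post-stress prompts were completed.
#'
#' @param flow A `flow_state`.
#' @return Logical.
#' @export
flow_engaged <- function(flow) {
  !is.null(flow$timestamps[["done"]])
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("Engagement flow %s [%s nudge]: %s\n",
              x$nudge_id, x$nudge_source, x$state))
  invisible(x)
}
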