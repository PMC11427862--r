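#' Floor a timestamp to its half-hour telemetry slot
#'
#' Telemetry aggregates arrive in half-hour windows; a nudge is associated
#' with the window holding its timestamp, i.e. the largest :00/:30 boundary
#' not after it (half-open interval convention).
#'
#' @param ts POSIXct vector.
#' @return POSIXct vector of slot starts.
#' @export
assign_half_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 1800) * 1800,
             origin = "1970-01-01", tz = "UTC")
}

#' Fisher-Pearson coefficient of skewness of engagement hours
#'
#' Computed on the hour-of-day values of a participant's engaged
#' interventions: `g1 = m3 / m2^(3/2)` with `m2`, `m3` the second and third
#' central sample moments. Positive values mean engagement concentrated
#' early in the workday, negative values late. Fewer than three values, or
#' zero variance, yield 0 (with a warning) so that every participant
#' remains usable as a covariate row.
#'
#' @param engagement_hours Numeric vector of (fractional) hour-of-day
#'   values.
#' @return The skewness coefficient `g1`.
#' @export
engagement_skewness <- function(engagement_hours) {
  x <- engagement_hours[!is.na(engagement_hours)]
  n <- length(x)
  if (n < 3) {
    warning("fewer than 3 engagement hours; skewness set to 0")
    return(0)
  }
  m2 <- mean((x - mean(x))^2)
  if (m2 <= .Machine$double.eps) {
    warning("zero variance in engagement hours; skewness set to 0")
    return(0)
  }
  m3 <- mean((x - mean(x))^3)
  m3 / m2^1.5
}

#' Per-slot nudge probability, in percent
#'
#' The share of a participant's nudges that fall in a given half-hour-of-day
#' slot, multiplied by 100. Over a participant's observed slots the values
#' sum to 100.
#'
#' @param all_nudge_slots Character/numeric vector identifying the slot of
#'   day of each of the participant's nudges (e.g. `"10:30"`).
#' @param query_slot The slot to evaluate.
#' @return Percentage in \[0, 100\].
#' @export
nudge_probability <- function(all_nudge_slots, query_slot) {
  if (length(all_nudge_slots) == 0) {
    stop("nudge probability undefined: participant has no nudges")
  }
  100 * sum(all_nudge_slots == query_slot) / length(all_nudge_slots)
}

#' Derive the outcome labels of one completed (or partial) engagement flow
#'
#' `engaged` is true iff the flow reached `done`; `liked` is true iff the
#' intervention was rated good or very good (rating >= 4 on 1-5);
#' `improved` is true iff the post-intervention stress rating is strictly
#' below the pre-intervention one; `stress_reduction` is pre minus post.
#' Fields further down the flow than the participant went are `NA`, not
#' `FALSE`.
#'
#' @param flow A `flow_state`, or a list with elements `timestamps`,
#'   `rating`, `stress_before`, `stress_after` in the same shape.
#' @return List with `engaged`, `liked`, `improved`, `stress_reduction`,
#'   `rating`, `stress_before`, `stress_after`.
#' @export
label_outcomes <- function(flow) {
  rating <- flow$rating
  if (!is.null(rating) && !is.na(rating) && (rating < 1 || rating > 5)) {
    stop("intervention rating must lie on the 1-5 scale")
  }
  engaged <- !is.null(flow$timestamps[["done"]])
  liked <- if (is.null(rating) || is.na(rating)) NA else rating >= 4
  pre <- flow$stress_before
  post <- flow$stress_after
  has_both <- !is.null(pre) && !is.null(post) && !is.na(pre) && !is.na(post)
  list(
    engaged = engaged,
    liked = liked,
    improved = if (has_both) post < pre else NA,
    stress_reduction = if (has_both) pre - post else NA_integer_,
    rating = if (is.null(rating)) NA_integer_ else rating,
    stress_before = if (is.null(pre)) NA_integer_ else pre,
    stress_after = if (is.null(post)) NA_integer_ else post
  )
}

slot_of_day <- function(ts) format(assign_half_hour(ts), "%H:%M")

#' Reconstruct the three analysis tables from an event log
#'
#' Builds, from a deployment event log, (1) the per-nudge table (one row
#' per system-initiated nudge, with participant traits, the engagement
#' skewness and per-slot nudge probability derived from the log itself,
#' the half-hour telemetry context holding the nudge, and the engagement
#' label), (2) the chosen-intervention table (the subset where a category
#' was selected, with intervention attributes), and (3) the
#' completed-intervention table (the subset with both stress reports, plus
#' rating/liked/improved/stress-reduction labels). Attention signals are
#' divided by 2000; nudge probability is in percent.
#'
#' @param log A `jitai_event_log`.
#' @return List of class `jitai_tables` with data frames `per_nudge`,
#'   `chosen`, `completed`.
#' @export
build_model_tables <- function(log) {
  nudges <- log[log$event_type == "nudge_sent", ]
  flow_types <- c("category_chosen", "pre_stress", "intervention_started",
                  "intervention_done", "intervention_rated", "post_stress",
                  "nudge_postponed", "nudge_expired", "flow_abandoned")
  flows <- log[log$event_type %in% flow_types, ]
  orphans <- setdiff(flows$nudge_id, nudges$nudge_id)
  if (length(orphans)) {
    stop("flow events without a matching nudge: ",
         paste(unique(orphans), collapse = ", "))
  }

  enroll <- log[log$event_type == "enrollment", ]
  windows <- log[log$event_type == "context_window", ]
  trait_cols <- c("age_group", "gender", "cognitive_reappraisal",
                  "expressive_suppression", "resilience", "agreeableness",
                  "conscientiousness", "extraversion", "neuroticism",
                  "openness")

  per <- data.frame(
    participant_id = nudges$participant_id,
    nudge_id = nudges$nudge_id,
    timestamp = nudges$timestamp,
    nudge_source = nudges$source,
    stress_at_nudge = nudges$value,
    stringsAsFactors = FALSE)

  ei <- match(per$participant_id, enroll$participant_id)
  for (nm in trait_cols) per[[nm]] <- enroll[[nm]][ei]

  # context join on (participant, half-hour slot)
  per_key <- paste(per$participant_id, assign_half_hour(per$timestamp))
  win_key <- paste(windows$participant_id, windows$slot_start)
  wi <- match(per_key, win_key)
  for (nm in c("meeting_counts", "no_meeting_minutes", "self_event_counts",
               "email_messages_sent", "email_messages_read",
               "chat_messages_count", "ad_hoc_call_count")) {
    per[[nm]] <- windows[[nm]][wi]
  }
  per$attention_signals <- windows$attention_raw[wi] / 2000

  # engagement label and flow payloads per nudge
  pick <- function(type, col = "value") {
    sub <- flows[flows$event_type == type, ]
    sub[[col]][match(per$nudge_id, sub$nudge_id)]
  }
  done_t <- pick("intervention_done", "timestamp")
  per$engaged <- !is.na(done_t)
  category <- pick("category_chosen", "category")
  modality <- pick("category_chosen", "modality")
  location <- pick("category_chosen", "location")
  stress_before <- pick("pre_stress")
  stress_after <- pick("post_stress")
  rating <- pick("intervention_rated")

  # per-participant features derived from the log itself
  per$engagement_skewness <- NA_real_
  per$nudge_probability <- NA_real_
  slot <- slot_of_day(per$timestamp)
  for (pid in unique(per$participant_id)) {
    sel <- per$participant_id == pid
    hours <- as.numeric(format(done_t[sel & per$engaged], "%H")) +
      as.numeric(format(done_t[sel & per$engaged], "%M")) / 60
    per$engagement_skewness[sel] <-
      suppressWarnings(engagement_skewness(hours))
    slots <- slot[sel]
    per$nudge_probability[sel] <- vapply(
      slots, function(s) nudge_probability(slots, s), numeric(1))
  }

  chosen <- per[!is.na(category), , drop = FALSE]
  chosen$category <- category[!is.na(category)]
  chosen$modality <- modality[!is.na(category)]
  chosen$location <- location[!is.na(category)]
  chosen$distract_chosen <- chosen$category == "distract"
  chosen$calm_chosen <- chosen$category == "calm"
  chosen$address_chosen <- chosen$category == "address"

  comp_sel <- !is.na(category) & !is.na(stress_before) & !is.na(stress_after)
  completed <- per[comp_sel, , drop = FALSE]
  completed$category <- category[comp_sel]
  completed$modality <- modality[comp_sel]
  completed$location <- location[comp_sel]
  completed$stress_before <- stress_before[comp_sel]
  completed$stress_after <- stress_after[comp_sel]
  completed$stress_reduction <- completed$stress_before -
    completed$stress_after
  completed$rating <- rating[comp_sel]
  completed$liked <- !is.na(completed$rating) & completed$rating >= 4
  completed$improved <- completed$stress_after < completed$stress_before

  structure(list(per_nudge = per, chosen = chosen, completed = completed),
            class = "jitai_tables")
}

#' Write the analysis tables as CSV files
#'
#' @param tables A `jitai_tables` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (!is.null(df$timestamp)) {
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
    }
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
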