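#' Ground-truth behavioral models for the simulator
#'
#' The simulator draws every behavioral outcome (engaging with a nudge,
#' which category is chosen, engagement after a choice, stress improvement)
#' from logistic models whose coefficients default to the natural logs of
#' the odds ratios estimated on the real deployment. Coefficients are named
#' after the encoded feature columns produced by [encode_features()]. The
#' improvement model's intercept corresponds to an odds ratio far below
#' printable precision; it is calibrated numerically at simulation time so
#' that the marginal improvement rate matches the deployment's observed
#' rate (see [calibrate_intercept()]), and is stored as `NA` here.
#'
#' @return Object of class `truth_models`: named coefficient vectors
#'   `engagement_coefs`, `choice_coefs` (list of three), `engaged_after_chosen_coefs`,
#'   `liked_coefs`, `improved_coefs`, plus behavioral rates copied from the
#'   configuration.
#' @param config Simulation configuration, see [default_config()].
#' @export
default_truth_models <- function(config = default_config()) {
  base2 <- c(
    intercept = 0.1,
    age_36_45 = 1.17, age_gt46 = 1.47,
    gender_woman = 1.37,
    cognitive_reappraisal = 1.14, expressive_suppression = 0.92,
    resilience = 1.05, agreeableness = 0.87, conscientiousness = 1.13,
    extraversion = 1.03, neuroticism = 0.97, openness = 1.15,
    engagement_skewness = 0.64, nudge_probability = 1.02,
    meeting_counts = 0.62, no_meeting_minutes = 1.00,
    self_event_counts = 1.15, email_messages_sent = 1.05,
    email_messages_read = 1.01, ad_hoc_call_count = 0.89,
    attention_signals = 1.39, source_rescheduled = 1.77
  )
  distract <- c(
    intercept = 0.11, age_36_45 = 1.65, age_gt46 = 0.71,
    gender_woman = 0.62, cognitive_reappraisal = 1.01,
    expressive_suppression = 0.99, resilience = 0.93,
    agreeableness = 0.75, conscientiousness = 1.30, extraversion = 1.18,
    neuroticism = 0.88, openness = 1.67, engagement_skewness = 1.12,
    nudge_probability = 1.00, meeting_counts = 0.84,
    no_meeting_minutes = 1.00, self_event_counts = 1.08,
    email_messages_sent = 1.05, email_messages_read = 1.03,
    ad_hoc_call_count = 0.88, attention_signals = 0.65,
    source_rescheduled = 1.01
  )
  calm <- c(
    intercept = 1.84, age_36_45 = 0.62, age_gt46 = 0.95,
    gender_woman = 1.31, cognitive_reappraisal = 1.27,
    expressive_suppression = 1.06, resilience = 0.87,
    agreeableness = 1.02, conscientiousness = 0.92, extraversion = 1.00,
    neuroticism = 1.00, openness = 0.71, engagement_skewness = 1.11,
    nudge_probability = 1.01, meeting_counts = 1.07,
    no_meeting_minutes = 1.00, self_event_counts = 0.83,
    email_messages_sent = 1.00, email_messages_read = 0.99,
    ad_hoc_call_count = 0.93, attention_signals = 1.18,
    source_rescheduled = 0.76
  )
  address <- c(
    intercept = 0.44, age_36_45 = 0.88, age_gt46 = 1.60,
    gender_woman = 1.29, cognitive_reappraisal = 0.67,
    expressive_suppression = 0.95, resilience = 1.42,
    agreeableness = 1.46, conscientiousness = 0.74, extraversion = 0.79,
    neuroticism = 1.36, openness = 0.83, engagement_skewness = 0.86,
    nudge_probability = 0.97, meeting_counts = 1.14,
    no_meeting_minutes = 1.00, self_event_counts = 1.19,
    email_messages_sent = 0.99, email_messages_read = 0.96,
    ad_hoc_call_count = 1.26, attention_signals = 1.33,
    source_rescheduled = 1.39
  )
  after_chosen <- c(
    intercept = 0.05, age_36_45 = 1.06, age_gt46 = 1.65,
    gender_woman = 1.65, cognitive_reappraisal = 1.11,
    expressive_suppression = 1.25, resilience = 1.63,
    agreeableness = 1.24, conscientiousness = 0.81, extraversion = 0.72,
    neuroticism = 1.39, openness = 1.24, engagement_skewness = 1.01,
    nudge_probability = 1.01, meeting_counts = 0.65,
    no_meeting_minutes = 1.00, self_event_counts = 1.94,
    email_messages_sent = 1.16, email_messages_read = 0.97,
    ad_hoc_call_count = 0.54, attention_signals = 0.90,
    source_rescheduled = 1.79,
    category_calm = 1.14, category_address = 0.55,
    modality_prompt = 3.53, modality_video = 5.86,
    location_inside = 0.43, location_outside = 0.34
  )
  liked <- c(
    intercept = 5.95, age_36_45 = 0.51, age_gt46 = 1.01,
    gender_woman = 2.51, cognitive_reappraisal = 1.35,
    expressive_suppression = 0.82, resilience = 1.10,
    agreeableness = 0.72, conscientiousness = 0.80, extraversion = 1.46,
    neuroticism = 0.84, openness = 0.99, engagement_skewness = 0.73,
    nudge_probability = 0.94, meeting_counts = 0.93,
    no_meeting_minutes = 1.00, self_event_counts = 0.66,
    email_messages_sent = 1.01, email_messages_read = 1.00,
    ad_hoc_call_count = 0.66, attention_signals = 1.16,
    source_rescheduled = 0.78,
    category_calm = 0.80, category_address = 0.94,
    stress_reduction = 2.36,
    modality_prompt = 0.52, modality_video = 0.75,
    location_inside = 0.69, location_outside = 2.56
  )
  improved <- c(
    intercept = NA,  # calibrated at simulation time; see calibrate_intercept()
    age_36_45 = 0.58, age_gt46 = 0.98,
    gender_woman = 0.41, cognitive_reappraisal = 0.69,
    expressive_suppression = 1.01, resilience = 0.84,
    agreeableness = 1.73, conscientiousness = 1.27, extraversion = 0.89,
    neuroticism = 0.57, openness = 1.09, engagement_skewness = 1.18,
    nudge_probability = 1.09, meeting_counts = 0.85,
    no_meeting_minutes = 1.01, self_event_counts = 1.29,
    email_messages_sent = 1.04, email_messages_read = 0.96,
    ad_hoc_call_count = 0.94, attention_signals = 1.40,
    source_rescheduled = 1.08,
    category_calm = 0.43, category_address = 0.40,
    stress_before = 5.76, rating = 2.47,
    modality_prompt = 6.65, modality_video = 5.62,
    location_inside = 1.17, location_outside = 0.23
  )
  structure(list(
    engagement_coefs = log(base2),
    choice_coefs = list(distract = log(distract), calm = log(calm),
                        address = log(address)),
    engaged_after_chosen_coefs = log(after_chosen),
    liked_coefs = log(liked),
    improved_coefs = suppressWarnings(log(improved)),
    improved_target_rate = 150 / 521,
    postponement_prob = config$response$postponement_prob,
    abandon_after_choice_prob = config$response$abandon_after_choice_prob,
    post_report_prob = config$response$post_report_prob,
    rating_params = config$response$rating_probs,
    stress_before_probs = config$response$stress_before_probs,
    reduction_improved_probs = config$response$reduction_improved_probs,
    reduction_not_improved_probs = config$response$reduction_not_improved_probs
  ), class = "truth_models")
}

#' Encode analysis-table rows into the simulator's design columns
#'
#' Produces the numeric dummy/continuous columns that both the simulator's
#' linear predictors and the fitted models operate on: age-group and gender
#' indicators, the eight trait scores, engagement skewness, the nudge
#' probability (percent), the seven telemetry features with attention
#' signals divided by 2000, the rescheduled-trigger indicator, and -- when
#' present -- the intervention category/modality/location indicators,
#' pre-intervention stress, rating and stress reduction.
#'
#' @param df Data frame of per-nudge (or chosen/completed) records.
#' @return Numeric matrix with one named column per encoded feature.
#' @export
encode_features <- function(df) {
  n <- nrow(df)
  out <- list()
  if (!is.null(df$age_group)) {
    out$age_36_45 <- as.numeric(df$age_group == "36-45")
    out$age_gt46 <- as.numeric(df$age_group == ">46")
  }
  if (!is.null(df$gender)) out$gender_woman <- as.numeric(df$gender == "woman")
  for (nm in c("cognitive_reappraisal", "expressive_suppression", "resilience",
               "agreeableness", "conscientiousness", "extraversion",
               "neuroticism", "openness", "engagement_skewness",
               "nudge_probability", "meeting_counts", "no_meeting_minutes",
               "self_event_counts", "email_messages_sent",
               "email_messages_read", "ad_hoc_call_count")) {
    if (!is.null(df[[nm]])) out[[nm]] <- as.numeric(df[[nm]])
  }
  if (!is.null(df$attention_signals)) {
    out$attention_signals <- as.numeric(df$attention_signals)
  } else if (!is.null(df$attention_raw)) {
    out$attention_signals <- as.numeric(df$attention_raw) / 2000
  }
  if (!is.null(df$nudge_source)) {
    out$source_rescheduled <- as.numeric(df$nudge_source == "rescheduled")
  }
  if (!is.null(df$category)) {
    out$category_calm <- as.numeric(df$category == "calm")
    out$category_address <- as.numeric(df$category == "address")
  }
  if (!is.null(df$modality)) {
    out$modality_prompt <- as.numeric(df$modality == "prompt")
    out$modality_video <- as.numeric(df$modality == "video")
  }
  if (!is.null(df$location)) {
    out$location_inside <- as.numeric(df$location == "inside")
    out$location_outside <- as.numeric(df$location == "outside")
  }
  for (nm in c("stress_before", "rating", "stress_reduction")) {
    if (!is.null(df[[nm]])) out[[nm]] <- as.numeric(df[[nm]])
  }
  mat <- do.call(cbind, out)
  rownames(mat) <- NULL
  mat
}

#' Linear predictor of a truth-model coefficient map over encoded records
#'
#' @param coefs Named coefficient vector on the log-odds scale, including
#'   `intercept`; every non-intercept name must match a column of `features`.
#' @param features Encoded feature matrix from [encode_features()].
#' @return Numeric vector of linear predictors.
#' @export
truth_lp <- function(coefs, features) {
  terms <- setdiff(names(coefs), "intercept")
  missing <- setdiff(terms, colnames(features))
  if (length(missing)) {
    stop("covariate(s) named in truth model but absent from record: ",
         paste(missing, collapse = ", "))
  }
  drop(features[, terms, drop = FALSE] %*% coefs[terms]) + coefs[["intercept"]]
}

#' Calibrate a logistic intercept to a target marginal event rate
#'
#' Finds the intercept `a` such that `mean(plogis(a + lp0))` equals the
#' target rate, where `lp0` is the linear predictor without intercept.
#' Used for the stress-improvement model, whose published intercept odds
#' ratio is below printable precision.
#'
#' @param lp0 Linear predictors excluding the intercept.
#' @param target_rate Desired marginal event probability.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(lp0, target_rate) {
  stopifnot(target_rate > 0, target_rate < 1)
  uniroot(function(a) mean(plogis(a + lp0)) - target_rate,
          interval = c(-40, 40), tol = 1e-10)$root
}
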