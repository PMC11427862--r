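factor_levels <- list(
  age_group = c("18-35", "36-45", ">46"),
  gender = c("man", "woman"),
  nudge_source = c("JIT", "rescheduled"),
  category = c("distract", "calm", "address"),
  modality = c("conversation", "prompt", "video"),
  location = c("at_desk", "inside", "outside")
)

base_predictors <- c(
  "age_group", "gender", "cognitive_reappraisal", "expressive_suppression",
  "resilience", "agreeableness", "conscientiousness", "extraversion",
  "neuroticism", "openness", "engagement_skewness", "nudge_probability",
  "meeting_counts", "no_meeting_minutes", "self_event_counts",
  "email_messages_sent", "email_messages_read", "ad_hoc_call_count",
  "attention_signals", "nudge_source"
)

#' Define a logistic outcome-model specification
#'
#' A specification names the binary outcome, the ordered predictor list and
#' the analysis table it applies to. Categorical predictors use the fixed
#' reference levels of the deployment analysis: age 18-35, gender man,
#' trigger source system (JIT), category distract, modality conversation,
#' location at desk.
#'
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns.
#' @param scope One of `"per_nudge"`, `"chosen"`, `"completed"`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome, predictors, scope = c("per_nudge", "chosen",
                                                      "completed")) {
  scope <- match.arg(scope)
  structure(list(outcome = outcome, predictors = predictors, scope = scope),
            class = "model_spec")
}

#' The five outcome-model specifications of the tailoring analysis
#'
#' Momentary engagement over all nudges; the three category-choice models
#' and engagement-after-choice over chosen interventions; liking and stress
#' improvement over completed interventions. Chat message counts are built
#' by the feature builder but excluded from all default model formulas.
#'
#' @return Named list of `model_spec` objects: `engaged`, `distract_chosen`,
#'   `calm_chosen`, `address_chosen`, `engaged_after_chosen`, `liked`,
#'   `improved`.
#' @export
default_model_specs <- function() {
  content <- c("category", "modality", "location")
  list(
    engaged = model_spec("engaged", base_predictors, "per_nudge"),
    distract_chosen = model_spec("distract_chosen", base_predictors,
                                 "chosen"),
    calm_chosen = model_spec("calm_chosen", base_predictors, "chosen"),
    address_chosen = model_spec("address_chosen", base_predictors, "chosen"),
    engaged_after_chosen = model_spec("engaged",
                                      c(base_predictors, content), "chosen"),
    liked = model_spec("liked",
                       c(base_predictors, "category", "stress_reduction",
                         "modality", "location"), "completed"),
    improved = model_spec("improved",
                          c(base_predictors, "category", "stress_before",
                            "rating", "modality", "location"), "completed")
  )
}
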