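#' Default simulation configuration
#'
#' Bundles every tunable of the synthetic deployment: cohort composition
#' (trait means/SDs and instrument ranges, gender and age-group marginals),
#' working hours, study length, telemetry count distributions calibrated to
#' the deployment's descriptive statistics, sensed-signal parameters, EMA
#' settings, and engine rules. Count telemetry uses Poisson draws for
#' low-rate, near-equidispersed channels (meetings, self events, ad hoc
#' calls) and negative binomial draws for overdispersed ones (emails read,
#' chats, attention signals), with negative binomial `size` chosen by moment
#' matching to the observed means and SDs.
#'
#' @return Nested configuration list with sections `cohort`, `workday`,
#'   `context`, `sensed`, `ema`, `engine`, `response`.
#' @export
default_config <- function() {
  list(
    cohort = list(
      n_participants = 43,
      weeks = 4,
      start_date = "2023-01-02",  # a Monday; workdays are Mon-Fri
      p_woman = 14 / 43,
      age_probs = c("18-35" = 14, "36-45" = 18, ">46" = 11) / 43,
      traits = list(
        cognitive_reappraisal  = list(mean = 4.69, sd = 1.09, lo = 1, hi = 7),
        expressive_suppression = list(mean = 3.74, sd = 1.26, lo = 1, hi = 7),
        resilience             = list(mean = 3.51, sd = 0.89, lo = 1, hi = 5),
        agreeableness          = list(mean = 3.79, sd = 0.74, lo = 1, hi = 5),
        conscientiousness      = list(mean = 4.12, sd = 0.83, lo = 1, hi = 5),
        extraversion           = list(mean = 2.62, sd = 0.86, lo = 1, hi = 5),
        neuroticism            = list(mean = 2.85, sd = 1.04, lo = 1, hi = 5),
        openness               = list(mean = 3.48, sd = 0.79, lo = 1, hi = 5)
      ),
      # latent temporal-tendency trait on the engagement-skewness scale
      skewness = list(mean = -0.09, sd = 0.58)
    ),
    workday = list(start = "09:00", end = "17:00"),
    context = list(
      meeting_rate = 0.30,            # per half-hour window, Poisson
      self_event_rate = 0.12,         # Poisson
      ad_hoc_call_rate = 0.04,        # Poisson
      email_sent = list(mu = 0.39, size = 0.40),    # negative binomial
      email_read = list(mu = 3.22, size = 0.46),
      chat = list(mu = 3.88, size = 0.49),
      attention = list(mu = 1442.64, size = 1.20, cap = 5705),
      no_meeting = list(p_zero = 0.75, mean_when_busy = 21, cap = 50)
    ),
    sensed = list(
      emails_received_per_day = 15,   # drives the email score component
      heart_rate = list(mean = 72, ar = 0.9, sd = 2.5),
      facial = list(sd = 1)
    ),
    ema = list(per_day = 5, min_spacing_min = 30, response_prob = 0.9,
               freshness_min = 90),
    engine = list(
      tick_min = 5,
      rules = gating_rules(),
      expiry_min = 30,
      normalizers = default_normalizers()
    ),
    response = list(
      postponement_prob = 0.19,
      abandon_after_choice_prob = 0.085,
      post_report_prob = 0.925,
      # 1-5 categorical distributions for pre-intervention stress and rating
      stress_before_probs = c(0.28, 0.41, 0.22, 0.07, 0.02),
      rating_probs = c(0.04, 0.10, 0.26, 0.41, 0.19),
      # stress reduction given improved (values 1,2,3) / not improved (0,-1)
      reduction_improved_probs = c(0.72, 0.23, 0.05),
      reduction_not_improved_probs = c(0.93, 0.07),
      nudge_probability_covariate = 6.25  # percent; 1/16 working slots
    )
  )
}

#' Read a simulation configuration from YAML
#'
#' The YAML file may specify any subset of the sections of
#' [default_config()]; unspecified entries keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_list_deep(default_config(), user)
  validate_config(cfg)
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (nm in names(cfg$cohort$traits)) {
    tr <- cfg$cohort$traits[[nm]]
    if (tr$mean < tr$lo || tr$mean > tr$hi) {
      stop(sprintf("trait '%s': mean %.2f outside instrument range [%g, %g]",
                   nm, tr$mean, tr$lo, tr$hi))
    }
    if (tr$sd < 0) stop(sprintf("trait '%s': negative sd", nm))
  }
  rates <- c(meetings = cfg$context$meeting_rate,
             self_events = cfg$context$self_event_rate,
             ad_hoc_calls = cfg$context$ad_hoc_call_rate)
  bad <- names(rates)[rates < 0]
  if (length(bad)) stop("negative context rate for: ",
                        paste(bad, collapse = ", "))
  if (parse_clock(cfg$workday$start) >= parse_clock(cfg$workday$end)) {
    stop("workday start must precede workday end")
  }
  invisible(cfg)
}

# "HH:MM" -> minutes after midnight
parse_clock <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] * 60 + parts[2]
}
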