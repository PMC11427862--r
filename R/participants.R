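#' Generate a synthetic cohort of information workers
#'
#' Draws `n` participant profiles matching the deployment cohort's
#' descriptive statistics: gender and (collapsed) age-group marginals,
#' emotion-regulation scores (cognitive reappraisal and expressive
#' suppression on 1-7), resilience and the Big Five traits (1-5). Trait
#' values are drawn from normals with the configured means/SDs and clipped
#' to their instrument ranges. Each profile also carries a latent temporal
#' engagement tendency (on the engagement-skewness scale) and the working
#' hours used by the scheduling engine.
#'
#' @param n Number of participants (>= 1).
#' @param config Simulation configuration, see [default_config()].
#' @param seed Integer seed; the same `(config, seed)` always yields the
#'   identical cohort, and extending `n` leaves earlier profiles unchanged.
#' @return Data frame of class `participant_profiles`, one row per
#'   participant, including a `seed` column of per-participant substream
#'   seeds used by [run_deployment()].
#' @export
generate_participants <- function(n, config = default_config(), seed = 1) {
  stopifnot(n >= 1)
  validate_config(config)
  set.seed(seed)
  # one substream per participant, so growing the cohort preserves
  # already-generated participants
  sub_seeds <- sample.int(.Machine$integer.max, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i] %% .Machine$integer.max)
    row <- data.frame(participant_id = sprintf("P%03d", i),
                      stringsAsFactors = FALSE)
    row$gender <- if (runif(1) < config$cohort$p_woman) "woman" else "man"
    row$age_group <- sample(names(config$cohort$age_probs), 1,
                            prob = config$cohort$age_probs)
    for (nm in names(config$cohort$traits)) {
      tr <- config$cohort$traits[[nm]]
      row[[nm]] <- pmin(tr$hi, pmax(tr$lo, rnorm(1, tr$mean, tr$sd)))
    }
    sk <- config$cohort$skewness
    row$engagement_tendency <- rnorm(1, sk$mean, sk$sd)
    rows[[i]] <- row
  }
  profiles <- do.call(rbind, rows)
  profiles$work_start <- config$workday$start
  profiles$work_end <- config$workday$end
  profiles$seed <- sub_seeds
  class(profiles) <- c("participant_profiles", "data.frame")
  profiles
}

workday_bounds <- function(profile, date) {
  day <- as.POSIXct(paste(format(date, "%Y-%m-%d"), "00:00:00"), tz = "UTC")
  list(start = day + parse_clock(profile$work_start) * 60,
       end = day + parse_clock(profile$work_end) * 60)
}
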