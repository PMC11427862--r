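#' Default component normalizers for the composite stress score
#'
#' The composite stress score averages five signals that prior work links to
#' workplace stress: emails received so far today, total meetings scheduled
#' today, the fraction of the workday elapsed, a facial-expression score
#' (corrugator + lip depressor - zygomatic major), and heart rate. Each raw
#' signal is mapped to \[0, 1\] by a clipped min-max transform; the floors and
#' caps below are package defaults chosen to be monotone, bounded and
#' plausible for information workers (emails 0-20/day, meetings 0-8/day,
#' facial score symmetric around 0 with cap +/-3 arbitrary units, heart rate
#' 55-110 beats/min). The fraction-of-day component is already a proportion.
#'
#' @return A named list with one `c(lo, hi)` range per component, in the
#'   canonical component order `emails_received`, `meetings_today`,
#'   `fraction_of_day`, `facial`, `heart_rate`.
#' @export
default_normalizers <- function() {
  list(
    emails_received = c(0, 20),
    meetings_today  = c(0, 8),
    fraction_of_day = c(0, 1),
    facial          = c(-3, 3),
    heart_rate      = c(55, 110)
  )
}

stress_components <- c(
  "emails_received", "meetings_today", "fraction_of_day",
  "facial", "heart_rate"
)

clip01 <- function(x) pmin(1, pmax(0, x))

normalize_component <- function(x, range) {
  clip01((x - range[1]) / (range[2] - range[1]))
}

#' Compute the composite stress score from one sensed sample
#'
#' The score is the arithmetic mean of five components, each normalized to
#' \[0, 1\] (see [default_normalizers()]). It is monotone nondecreasing in
#' every raw signal and always lies in \[0, 1\].
#'
#' @param sample Named list or one-row data frame with the five raw signals
#'   `emails_received`, `meetings_today`, `fraction_of_day`, `facial`,
#'   `heart_rate`.
#' @param normalizers Named list of `c(lo, hi)` ranges, one per component.
#' @return An object of class `stress_score`: a list with `value` (the mean)
#'   and `components` (the five normalized values).
#' @examples
#' s <- compute_stress_score(list(emails_received = 10, meetings_today = 4,
#'                                fraction_of_day = 0.5, facial = 0,
#'                                heart_rate = 82.5))
#' s$value  # 0.5: every component sits at its midpoint
#' @export
compute_stress_score <- function(sample, normalizers = default_normalizers()) {
  missing_norm <- setdiff(stress_components, names(normalizers))
  if (length(missing_norm)) {
    stop("missing normalizer for component(s): ",
         paste(missing_norm, collapse = ", "))
  }
  missing_comp <- setdiff(stress_components, names(sample))
  if (length(missing_comp)) {
    stop("missing stress component(s): ",
         paste(missing_comp, collapse = ", "))
  }
  comps <- vapply(stress_components, function(nm) {
    normalize_component(as.numeric(sample[[nm]]), normalizers[[nm]])
  }, numeric(1))
  structure(list(value = mean(comps), components = comps),
            class = "stress_score")
}

#' Vectorized stress-score series over a day of sensed samples
#'
#' @param sensed Data frame with one row per heuristic tick and the five raw
#'   signal columns.
#' @param normalizers As in [compute_stress_score()].
#' @return Numeric vector of composite scores, one per row.
#' @export
stress_score_series <- function(sensed, normalizers = default_normalizers()) {
  missing_comp <- setdiff(stress_components, names(sensed))
  if (length(missing_comp)) {
    stop("missing stress component(s): ",
         paste(missing_comp, collapse = ", "))
  }
  mats <- vapply(stress_components, function(nm) {
    normalize_component(as.numeric(sensed[[nm]]), normalizers[[nm]])
  }, numeric(nrow(sensed)))
  if (is.null(dim(mats))) mats <- matrix(mats, nrow = 1)
  rowMeans(mats)
}

#' Learn individualized baselines from week-one observations
#'
#' Baselines separate high from low stress in weeks two onward: one threshold
#' on the composite score scale (\[0, 1\]) and one on the self-reported EMA
#' scale (1-5). Each is the arithmetic mean of the week-one observations;
#' with no data the default is the midpoint of the range (0.5 and 3).
#'
#' @param week1_scores Numeric vector of composite stress scores from week 1
#'   (may be empty).
#' @param week1_emas Integer vector of week-1 EMA stress ratings on 1-5
#'   (may be empty).
#' @return An object of class `jitai_baseline`: list with `score_threshold`,
#'   `ema_threshold`, per-threshold sources, and an overall `source` flag
#'   (`"default"` only when both thresholds are defaults).
#' @export
learn_baseline <- function(week1_scores = numeric(), week1_emas = numeric()) {
  if (length(week1_emas) &&
      (any(week1_emas < 1) || any(week1_emas > 5))) {
    stop("EMA ratings must lie on the 1-5 scale")
  }
  score_threshold <- if (length(week1_scores)) mean(week1_scores) else 0.5
  ema_threshold <- if (length(week1_emas)) mean(week1_emas) else 3
  score_source <- if (length(week1_scores)) "learned" else "default"
  ema_source <- if (length(week1_emas)) "learned" else "default"
  structure(list(
    score_threshold = score_threshold,
    ema_threshold = ema_threshold,
    score_source = score_source,
    ema_source = ema_source,
    source = if (score_source == "default" && ema_source == "default")
      "default" else "learned"
  ), class = "jitai_baseline")
}

#' @export
print.stress_score <- function(x, ...) {
  cat("Composite stress score:", format(x$value, digits = 4), "\n")
  print(round(x$components, 4))
  invisible(x)
}

#' @export
print.jitai_baseline <- function(x, ...) {
  cat(sprintf("Baseline (%s): score threshold %.3f (%s), EMA threshold %.2f (%s)\n",
              x$source, x$score_threshold, x$score_source,
              x$ema_threshold, x$ema_source))
  invisible(x)
}
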