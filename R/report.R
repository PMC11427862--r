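#' Run the full simulate -> features -> fit pipeline
#'
#' Generates a cohort, simulates the deployment, reconstructs the three
#' analysis tables, fits the five outcome models, and summarizes the
#' momentary stress ratings. Deterministic given `(config, seed)`. When a
#' stage fails, the error is re-raised with the stage name attached.
#'
#' @param config Simulation configuration (a list from [default_config()] /
#'   [read_config()], or a path to a YAML file).
#' @param seed Integer seed.
#' @param outdir Optional directory; when given, the event log (JSONL),
#'   the three tables (CSV), the model results (JSON) and a run manifest
#'   are written there.
#' @return List of class `jitai_report` with elements `cohort`, `log`,
#'   `tables`, `fits`, `stress_summary`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("cohort", generate_participants(
    config$cohort$n_participants, config, seed))
  truth <- stage("truth", {
    set.seed(seed + 1L)
    calibrate_truth_intercept(default_truth_models(config), config)
  })
  log <- stage("deployment", run_deployment(cohort, truth,
                                            config$cohort$weeks, seed,
                                            config))
  tables <- stage("features", build_model_tables(log))
  specs <- default_model_specs()
  fits <- stage("models", lapply(specs, function(sp) {
    fit_model(tables, sp, separation = "firth")
  }))
  stress_summary <- stage("report", summarize_stress(tables$completed,
                                                     tables$per_nudge))
  manifest <- list(
    seed = seed,
    n_participants = nrow(cohort),
    weeks = config$cohort$weeks,
    n_nudges = nrow(tables$per_nudge),
    n_chosen = nrow(tables$chosen),
    n_completed = nrow(tables$completed),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  out <- structure(list(cohort = cohort, log = log, tables = tables,
                        fits = fits, stress_summary = stress_summary,
                        manifest = manifest), class = "jitai_report")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

#' Summarize momentary stress ratings around nudges and interventions
#'
#' Means and normal-approximation 95% confidence intervals of (a) the EMA
#' stress rating current when each nudge was sent, (b) the pre-intervention
#' and (c) the post-intervention self-reports. When interventions reduce
#' stress on average, the post mean sits below the pre mean.
#'
#' @param completed Completed-intervention table.
#' @param per_nudge Per-nudge table.
#' @return List of class `stress_summary`: per series, `mean`, `ci_low`,
#'   `ci_high`, `n`, plus the raw rating vectors for density plots.
#' @export
summarize_stress <- function(completed, per_nudge) {
  if (nrow(completed) == 0) {
    warning("no completed interventions; stress summary is empty")
  }
  one <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(list(mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  n = 0L))
    }
    m <- mean(x)
    half <- if (length(x) > 1) qnorm(0.975) * sd(x) / sqrt(length(x)) else 0
    list(mean = m, ci_low = m - half, ci_high = m + half, n = length(x))
  }
  structure(list(
    at_nudge = one(per_nudge$stress_at_nudge),
    pre_intervention = one(completed$stress_before),
    post_intervention = one(completed$stress_after),
    ratings = list(at_nudge = per_nudge$stress_at_nudge,
                   pre = completed$stress_before,
                   post = completed$stress_after)
  ), class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  for (nm in c("at_nudge", "pre_intervention", "post_intervention")) {
    s <- x[[nm]]
    cat(sprintf("%-18s mean %.2f (95%% CI %.2f-%.2f, n=%d)\n",
                nm, s$mean, s$ci_low, s$ci_high, s$n))
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_event_log(report$log, file.path(outdir, "events.jsonl"))
  write_tables(report$tables, file.path(outdir, "tables"))
  fits_json <- lapply(report$fits, function(f) {
    list(outcome = f$spec$outcome, scope = f$spec$scope, n = f$n,
         terms = f$terms,
         lr = f$lr, tjur_r2 = f$tjur_r2, vif = as.list(f$vif),
         type2 = f$type2, tukey = f$tukey)
  })
  jsonlite::write_json(fits_json, file.path(outdir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
print.jitai_report <- function(x, ...) {
  cat(sprintf("JITAI deployment report: %d participants, %d weeks\n",
              x$manifest$n_participants, x$manifest$weeks))
  cat(sprintf("  nudges %d | chosen %d | completed %d\n",
              x$manifest$n_nudges, x$manifest$n_chosen,
              x$manifest$n_completed))
  cat("Models:", paste(names(x$fits), collapse = ", "), "\n")
  invisible(x)
}
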