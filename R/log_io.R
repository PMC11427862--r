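#' Write an event log as JSON Lines
#'
#' One event per line; each line is a JSON object with `timestamp`
#' (ISO-8601), `participant_id`, `event_type`, and the event's non-missing
#' payload fields. Timestamps are study-local and timezone-naive.
#'
#' @param log A `jitai_event_log` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) {
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S")
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  payload_cols <- setdiff(names(df), character())
  for (i in seq_len(nrow(df))) {
    row <- df[i, payload_cols]
    row <- row[, !vapply(row, function(x) is.na(x), logical(1)), drop = FALSE]
    writeLines(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' @param path File written by [write_event_log()] (or any log in the same
#'   schema).
#' @return A `jitai_event_log` data frame.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  template <- event_columns()
  rows <- lapply(rows, function(df) {
    for (nm in c("timestamp", "until", "slot_start")) {
      if (!is.null(df[[nm]])) {
        df[[nm]] <- as.POSIXct(df[[nm]], format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
      }
    }
    for (nm in names(template)) {
      if (!is.null(df[[nm]]) && is.numeric(template[[nm]]) &&
          !inherits(template[[nm]], "POSIXct")) {
        df[[nm]] <- as.numeric(df[[nm]])
      }
    }
    conform_events(df)
  })
  log <- do.call(rbind, rows)
  class(log) <- c("jitai_event_log", "data.frame")
  log
}

#' Export an event log as CSV
#'
#' Column-stable CSV mirror of the JSONL schema.
#'
#' @param log A `jitai_event_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log_csv <- function(log, path) {
  df <- as.data.frame(log)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) {
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S")
    }
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
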