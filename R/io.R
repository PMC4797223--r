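# CSV I/O with declared schemas. Validation reports offending row numbers;
# empty cells become NA (never silently zero).

table_schemas <- list(
  roster = list(
    cols = c("id", "age", "hearing_loss_db", "tinnitus_hz",
             "chronicity_months"),
    numeric = c("age", "hearing_loss_db", "tinnitus_hz", "chronicity_months")
  ),
  outcomes = list(
    cols = c("id", "arm", "session", "measure", "value"),
    numeric = "value"
  ),
  harms = list(cols = c("id", "arm", "category"), numeric = character()),
  session_log = list(
    cols = c("session_id", "round", "low_hz", "high_hz", "choice_low",
             "choice_high", "matched_hz", "loudness"),
    numeric = c("round", "low_hz", "high_hz", "matched_hz", "loudness")
  ),
  trace = list(
    cols = c("time_s", "center_hz", "direction"),
    numeric = c("time_s", "center_hz")
  )
)

#' Read / write schema-validated CSV tables
#'
#' Reads a CSV with a declared schema (`roster`, `outcomes`, `harms`,
#' `session_log` or `trace`), validating column presence and types and, for
#' outcome tables, the 0-100 VAS bound and the session label set.
#' Violations are reported with their row numbers.
#'
#' @param path CSV path.
#' @param schema One of the schema names above.
#' @return The validated data.frame.
#' @export
read_table_csv <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema)
}

#' @rdname read_table_csv
#' @param df Data frame to validate or write.
#' @export
validate_table <- function(df, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  sc <- table_schemas[[schema]]
  miss <- setdiff(sc$cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s table missing column(s): %s", schema,
                 paste(miss, collapse = ", ")))
  }
  for (col in sc$numeric) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("%s: column '%s' is not numeric at row(s) %s",
                     schema, col, paste(utils::head(bad, 5L), collapse = ", ")))
      }
      df[[col]] <- v
    }
  }
  if (schema == "outcomes") {
    bad <- which(!df$session %in% outcome_sessions)
    if (length(bad) > 0L) {
      stop(sprintf(
        "outcomes: unknown session label at row(s) %s (allowed: %s)",
        paste(utils::head(bad, 5L), collapse = ", "),
        paste(outcome_sessions, collapse = ", ")
      ))
    }
    is_vas <- startsWith(df$measure, "vas")
    bad <- which(is_vas & !is.na(df$value) & (df$value < 0 | df$value > 100))
    if (length(bad) > 0L) {
      stop(sprintf("outcomes: VAS value outside [0, 100] at row(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  df
}

#' @rdname read_table_csv
#' @export
write_table_csv <- function(df, path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  validate_table(df, schema)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Session log round-trip helpers
#'
#' Converts a [run_session()] result to the App-style per-round log rows
#' and back-aggregates a log to matched frequencies.
#'
#' @param session A `pitch_session`.
#' @param session_id Identifier stored in the log.
#' @return Data frame in the `session_log` schema.
#' @export
session_to_log <- function(session, session_id = 1L) {
  r <- session$responses
  data.frame(
    session_id = session_id, round = r$round, low_hz = r$low_hz,
    high_hz = r$high_hz, choice_low = r$choice_low,
    choice_high = r$choice_high, matched_hz = session$matched_hz,
    loudness = session$loudness_setting
  )
}

#' Write a JSON provenance record
#'
#' Every CLI run records its package version, subcommand, seed and
#' parameters next to its outputs, so any result can be regenerated.
#'
#' @param path Output JSON path.
#' @param command Subcommand name.
#' @param params Named list of parameters (include every seed used).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, command, params) {
  jsonlite::write_json(
    list(
      package = "notchkit",
      version = as.character(utils::packageVersion("notchkit")),
      command = command,
      params = params,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
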