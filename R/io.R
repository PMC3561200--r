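# Interchange formats: programme config as JSON/YAML, score/dose/roster
# tables as comma-separated UTF-8 CSV with a header row and "." decimals.
# Locale decimal commas are rejected by R's numeric parsing, not guessed.

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "json"
}

#' Read and write a programme configuration file
#'
#' The config file (JSON or YAML, chosen by extension) holds the lists of
#' settings, interventions and periods, the optional `mas` (default 20) and
#' an `assignment` table of `(setting, intervention, status)` records.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#'
#' @return `read_programme()`: list with `programme` and `assignment`.
#' @export
read_programme <- function(path) {
  if (!file.exists(path)) {
    stop_irg("programme config not found: ", path, class = "irgdose_io_error")
  }
  raw <- if (file_format(path) == "yaml") {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  for (field in c("settings", "interventions", "periods", "assignment")) {
    if (is.null(raw[[field]])) {
      stop_irg("programme config is missing field '", field, "'",
        class = "irgdose_io_error"
      )
    }
  }
  prog <- programme(
    settings = unlist(raw$settings),
    interventions = unlist(raw$interventions),
    periods = unlist(raw$periods),
    mas = raw$mas %||% 20
  )
  assignment <- raw$assignment
  if (!is.data.frame(assignment)) {
    assignment <- dplyr::bind_rows(lapply(assignment, tibble::as_tibble))
  }
  assignment <- strategy_assignment(assignment)
  # validate completeness against the programme
  invisible(enumerate_irgs(prog, assignment))
  list(programme = prog, assignment = assignment)
}

#' @rdname read_programme
#' @param programme An [programme()] object.
#' @param assignment A [strategy_assignment()] table.
#' @return `write_programme()`: `path`, invisibly.
#' @export
write_programme <- function(programme, assignment, path) {
  stopifnot(inherits(programme, "irg_programme"))
  assignment <- strategy_assignment(assignment)
  payload <- list(
    settings = programme$settings,
    interventions = programme$interventions,
    periods = programme$periods,
    mas = programme$mas,
    assignment = assignment
  )
  if (file_format(path) == "yaml") {
    payload$assignment <- lapply(
      seq_len(nrow(assignment)),
      function(i) as.list(assignment[i, ])
    )
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

SCORE_CSV_COLS <- c(
  "expert_id", "group_id", "setting", "intervention", "activity_class",
  "period", "domain", "declension", "round", "value"
)

#' Read and write expert-score CSV files
#'
#' The score CSV carries one row per expert mark with columns `expert_id`,
#' `group_id`, `setting`, `intervention`, `activity_class` (PDA|NPDA),
#' `period`, `domain`, `declension`, `round` (1|2), `value`. The fictitious
#' calibration IRG uses the reserved setting id
#' `"__FICTITIOUS__"` ([FICTITIOUS_SETTING]). Malformed rows are reported
#' with their row numbers.
#'
#' @param path CSV file path.
#' @param mas Common maximal assignable score; values outside `[0, mas]`
#'   are rejected.
#'
#' @return `read_scores()`: expert-score tibble.
#' @export
read_scores <- function(path, mas = 20) {
  if (!file.exists(path)) {
    stop_irg("score file not found: ", path, class = "irgdose_io_error")
  }
  df <- utils::read.csv(path,
    colClasses = "character",
    fileEncoding = "UTF-8", check.names = FALSE
  )
  check_columns(df, SCORE_CSV_COLS, what = basename(path))
  df$round <- suppressWarnings(as.integer(df$round))
  df$value <- suppressWarnings(as.numeric(df$value))
  report_rows <- function(bad, why) {
    if (any(bad)) {
      stop_irg(
        why, " at row(s): ",
        paste(utils::head(which(bad), 10), collapse = ", "),
        class = "irgdose_io_error"
      )
    }
  }
  report_rows(is.na(df$round) | !(df$round %in% c(1L, 2L)), "round must be 1 or 2")
  report_rows(is.na(df$value), "non-numeric score value")
  report_rows(
    df$value < 0 | df$value > mas,
    paste0("score outside [0, ", mas, "]")
  )
  report_rows(
    !(df$activity_class %in% c("PDA", "NPDA")),
    "activity_class must be PDA or NPDA"
  )
  report_rows(
    !(df$domain %in% c("delivery", "participation")),
    "domain must be delivery or participation"
  )
  report_rows(
    !(df$declension %in% c("quantity", "quality")),
    "declension must be quantity or quality"
  )
  tibble::as_tibble(df)
}

#' @rdname read_scores
#' @param scores Expert-score table.
#' @return `write_scores()`: `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  check_columns(scores, SCORE_CSV_COLS, what = "scores")
  utils::write.csv(scores[SCORE_CSV_COLS], path,
    row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read and write dose tables as CSV
#'
#' Columns: `setting`, `intervention`, `status`, `activity_class`,
#' `period`, `DQt`, `DQl`, `PQt`, `PQl`, `mas`, `dose` (score columns are
#' optional on read).
#'
#' @param path CSV file path.
#' @return `read_doses()`: dose tibble.
#' @export
read_doses <- function(path) {
  if (!file.exists(path)) {
    stop_irg("dose file not found: ", path, class = "irgdose_io_error")
  }
  df <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  check_columns(
    df,
    c("setting", "intervention", "status", "activity_class", "period", "dose"),
    what = basename(path)
  )
  df$setting <- as.character(df$setting)
  df$intervention <- as.character(df$intervention)
  df$period <- as.character(df$period)
  tibble::as_tibble(df)
}

#' @rdname read_doses
#' @param doses Dose table from [compute_all_doses()].
#' @return `write_doses()`: `path`, invisibly.
#' @export
write_doses <- function(doses, path) {
  check_columns(
    doses,
    c("setting", "intervention", "status", "activity_class", "period", "dose"),
    what = "doses"
  )
  utils::write.csv(doses, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a target-person roster CSV
#'
#' @param path CSV with columns `target_id`, `setting`.
#' @return Roster tibble.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) {
    stop_irg("roster file not found: ", path, class = "irgdose_io_error")
  }
  df <- utils::read.csv(path,
    colClasses = "character",
    fileEncoding = "UTF-8", check.names = FALSE
  )
  check_columns(df, c("target_id", "setting"), what = basename(path))
  tibble::as_tibble(df)
}

#' Render an indicator report sheet as markdown
#'
#' One sheet per (IRG, activity class): indicators are presented by domain,
#' then declension, then concerned actor, for each period. Quantitative
#' indicators are shown with their unit, qualitative (literal) indicators
#' verbatim; missing cells are rendered as explicit gaps. Output is
#' deterministic: the same input always yields byte-identical text.
#'
#' @param sheet One-row data frame with `setting`, `intervention`,
#'   `status`, `activity_class` (a row of [plan_report_sheets()]).
#' @param indicators Optional data frame with columns `domain`,
#'   `declension`, `period`, `label`, `value` and optionally `actor_role`,
#'   `unit`.
#' @param scores Optional one-row score set (columns `DQt`, `DQl`, `PQt`,
#'   `PQl`) appended as the sheet's consolidated scores.
#'
#' @return A single character string of markdown.
#' @export
render_report_sheet <- function(sheet, indicators = NULL, scores = NULL) {
  check_columns(sheet, c("setting", "intervention", "status", "activity_class"),
    what = "sheet"
  )
  stopifnot(nrow(sheet) == 1)
  if (!is.null(indicators)) {
    check_columns(indicators,
      c("domain", "declension", "period", "label", "value"),
      what = "indicators"
    )
  }
  lines <- c(
    sprintf(
      "# Indicator report sheet: %s / %s (%s, %s)",
      sheet$setting, sheet$intervention, sheet$status, sheet$activity_class
    ),
    ""
  )
  for (dom in c("delivery", "participation")) {
    lines <- c(lines, sprintf("## %s", dom), "")
    for (dec in c("quantity", "quality")) {
      lines <- c(lines, sprintf("### %s", dec), "")
      rows <- if (is.null(indicators)) {
        NULL
      } else {
        ind <- indicators[
          indicators$domain == dom & indicators$declension == dec,
        ]
        ord <- order(
          ind$period,
          if ("actor_role" %in% names(ind)) ind$actor_role else ind$label,
          ind$label
        )
        ind[ord, ]
      }
      if (is.null(rows) || nrow(rows) == 0) {
        lines <- c(lines, "_(no indicators recorded)_", "")
        next
      }
      for (i in seq_len(nrow(rows))) {
        actor <- if ("actor_role" %in% names(rows)) {
          paste0(" [", rows$actor_role[i], "]")
        } else {
          ""
        }
        unit <- if ("unit" %in% names(rows) && !is.na(rows$unit[i]) &&
          nzchar(rows$unit[i])) {
          paste0(" ", rows$unit[i])
        } else {
          ""
        }
        lines <- c(lines, sprintf(
          "- (%s)%s %s: %s%s",
          rows$period[i], actor, rows$label[i], rows$value[i], unit
        ))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(scores)) {
    check_columns(scores, c("DQt", "DQl", "PQt", "PQl"), what = "scores")
    lines <- c(
      lines, "## Consolidated scores", "",
      "| DQt | DQl | PQt | PQl |",
      "| --- | --- | --- | --- |",
      sprintf(
        "| %s | %s | %s | %s |",
        scores$DQt[1], scores$DQl[1], scores$PQt[1], scores$PQl[1]
      ),
      ""
    )
  }
  paste(lines, collapse = "\n")
}
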