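#' Distribute IRGs among expert groups
#'
#' IRGs are scored blind and are distributed fairly among the expert groups:
#' a seeded random shuffle followed by round-robin allocation, so group
#' sizes never differ by more than one and the same seed always reproduces
#' the same allocation.
#'
#' @param irgs IRG table (`setting`, `intervention`, `status`).
#' @param group_ids Character vector of expert-group identifiers (>= 1).
#' @param seed Optional integer seed; the global RNG state is preserved.
#'
#' @return The IRG table with an added `group_id` column.
#' @export
distribute_irgs <- function(irgs, group_ids, seed = NULL) {
  check_columns(irgs, c("setting", "intervention"), what = "irgs")
  group_ids <- as.character(group_ids)
  if (length(group_ids) < 1 || anyDuplicated(group_ids)) {
    stop_irg("group_ids must be a non-empty set of unique identifiers",
      class = "irgdose_bad_input"
    )
  }
  n <- nrow(irgs)
  if (n == 0) {
    return(dplyr::mutate(tibble::as_tibble(irgs), group_id = character(0)))
  }
  ord <- local_seed(seed, sample.int(n))
  out <- tibble::as_tibble(irgs)
  out$group_id <- NA_character_
  out$group_id[ord] <- rep_len(group_ids, n)
  out
}

#' Summarise one score cell
#'
#' For every domain/declension and every period the mean, sample standard
#' deviation and range (max - min) of the experts' scores are computed; the
#' dispersion statistics drive the debate rule (see [flag_for_debate()]).
#'
#' @param scores Either a numeric vector of at least two expert scores, or a
#'   data frame of expert-score rows that must all belong to one cell
#'   (same setting, intervention, activity class, period, domain,
#'   declension) and one round.
#'
#' @return One-row tibble with `n_experts`, `mean`, `sd`, `range`.
#' @examples
#' summarize_cell(c(10, 12, 14, 16, 18, 20))
#' @export
summarize_cell <- function(scores) {
  if (is.data.frame(scores)) {
    check_columns(scores, "value", what = "scores")
    keys <- intersect(c(CELL_COLS, "round"), names(scores))
    if (length(keys) > 0 && nrow(dplyr::distinct(scores[keys])) > 1) {
      stop_irg("scores mix several cells or rounds; summarise one cell at a time",
        class = "irgdose_inconsistent_cell"
      )
    }
    values <- scores$value
  } else {
    values <- as.numeric(scores)
  }
  if (length(values) < 2) {
    stop_irg("at least two expert scores are required to summarise a cell",
      class = "irgdose_insufficient_raters"
    )
  }
  tibble::tibble(
    n_experts = length(values),
    mean = mean(values),
    sd = stats::sd(values),
    range = max(values) - min(values)
  )
}

#' Debate rule: should the experts re-score a cell?
#'
#' A cell is flagged for debate when the round-1 scores disperse too much:
#' standard deviation strictly above `sd_threshold` or range strictly above
#' `range_threshold` (defaults 2.5 and 6). Both comparisons are strict, so
#' a cell sitting exactly on a threshold is not debated.
#'
#' @param sd Sample standard deviation(s) of the round-1 scores.
#' @param range Range(s) (max - min) of the round-1 scores.
#' @param sd_threshold,range_threshold Positive thresholds.
#'
#' @return Logical vector.
#' @export
flag_for_debate <- function(sd, range, sd_threshold = 2.5, range_threshold = 6) {
  if (!is.numeric(sd_threshold) || sd_threshold <= 0 ||
    !is.numeric(range_threshold) || range_threshold <= 0) {
    stop_irg("thresholds must be positive", class = "irgdose_bad_input")
  }
  sd > sd_threshold | range > range_threshold
}

#' Consolidate one cell across scoring rounds
#'
#' When a cell was debated, the second-round scores replace the first-round
#' ones entirely; the consolidated value is the mean of the retained round.
#' Mean scores are kept even in the absence of consensus.
#'
#' @param round1 Numeric vector of round-1 scores.
#' @param round2 Numeric vector of round-2 scores, or `NULL` if the cell was
#'   not debated.
#' @param flagged Was the cell flagged for debate after round 1? Supplying
#'   `round2` for an unflagged cell is a protocol violation.
#'
#' @return The consolidated (final) score.
#' @export
consolidate_cell <- function(round1, round2 = NULL, flagged = !is.null(round2)) {
  if (length(round1) < 1) {
    stop_irg("round-1 scores are required", class = "irgdose_insufficient_raters")
  }
  if (!is.null(round2) && length(round2) > 0 && !flagged) {
    stop_irg(
      "round-2 scores supplied for a cell that was not flagged for debate",
      class = "irgdose_protocol_violation"
    )
  }
  if (!is.null(round2) && length(round2) > 0) mean(round2) else mean(round1)
}

#' Summarise and flag all round-1 score cells
#'
#' @param scores Expert-score table with columns `expert_id`, `group_id`,
#'   `setting`, `intervention`, `activity_class`, `period`, `domain`,
#'   `declension`, `round`, `value`.
#' @inheritParams flag_for_debate
#'
#' @return Tibble with one row per (cell, group): cell key columns,
#'   `group_id`, `n_experts`, `mean`, `sd`, `range`, `flagged`.
#' @export
summarize_scores <- function(scores, sd_threshold = 2.5, range_threshold = 6) {
  check_columns(scores, c(CELL_COLS, "group_id", "round", "value"),
    what = "scores"
  )
  keys <- c(CELL_COLS, intersect("status", names(scores)), "group_id")
  out <- scores |>
    dplyr::filter(.data$round == 1) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_experts = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      range = max(.data$value) - min(.data$value),
      .groups = "drop"
    )
  if (any(out$n_experts < 2)) {
    stop_irg("every cell needs at least two round-1 expert scores",
      class = "irgdose_insufficient_raters"
    )
  }
  out$flagged <- flag_for_debate(out$sd, out$range, sd_threshold, range_threshold)
  out
}

#' Consolidate a full expert-score table
#'
#' Applies the nominal-group protocol to every (cell, group): round-1 scores
#' are summarised, the debate rule decides which cells were flagged, and the
#' final score is the mean of round 2 where it exists, otherwise the mean of
#' round 1. Round-2 records on unflagged cells raise a protocol-violation
#' error.
#'
#' @inheritParams summarize_scores
#'
#' @return Tibble with one row per (cell, group): cell keys, `group_id`,
#'   `n_experts`, `sd`, `range`, `flagged`, `debated` (round-2 scores
#'   present) and the final `score`.
#' @export
consolidate_scores <- function(scores, sd_threshold = 2.5, range_threshold = 6) {
  check_columns(scores, c(CELL_COLS, "group_id", "round", "value"),
    what = "scores"
  )
  if (!all(scores$round %in% c(1, 2))) {
    stop_irg("round must be 1 or 2", class = "irgdose_bad_input")
  }
  keys <- c(CELL_COLS, intersect("status", names(scores)), "group_id")
  out <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_experts = sum(.data$round == 1),
      mean1 = mean(.data$value[.data$round == 1]),
      sd = stats::sd(.data$value[.data$round == 1]),
      range = diff(range(.data$value[.data$round == 1])),
      debated = any(.data$round == 2),
      mean2 = if (any(.data$round == 2)) {
        mean(.data$value[.data$round == 2])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (any(out$n_experts < 2)) {
    stop_irg("every cell needs at least two round-1 expert scores",
      class = "irgdose_insufficient_raters"
    )
  }
  out$flagged <- flag_for_debate(out$sd, out$range, sd_threshold, range_threshold)
  if (any(out$debated & !out$flagged)) {
    stop_irg(
      "round-2 scores found for cell(s) that the debate rule did not flag",
      class = "irgdose_protocol_violation"
    )
  }
  out$score <- ifelse(out$debated, out$mean2, out$mean1)
  dplyr::select(out, -"mean1", -"mean2")
}

#' Estimate between-group calibration offsets from a fictitious IRG
#'
#' When several expert groups are constituted, a fictitious IRG scored by
#' all of them measures the group effect. A group's offset is its mean score
#' over all fictitious cells minus the grand mean of the group means, so the
#' offsets always sum to zero; subtracting them equalises the groups on the
#' fictitious IRG.
#'
#' @param fictitious_scores Table of the fictitious IRG's scores with a
#'   `group_id` column and a `value` (or consolidated `score`) column. If
#'   cell key columns are present, every group must cover the same cells.
#'
#' @return Tibble with columns `group_id`, `offset`.
#' @examples
#' compute_group_offsets(tibble::tibble(
#'   group_id = rep(c("g1", "g2", "g3"), each = 2),
#'   value = c(12, 12, 14, 14, 16, 16)
#' ))
#' @export
compute_group_offsets <- function(fictitious_scores) {
  check_columns(fictitious_scores, "group_id", what = "fictitious_scores")
  value_col <- if ("value" %in% names(fictitious_scores)) "value" else "score"
  check_columns(fictitious_scores, value_col, what = "fictitious_scores")
  groups <- unique(fictitious_scores$group_id)
  if (length(groups) < 2) {
    stop_irg("calibration needs fictitious scores from at least two groups",
      class = "irgdose_incomplete_calibration"
    )
  }
  cell_keys <- intersect(CELL_COLS, names(fictitious_scores))
  if (length(cell_keys) > 0) {
    cells_by_group <- split(
      do.call(paste, c(fictitious_scores[cell_keys], sep = "\r")),
      fictitious_scores$group_id
    )
    all_cells <- unique(unlist(cells_by_group))
    covered <- vapply(
      cells_by_group,
      function(x) all(all_cells %in% x), logical(1)
    )
    if (!all(covered)) {
      stop_irg(
        "incomplete calibration: group(s) ",
        paste(names(covered)[!covered], collapse = ", "),
        " did not score every fictitious cell",
        class = "irgdose_incomplete_calibration"
      )
    }
  }
  group_means <- tapply(
    fictitious_scores[[value_col]], fictitious_scores$group_id, mean
  )
  offsets <- group_means - mean(group_means)
  tibble::tibble(group_id = names(offsets), offset = as.numeric(offsets))
}

#' Remove the expert-group effect from consolidated scores
#'
#' Subtracts each group's calibration offset from its scores and clamps the
#' result to `[0, mas]`. Fictitious-IRG rows are dropped from the output:
#' they exist only to estimate the offsets.
#'
#' @param scores Consolidated score table with `group_id` and a `score`
#'   (or `value`) column.
#' @param offsets Offset table from [compute_group_offsets()], or `NULL`
#'   for a no-op calibration.
#' @param mas Common maximal assignable score.
#'
#' @return The score table with scores calibrated, fictitious rows removed.
#' @export
apply_calibration <- function(scores, offsets, mas = 20) {
  value_col <- if ("score" %in% names(scores)) "score" else "value"
  check_columns(scores, c("group_id", value_col), what = "scores")
  if (is.null(offsets)) {
    offsets <- tibble::tibble(
      group_id = unique(scores$group_id), offset = 0
    )
  }
  check_columns(offsets, c("group_id", "offset"), what = "offsets")
  missing <- setdiff(unique(scores$group_id), offsets$group_id)
  if (length(missing) > 0) {
    stop_irg(
      "no calibration offset for group(s): ",
      paste(missing, collapse = ", "),
      class = "irgdose_missing_offset"
    )
  }
  out <- dplyr::left_join(scores, offsets, by = "group_id")
  out[[value_col]] <- clamp(out[[value_col]] - out$offset, 0, mas)
  out$offset <- NULL
  if ("setting" %in% names(out)) {
    out <- dplyr::filter(out, .data$setting != FICTITIOUS_SETTING)
  }
  out
}

#' Assemble the four-score sets used by the dose formula
#'
#' For each (IRG, activity class, period) the four consolidated
#' domain/declension scores are gathered into one row: DQt (delivery
#' quantity), DQl (delivery quality), PQt (participation quantity), PQl
#' (participation quality). Triples missing any of the four cells are
#' skipped and reported in the `incomplete` attribute.
#'
#' @param calibrated Calibrated consolidated score table with the cell key
#'   columns and a `score` column.
#' @param mas Common maximal assignable score, recorded per row.
#'
#' @return Tibble with columns `setting`, `intervention`, (`status` if
#'   present), `activity_class`, `period`, `DQt`, `DQl`, `PQt`, `PQl`,
#'   `mas`; attribute `incomplete` lists skipped triples and their missing
#'   cells.
#' @export
build_score_sets <- function(calibrated, mas = 20) {
  check_columns(calibrated, c(CELL_COLS, "score"), what = "calibrated")
  dup <- duplicated(calibrated[CELL_COLS])
  if (any(dup)) {
    stop_irg("several scores supplied for the same cell; consolidate first",
      class = "irgdose_bad_input"
    )
  }
  keys <- c(
    "setting", "intervention", intersect("status", names(calibrated)),
    "activity_class", "period"
  )
  wide <- calibrated |>
    dplyr::mutate(cell = paste0(
      ifelse(.data$domain == "delivery", "D", "P"),
      ifelse(.data$declension == "quantity", "Qt", "Ql")
    )) |>
    dplyr::select(dplyr::all_of(keys), "cell", "score") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "score")
  for (col in c("DQt", "DQl", "PQt", "PQl")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide[c(keys, "DQt", "DQl", "PQt", "PQl")]
  complete <- stats::complete.cases(wide[c("DQt", "DQl", "PQt", "PQl")])
  incomplete <- wide[!complete, ]
  if (nrow(incomplete) > 0) {
    message(
      nrow(incomplete), " (IRG, activity class, period) triple(s) skipped: ",
      "missing domain/declension cells"
    )
  }
  out <- wide[complete, ]
  out$mas <- mas
  attr(out, "incomplete") <- incomplete
  out
}

#' Run the full scoring-to-dose pipeline
#'
#' Convenience wrapper chaining [consolidate_scores()],
#' [compute_group_offsets()] on the fictitious IRG (when present and more
#' than one group scored it), [apply_calibration()], [build_score_sets()]
#' and [compute_all_doses()].
#'
#' @inheritParams summarize_scores
#' @param irgs Optional IRG table used to attach `status` when the score
#'   table does not carry it.
#' @param mas Common maximal assignable score.
#' @param calibrate Estimate and remove group offsets via the fictitious
#'   IRG? Default `TRUE`.
#'
#' @return List with `doses`, `score_sets`, `consolidated`, `offsets`,
#'   `flagged` (debated cells) and `incomplete`.
#' @export
dose_pipeline <- function(scores, irgs = NULL, mas = 20,
                          sd_threshold = 2.5, range_threshold = 6,
                          calibrate = TRUE) {
  if (!is.null(irgs) && !"status" %in% names(scores)) {
    check_columns(irgs, c("setting", "intervention", "status"), what = "irgs")
    scores <- dplyr::left_join(scores, irgs,
      by = c("setting", "intervention")
    )
    scores$status[scores$setting == FICTITIOUS_SETTING] <- "control"
    if (anyNA(scores$status)) {
      stop_irg("some scored IRGs are absent from the IRG table",
        class = "irgdose_bad_input"
      )
    }
  }
  consolidated <- consolidate_scores(scores, sd_threshold, range_threshold)
  fict <- dplyr::filter(consolidated, .data$setting == FICTITIOUS_SETTING)
  offsets <- NULL
  if (calibrate && nrow(fict) > 0 && length(unique(fict$group_id)) >= 2) {
    offsets <- compute_group_offsets(fict)
  }
  calibrated <- apply_calibration(consolidated, offsets, mas = mas)
  score_sets <- build_score_sets(calibrated, mas = mas)
  doses <- compute_all_doses(score_sets)
  list(
    doses = doses,
    score_sets = score_sets,
    consolidated = consolidated,
    offsets = offsets %||%
      tibble::tibble(group_id = unique(consolidated$group_id), offset = 0),
    flagged = dplyr::filter(consolidated, .data$flagged),
    incomplete = attr(score_sets, "incomplete")
  )
}
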