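#' Intervention dose of one score set
#'
#' The four scores are nested rather than independent: participation is
#' subject to delivery, and quality to quantity. The delivery-quantity score
#' is therefore weighted down by the mean of the three remaining scores,
#' normalised by the common maximal assignable score:
#'
#' \deqn{Dose = DQt \times \frac{mean(DQl, PQt, PQl)}{mas}}
#'
#' The weighting factor lies in `[0, 1]`, so the dose never exceeds `DQt`
#' (nor `mas`).
#'
#' @param dqt,dql,pqt,pql Delivery quantity/quality and participation
#'   quantity/quality scores, each in `[0, mas]`. Vectorised.
#' @param mas Common maximal assignable score (positive).
#'
#' @return Numeric vector of doses.
#' @examples
#' compute_dose(13.6, 12.2, 12.2, 11.4) # 8.1147
#' @export
compute_dose <- function(dqt, dql, pqt, pql, mas = 20) {
  if (!is.numeric(mas) || any(mas <= 0)) {
    stop_irg("mas must be positive", class = "irgdose_bad_mas")
  }
  scores <- cbind(dqt, dql, pqt, pql)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > mas)) {
    stop_irg("all four scores must lie in [0, mas]",
      class = "irgdose_domain_error"
    )
  }
  dqt * ((dql + pqt + pql) / 3) / mas
}

#' Compute all intervention doses of a score-set table
#'
#' One dose per score set: for every period, each IRG yields one
#' non-programme-driven activities dose, and each active IRG additionally
#' one programme-driven activities dose. A PDA score set on a control IRG is
#' a consistency error: control IRGs have no programme-driven activities.
#'
#' @param score_sets Score-set table from [build_score_sets()] (columns
#'   `setting`, `intervention`, `status`, `activity_class`, `period`,
#'   `DQt`, `DQl`, `PQt`, `PQl`, `mas`).
#'
#' @return The table with an added `dose` column.
#' @export
compute_all_doses <- function(score_sets) {
  check_columns(
    score_sets,
    c(
      "setting", "intervention", "status", "activity_class", "period",
      "DQt", "DQl", "PQt", "PQl", "mas"
    ),
    what = "score_sets"
  )
  if (nrow(score_sets) == 0) {
    return(dplyr::mutate(tibble::as_tibble(score_sets), dose = numeric(0)))
  }
  check_status_tokens(score_sets$status)
  check_activity_class(score_sets$activity_class)
  bad <- score_sets$activity_class == "PDA" & score_sets$status == "control"
  if (any(bad)) {
    stop_irg(
      "programme-driven score set(s) found for control IRG(s), e.g. (",
      score_sets$setting[bad][1], ", ", score_sets$intervention[bad][1], ")",
      class = "irgdose_consistency_error"
    )
  }
  dplyr::mutate(
    score_sets,
    dose = compute_dose(.data$DQt, .data$DQl, .data$PQt, .data$PQl, .data$mas)
  )
}

#' Assign IRG doses to target persons
#'
#' The dose is measured collectively at the IRG level; every target person
#' of a setting inherits, verbatim, every dose of every IRG of that setting
#' (for use in later on-treatment outcome analyses).
#'
#' @param doses Dose table from [compute_all_doses()].
#' @param roster Data frame with columns `target_id`, `setting`.
#'
#' @return Long tibble: `target_id`, `setting`, `intervention`,
#'   `activity_class`, `period`, `dose`.
#' @export
assign_doses_to_targets <- function(doses, roster) {
  check_columns(doses, c(
    "setting", "intervention", "activity_class",
    "period", "dose"
  ), what = "doses")
  check_columns(roster, c("target_id", "setting"), what = "roster")
  roster <- tibble::as_tibble(roster)
  if (anyDuplicated(roster$target_id)) {
    stop_irg("duplicate target_id(s) in roster", class = "irgdose_roster_error")
  }
  unknown <- setdiff(unique(roster$setting), unique(doses$setting))
  if (length(unknown) > 0) {
    stop_irg(
      "roster names setting(s) with no doses: ",
      paste(unknown, collapse = ", "),
      class = "irgdose_roster_error"
    )
  }
  out <- dplyr::inner_join(
    roster,
    doses[c("setting", "intervention", "activity_class", "period", "dose")],
    by = "setting", relationship = "many-to-many"
  )
  dplyr::arrange(
    out, .data$target_id, .data$intervention,
    .data$activity_class, .data$period
  )
}

#' Pivot target dose records to one row per target
#'
#' @param records Long table from [assign_doses_to_targets()].
#'
#' @return Tibble with `target_id`, `setting` and one
#'   `<intervention>_<activity_class>_<period>` column per dose.
#' @export
widen_target_doses <- function(records) {
  check_columns(records, c(
    "target_id", "setting", "intervention",
    "activity_class", "period", "dose"
  ), what = "records")
  records |>
    dplyr::mutate(key = paste(.data$intervention, .data$activity_class,
      .data$period,
      sep = "_"
    )) |>
    dplyr::select("target_id", "setting", "key", "dose") |>
    tidyr::pivot_wider(names_from = "key", values_from = "dose")
}
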