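#' Define a health promotion programme
#'
#' A programme is described by its settings (the basic units in which an
#' intervention is planned: schools, hospitals, districts ...), the
#' interventions (strategies) under evaluation, the ordered intervention
#' periods, and the common maximal assignable score `mas` used on every
#' expert-scoring scale.
#'
#' @param settings Character vector of unique setting identifiers.
#' @param interventions Character vector of unique intervention identifiers.
#' @param periods Character (or coercible) vector of period identifiers,
#'   ordered in time; at least one.
#' @param mas Common maximal assignable score; positive number, default 20.
#'
#' @return An object of class `irg_programme`.
#' @examples
#' programme(c("s1", "s2"), c("education"), periods = "year_1")
#' @export
programme <- function(settings, interventions, periods, mas = 20) {
  settings <- as.character(settings)
  interventions <- as.character(interventions)
  periods <- as.character(periods)
  if (anyDuplicated(settings)) {
    stop_irg(
      "duplicate setting id(s): ",
      paste(unique(settings[duplicated(settings)]), collapse = ", "),
      class = "irgdose_duplicate_id"
    )
  }
  if (anyDuplicated(interventions)) {
    stop_irg(
      "duplicate intervention id(s): ",
      paste(unique(interventions[duplicated(interventions)]), collapse = ", "),
      class = "irgdose_duplicate_id"
    )
  }
  if (length(periods) < 1 || anyDuplicated(periods)) {
    stop_irg("periods must be a non-empty set of unique identifiers",
      class = "irgdose_bad_periods"
    )
  }
  if (!is.numeric(mas) || length(mas) != 1 || !is.finite(mas) || mas <= 0) {
    stop_irg("mas must be a single positive number", class = "irgdose_bad_mas")
  }
  structure(
    list(
      settings = settings, interventions = interventions,
      periods = periods, mas = as.numeric(mas)
    ),
    class = "irg_programme"
  )
}

#' @export
print.irg_programme <- function(x, ...) {
  cat(
    "<irg_programme> ", length(x$settings), " settings x ",
    length(x$interventions), " interventions, ",
    length(x$periods), " period(s), mas = ", x$mas, "\n",
    sep = ""
  )
  invisible(x)
}

#' Validate an active/control strategy assignment table
#'
#' @param assignment Data frame with columns `setting`, `intervention`,
#'   `status` (`"active"` or `"control"`), one row per pair.
#'
#' @return The assignment as a validated tibble.
#' @export
strategy_assignment <- function(assignment) {
  check_columns(assignment, c("setting", "intervention", "status"),
    what = "assignment"
  )
  assignment <- tibble::as_tibble(assignment)
  assignment$setting <- as.character(assignment$setting)
  assignment$intervention <- as.character(assignment$intervention)
  assignment$status <- as.character(assignment$status)
  check_status_tokens(assignment$status)
  dup <- duplicated(assignment[c("setting", "intervention")])
  if (any(dup)) {
    stop_irg(
      "assignment lists some (setting, intervention) pairs more than once",
      class = "irgdose_incomplete_assignment"
    )
  }
  assignment
}

#' Enumerate the intervention-related groups (IRGs) of a programme
#'
#' An IRG is one (setting, intervention) cell: the basic unit in which an
#' intervention is planned and in which its implementation may vary. A
#' setting assigned an intervention forms an IRG-Active for it; otherwise it
#' is an IRG-Control of that intervention. Every pair yields an IRG, so the
#' count is always `|settings| x |interventions|`.
#'
#' @param programme An [programme()] object.
#' @param assignment A [strategy_assignment()] table covering all pairs.
#'
#' @return Tibble with columns `setting`, `intervention`, `status`.
#' @examples
#' prog <- programme(c("s1", "s2", "s3"), c("i1", "i2"), "p1")
#' asg <- strategy_assignment(tibble::tibble(
#'   setting = rep(c("s1", "s2", "s3"), each = 2),
#'   intervention = rep(c("i1", "i2"), 3),
#'   status = c("active", "control", "active", "control", "control", "active")
#' ))
#' enumerate_irgs(prog, asg)
#' @export
enumerate_irgs <- function(programme, assignment) {
  stopifnot(inherits(programme, "irg_programme"))
  assignment <- strategy_assignment(assignment)
  grid <- tidyr::expand_grid(
    setting = programme$settings,
    intervention = programme$interventions
  )
  irgs <- dplyr::left_join(grid, assignment,
    by = c("setting", "intervention")
  )
  if (anyNA(irgs$status)) {
    miss <- irgs[is.na(irgs$status), c("setting", "intervention")]
    stop_irg(
      "assignment is incomplete: missing status for ",
      nrow(miss), " (setting, intervention) pair(s), e.g. (",
      miss$setting[1], ", ", miss$intervention[1], ")",
      class = "irgdose_incomplete_assignment"
    )
  }
  extra <- dplyr::anti_join(assignment, grid,
    by = c("setting", "intervention")
  )
  if (nrow(extra) > 0) {
    stop_irg(
      "assignment mentions pairs outside the programme, e.g. (",
      extra$setting[1], ", ", extra$intervention[1], ")",
      class = "irgdose_incomplete_assignment"
    )
  }
  irgs
}

#' The evaluation-object grid
#'
#' Crossing the two domains (delivery, participation) with the two
#' declensions (quantity, quality) gives four levels to estimate for each
#' category of programme actor -- supervisor, anchor personnel in its
#' receiver and provider roles, and target -- i.e. 16 evaluation objects.
#' Only 12 are eligible for process evaluation, because targets do not
#' perform interventions and supervisors do not work in the field; the
#' default ineligibility mask encodes those two exclusions and can be
#' overridden when a programme's actor structure differs.
#'
#' @param ineligible Data frame of ineligible cells with columns
#'   `actor_role`, `domain`, `declension`; defaults to
#'   [default_ineligible_cells()].
#'
#' @return Tibble of 16 rows with columns `actor_role`, `domain`,
#'   `declension`, `eligible`.
#' @export
evaluation_grid <- function(ineligible = default_ineligible_cells()) {
  check_columns(ineligible, c("actor_role", "domain", "declension"),
    what = "ineligible"
  )
  grid <- tidyr::expand_grid(
    actor_role = c("supervisor", "anchor_receiver", "anchor_provider", "target"),
    domain = c("delivery", "participation"),
    declension = c("quantity", "quality")
  )
  key <- function(d) paste(d$actor_role, d$domain, d$declension, sep = "\r")
  bad <- setdiff(key(ineligible), key(grid))
  if (length(bad) > 0) {
    stop_irg("ineligible mask names cells outside the 16-object grid",
      class = "irgdose_bad_input"
    )
  }
  grid$eligible <- !(key(grid) %in% key(ineligible))
  grid
}

#' @rdname evaluation_grid
#' @export
default_ineligible_cells <- function() {
  tibble::tibble(
    actor_role = c("target", "target", "supervisor", "supervisor"),
    domain = c("delivery", "delivery", "participation", "participation"),
    declension = c("quantity", "quality", "quantity", "quality")
  )
}

#' Plan the indicator report sheets of a programme
#'
#' Every IRG gets one report sheet of non-programme-driven activities (NPDA)
#' indicators; every active IRG additionally gets one sheet of
#' programme-driven activities (PDA) indicators. A setting's sheet count is
#' therefore `|interventions| + (number of its active strategies)`.
#'
#' @param irgs IRG table from [enumerate_irgs()].
#'
#' @return Tibble with columns `setting`, `intervention`, `status`,
#'   `activity_class` (`"NPDA"` or `"PDA"`), one row per sheet.
#' @export
plan_report_sheets <- function(irgs) {
  check_columns(irgs, c("setting", "intervention", "status"), what = "irgs")
  check_status_tokens(irgs$status)
  npda <- dplyr::mutate(irgs, activity_class = "NPDA")
  pda <- dplyr::mutate(
    dplyr::filter(irgs, .data$status == "active"),
    activity_class = "PDA"
  )
  dplyr::arrange(
    dplyr::bind_rows(npda, pda),
    .data$setting, .data$intervention, .data$activity_class
  )
}

#' Expected number of intervention doses
#'
#' Per period, every IRG yields one NPDA dose and every active IRG one
#' additional PDA dose, so an IRG-Active yields `2 * n_periods` doses and an
#' IRG-Control `n_periods`.
#'
#' @param irgs IRG table from [enumerate_irgs()].
#' @param n_periods Number of intervention periods (>= 1).
#'
#' @return List with elements `total` and `per_period`.
#' @export
expected_dose_count <- function(irgs, n_periods) {
  check_columns(irgs, c("setting", "intervention", "status"), what = "irgs")
  check_status_tokens(irgs$status)
  if (!is.numeric(n_periods) || length(n_periods) != 1 ||
    n_periods < 1 || n_periods != round(n_periods)) {
    stop_irg("n_periods must be a single integer >= 1",
      class = "irgdose_bad_input"
    )
  }
  n_active <- sum(irgs$status == "active")
  n_control <- sum(irgs$status == "control")
  per_period <- 2L * n_active + n_control
  list(total = as.integer(n_periods) * per_period, per_period = per_period)
}
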