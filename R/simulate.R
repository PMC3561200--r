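# Published 24-school x 3-strategy active/control pattern ("A"/"C"),
# columns: education, screening, environment. Column sums are 12 actives
# each; row-wise sheet totals range 3..6.
.pralimap_pattern <- matrix(
  c(
    "C", "C", "C",
    "A", "A", "C",
    "A", "A", "A",
    "A", "C", "A",
    "A", "C", "C",
    "A", "A", "A",
    "A", "A", "C",
    "C", "A", "C",
    "A", "A", "A",
    "C", "A", "A",
    "A", "C", "C",
    "C", "A", "C",
    "C", "C", "C",
    "A", "C", "A",
    "C", "A", "A",
    "C", "C", "A",
    "A", "A", "C",
    "A", "C", "A",
    "C", "C", "A",
    "C", "C", "C",
    "C", "C", "A",
    "C", "A", "A",
    "A", "C", "C",
    "C", "A", "C"
  ),
  nrow = 24, ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("education", "screening", "environment"))
)

#' The PRALIMAP-shaped programme preset
#'
#' A 24-high-school, 3-strategy (education, screening, environment),
#' 2-period programme with 12 active settings per strategy, reproducing the
#' published allocation pattern of the trial: 72 IRGs of which 36 active.
#'
#' @return `pralimap_programme()`: an [programme()] object;
#'   `pralimap_assignment()`: the matching [strategy_assignment()] tibble.
#' @export
pralimap_programme <- function() {
  programme(
    settings = sprintf("school_%02d", 1:24),
    interventions = colnames(.pralimap_pattern),
    periods = c("year_1", "year_2"),
    mas = 20
  )
}

#' @rdname pralimap_programme
#' @export
pralimap_assignment <- function() {
  strategy_assignment(tibble::tibble(
    setting = rep(sprintf("school_%02d", 1:24), each = 3),
    intervention = rep(colnames(.pralimap_pattern), times = 24),
    status = ifelse(t(.pralimap_pattern) == "A", "active", "control")[
      seq_len(72)
    ]
  ))
}

#' Configuration of a synthetic expert-panel study
#'
#' Collects the generator parameters: programme shape, expert-panel
#' structure, rater noise, expert-group offsets and true-score model. The
#' defaults emulate a study of the published shape -- 24 settings, three
#' strategies with 12 active settings each, two periods, a 0--20 score
#' scale, three groups of six experts -- with true scores whose implied mean
#' doses sit in the reported 5--9 range and group offsets straddling the
#' reported 0.8--2.8-point adjustments.
#'
#' @param n_settings Number of settings.
#' @param interventions Named integer vector: number of active settings per
#'   intervention.
#' @param n_periods Number of intervention periods.
#' @param mas Common maximal assignable score.
#' @param n_groups Number of expert groups.
#' @param experts_per_group Experts per group (>= 2).
#' @param rater_sd Independent rater noise SD, in score units (>= 0).
#' @param group_offsets Additive expert-group effects (length `n_groups`,
#'   sum 0).
#' @param true_mean Named vector `c(NPDA = , PDA = )` of true-score means.
#' @param true_sd Between-IRG true-score SD.
#' @param period_decay Drop in the true-score mean per successive period
#'   (implementation fatigue).
#' @param interaction Shift added to the generating mean, in score units,
#'   for the cells of `interaction_pair` strategies in settings active in
#'   both (negative = antagonism).
#' @param interaction_pair Character vector of two intervention ids, or
#'   `NULL`.
#' @param fictitious_mean True-score mean of the fictitious calibration IRG.
#' @param sd_threshold,range_threshold Debate thresholds (see
#'   [flag_for_debate()]).
#' @param seed Default seed used by the generators when they are not given
#'   one explicitly.
#'
#' @return A list of class `irg_sim_config`.
#' @export
simulation_config <- function(n_settings = 24,
                              interventions = c(
                                education = 12, screening = 12,
                                environment = 12
                              ),
                              n_periods = 2, mas = 20,
                              n_groups = 3, experts_per_group = 6,
                              rater_sd = 2,
                              group_offsets = c(-2, 0, 2),
                              true_mean = c(NPDA = 11.5, PDA = 12.5),
                              true_sd = 2.5, period_decay = 1,
                              interaction = 0, interaction_pair = NULL,
                              fictitious_mean = 12,
                              sd_threshold = 2.5, range_threshold = 6,
                              seed = NULL) {
  if (is.null(names(interventions)) || any(!nzchar(names(interventions)))) {
    stop_irg("interventions must be a named vector of active-setting counts",
      class = "irgdose_invalid_config"
    )
  }
  if (any(interventions > n_settings) || any(interventions < 0)) {
    stop_irg("active-setting counts must lie in [0, n_settings]",
      class = "irgdose_invalid_config"
    )
  }
  if (experts_per_group < 2) {
    stop_irg("experts_per_group must be >= 2", class = "irgdose_invalid_config")
  }
  if (rater_sd < 0 || true_sd < 0) {
    stop_irg("rater_sd and true_sd must be >= 0",
      class = "irgdose_invalid_config"
    )
  }
  if (length(group_offsets) != n_groups ||
    abs(sum(group_offsets)) > 1e-8) {
    stop_irg("group_offsets must have length n_groups and sum to 0",
      class = "irgdose_invalid_config"
    )
  }
  if (!all(c("NPDA", "PDA") %in% names(true_mean))) {
    stop_irg("true_mean needs named entries NPDA and PDA",
      class = "irgdose_invalid_config"
    )
  }
  if (!is.null(interaction_pair) && length(interaction_pair) != 2) {
    stop_irg("interaction_pair must name exactly two interventions",
      class = "irgdose_invalid_config"
    )
  }
  structure(
    list(
      n_settings = n_settings, interventions = interventions,
      n_periods = n_periods, mas = mas, n_groups = n_groups,
      experts_per_group = experts_per_group, rater_sd = rater_sd,
      group_offsets = group_offsets, true_mean = true_mean,
      true_sd = true_sd, period_decay = period_decay,
      interaction = interaction, interaction_pair = interaction_pair,
      fictitious_mean = fictitious_mean,
      sd_threshold = sd_threshold, range_threshold = range_threshold,
      seed = seed
    ),
    class = "irg_sim_config"
  )
}

#' Generate a programme and its strategy assignment
#'
#' With `preset = "pralimap"`, returns the fixed published allocation (see
#' [pralimap_programme()]); otherwise, samples the requested number of
#' active settings per intervention uniformly at random.
#'
#' @param config An [simulation_config()] object.
#' @param seed Optional seed (defaults to `config$seed`).
#' @param preset `NULL` or `"pralimap"`.
#'
#' @return List with elements `programme` and `assignment`.
#' @export
generate_programme <- function(config = simulation_config(), seed = config$seed,
                               preset = NULL) {
  if (!is.null(preset)) {
    if (!identical(preset, "pralimap")) {
      stop_irg("unknown preset: ", preset, class = "irgdose_invalid_config")
    }
    return(list(
      programme = pralimap_programme(),
      assignment = pralimap_assignment()
    ))
  }
  stopifnot(inherits(config, "irg_sim_config"))
  settings <- sprintf("setting_%02d", seq_len(config$n_settings))
  prog <- programme(
    settings = settings,
    interventions = names(config$interventions),
    periods = sprintf("period_%d", seq_len(config$n_periods)),
    mas = config$mas
  )
  assignment <- local_seed(seed, {
    dplyr::bind_rows(lapply(names(config$interventions), function(iv) {
      active <- sample(settings, config$interventions[[iv]])
      tibble::tibble(
        setting = settings, intervention = iv,
        status = ifelse(settings %in% active, "active", "control")
      )
    }))
  })
  list(programme = prog, assignment = strategy_assignment(assignment))
}

#' Generate per-cell true implementation scores
#'
#' Each (IRG, activity class, period, domain, declension) cell receives a
#' true score drawn from a normal distribution with a class- and
#' period-specific mean (later periods decay by `period_decay`), clamped to
#' `[0, mas]`. Settings active in both `interaction_pair` strategies have
#' the `interaction` shift added to the generating mean of those
#' strategies' cells, making their truth depart from additivity by
#' construction. A fictitious calibration IRG (NPDA only) is appended with
#' its own fixed-mean cells.
#'
#' @param programme An [programme()] object.
#' @param assignment Matching [strategy_assignment()] table.
#' @param config An [simulation_config()] object.
#' @param seed Optional seed (defaults to `config$seed`).
#'
#' @return Tibble with the cell key columns, `status` and `truth`.
#' @export
generate_true_scores <- function(programme, assignment,
                                 config = simulation_config(),
                                 seed = config$seed) {
  stopifnot(inherits(programme, "irg_programme"))
  stopifnot(inherits(config, "irg_sim_config"))
  irgs <- enumerate_irgs(programme, assignment)
  sheets <- plan_report_sheets(irgs) # one NPDA per IRG + one PDA per IRG-A
  cells <- tidyr::expand_grid(
    sheets,
    period = programme$periods,
    domain = c("delivery", "participation"),
    declension = c("quantity", "quality")
  )
  period_idx <- match(cells$period, programme$periods)
  mu <- unname(config$true_mean[cells$activity_class]) -
    config$period_decay * (period_idx - 1)
  if (!is.null(config$interaction_pair) && config$interaction != 0) {
    pair <- config$interaction_pair
    both_active <- assignment |>
      dplyr::filter(
        .data$intervention %in% pair,
        .data$status == "active"
      ) |>
      dplyr::count(.data$setting) |>
      dplyr::filter(.data$n == 2)
    hit <- cells$setting %in% both_active$setting &
      cells$intervention %in% pair
    mu[hit] <- mu[hit] + config$interaction
  }
  fict <- tidyr::expand_grid(
    setting = FICTITIOUS_SETTING, intervention = "fictitious",
    status = "control", activity_class = "NPDA",
    period = programme$periods,
    domain = c("delivery", "participation"),
    declension = c("quantity", "quality")
  )
  local_seed(seed, {
    cells$truth <- clamp(
      stats::rnorm(nrow(cells), mean = mu, sd = config$true_sd),
      0, programme$mas
    )
    fict$truth <- clamp(
      stats::rnorm(nrow(fict), mean = config$fictitious_mean, sd = config$true_sd),
      0, programme$mas
    )
    dplyr::bind_rows(cells, fict)
  })
}

#' Generate expert-panel scores around a synthetic truth
#'
#' Real IRGs are distributed fairly among the expert groups; the fictitious
#' IRG is scored by every group. Each expert's round-1 score is
#' `truth + group offset + N(0, rater_sd)`, clamped to `[0, mas]`. Cells
#' that the debate rule flags (see [flag_for_debate()]) receive round-2
#' scores drawn with half the rater noise around `truth + offset`,
#' emulating the convergence a moderated debate produces.
#'
#' @param truth Truth table from [generate_true_scores()].
#' @param config An [simulation_config()] object.
#' @param seed Optional seed (defaults to `config$seed`).
#'
#' @return Expert-score tibble (`expert_id`, `group_id`, cell keys,
#'   `status`, `round`, `value`).
#' @export
generate_expert_scores <- function(truth, config = simulation_config(),
                                   seed = config$seed) {
  stopifnot(inherits(config, "irg_sim_config"))
  check_columns(truth, c(CELL_COLS, "status", "truth"), what = "truth")
  group_ids <- sprintf("group_%d", seq_len(config$n_groups))
  offsets <- stats::setNames(config$group_offsets, group_ids)
  local_seed(seed, {
    real <- dplyr::filter(truth, .data$setting != FICTITIOUS_SETTING)
    fict <- dplyr::filter(truth, .data$setting == FICTITIOUS_SETTING)
    alloc <- distribute_irgs(
      dplyr::distinct(real, .data$setting, .data$intervention, .data$status),
      group_ids
    )
    real <- dplyr::left_join(real, alloc,
      by = c("setting", "intervention", "status")
    )
    fict <- tidyr::expand_grid(group_id = group_ids, fict)
    cells <- dplyr::bind_rows(real, fict)
    expert_groups <- rep(group_ids, each = config$experts_per_group)
    experts <- tibble::tibble(
      group_id = expert_groups,
      expert_id = sprintf(
        "%s_e%d", expert_groups,
        rep(seq_len(config$experts_per_group), times = config$n_groups)
      )
    )
    r1 <- dplyr::inner_join(cells, experts,
      by = "group_id", relationship = "many-to-many"
    )
    r1$round <- 1
    r1$value <- clamp(
      r1$truth + unname(offsets[r1$group_id]) +
        stats::rnorm(nrow(r1), 0, config$rater_sd),
      0, config$mas
    )
    summ <- summarize_scores(
      dplyr::select(r1, -"truth"),
      sd_threshold = config$sd_threshold,
      range_threshold = config$range_threshold
    )
    flagged <- dplyr::filter(summ, .data$flagged)
    r2 <- dplyr::semi_join(r1, flagged, by = c(CELL_COLS, "group_id"))
    if (nrow(r2) > 0) {
      r2$round <- 2
      r2$value <- clamp(
        r2$truth + unname(offsets[r2$group_id]) +
          stats::rnorm(nrow(r2), 0, config$rater_sd / 2),
        0, config$mas
      )
    } else {
      r2 <- r1[0, ]
    }
    out <- dplyr::bind_rows(r1, r2)
    cols <- c(
      "expert_id", "group_id", CELL_COLS, "status", "round", "value"
    )
    dplyr::arrange(
      out[cols],
      .data$setting, .data$intervention, .data$activity_class,
      .data$period, .data$domain, .data$declension,
      .data$round, .data$expert_id
    )
  })
}

#' Generate a target-person roster
#'
#' @param programme An [programme()] object.
#' @param targets_per_setting Number of target persons per setting (>= 0).
#' @param seed Kept for interface symmetry; identifiers are deterministic.
#'
#' @return Tibble with columns `target_id`, `setting`.
#' @export
generate_roster <- function(programme, targets_per_setting, seed = NULL) {
  stopifnot(inherits(programme, "irg_programme"))
  if (targets_per_setting < 0) {
    stop_irg("targets_per_setting must be >= 0", class = "irgdose_invalid_config")
  }
  if (targets_per_setting == 0) {
    return(tibble::tibble(target_id = character(0), setting = character(0)))
  }
  setting <- rep(programme$settings, each = targets_per_setting)
  tibble::tibble(
    target_id = sprintf(
      "%s_t%03d", setting,
      rep(seq_len(targets_per_setting), times = length(programme$settings))
    ),
    setting = setting
  )
}

#' Doses implied directly by a synthetic truth
#'
#' Bypasses the expert panel: pivots the true cell scores into score sets
#' and applies the dose formula. Used to check that the full scoring
#' pipeline is exact when rater noise and group offsets are zero.
#'
#' @param truth Truth table from [generate_true_scores()].
#' @param mas Common maximal assignable score.
#'
#' @return Dose table as from [compute_all_doses()].
#' @export
doses_from_truth <- function(truth, mas = 20) {
  check_columns(truth, c(CELL_COLS, "status", "truth"), what = "truth")
  real <- dplyr::filter(truth, .data$setting != FICTITIOUS_SETTING)
  sets <- build_score_sets(
    dplyr::rename(real, score = "truth"),
    mas = mas
  )
  compute_all_doses(sets)
}

#' Additive factorial cell means
#'
#' Helper building the four cell means of a 2 x 2 strategy design from a
#' baseline, two main effects and an interaction:
#' `both = baseline + effect_a + effect_b + interaction`.
#'
#' @param baseline Dose mean of settings active in neither strategy.
#' @param effect_a,effect_b Main effects of the two strategies.
#' @param interaction Departure from additivity in the "both" cell.
#'
#' @return Named numeric vector `(neither, a_only, b_only, both)`.
#' @export
additive_cell_means <- function(baseline = 4, effect_a = 3, effect_b = 2,
                                interaction = 0) {
  c(
    neither = baseline, a_only = baseline + effect_a,
    b_only = baseline + effect_b,
    both = baseline + effect_a + effect_b + interaction
  )
}

#' Simulate dose tables from a 2 x 2 factorial design
#'
#' Dose-scale generator for validating the analysis stage: settings are
#' split evenly over the four cells of a two-strategy factorial design and
#' each strategy's dose is the cell mean plus independent normal noise,
#' clamped to `[0, mas]`.
#'
#' @param n_per_cell Settings per factorial cell.
#' @param cell_means Named vector `(neither, a_only, b_only, both)`; see
#'   [additive_cell_means()].
#' @param noise_sd Dose-scale noise SD.
#' @param strategies Identifiers of the two strategies.
#' @param activity_class,period Labels stamped on the rows.
#' @param mas Clamp bound.
#' @param seed Optional seed.
#'
#' @return Dose table (`setting`, `intervention`, `status`,
#'   `activity_class`, `period`, `dose`) with rows for both strategies.
#' @export
simulate_factorial_doses <- function(n_per_cell = 6,
                                     cell_means = additive_cell_means(),
                                     noise_sd = 0.5,
                                     strategies = c("A", "B"),
                                     activity_class = "NPDA", period = "p1",
                                     mas = 20, seed = NULL) {
  stopifnot(
    length(strategies) == 2,
    all(c("neither", "a_only", "b_only", "both") %in% names(cell_means))
  )
  cell <- rep(c("neither", "a_only", "b_only", "both"), each = n_per_cell)
  settings <- sprintf("s_%02d", seq_along(cell))
  a_active <- cell %in% c("a_only", "both")
  b_active <- cell %in% c("b_only", "both")
  base <- tibble::tibble(
    setting = rep(settings, 2),
    intervention = rep(strategies, each = length(settings)),
    status = ifelse(c(a_active, b_active), "active", "control"),
    activity_class = activity_class,
    period = period,
    mu = rep(unname(cell_means[cell]), 2)
  )
  local_seed(seed, {
    base$dose <- clamp(
      stats::rnorm(nrow(base), base$mu, noise_sd), 0, mas
    )
    dplyr::select(base, -"mu")
  })
}
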