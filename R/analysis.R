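#' Descriptive summary of intervention doses
#'
#' One row per grouping cell with the distribution parameters used in
#' implementation reports: N, mean, sample standard deviation, median,
#' quartiles (linear interpolation between order statistics), min and max.
#' With a single dose in a cell the standard deviation is reported as 0 and
#' `N = 1` flags it as degenerate.
#'
#' @param doses Dose table with a `dose` column.
#' @param by Character vector of grouping columns; default
#'   `c("intervention", "activity_class", "period")`, the strategy x
#'   activity-class x period cells of a global description table.
#'
#' @return Tibble with the grouping columns plus `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `min`, `max`.
#' @export
describe_doses <- function(doses,
                           by = c("intervention", "activity_class", "period")) {
  check_columns(doses, c(by, "dose"), what = "doses")
  if (nrow(doses) == 0) {
    empty <- tibble::as_tibble(doses)[0, by]
    for (col in c("n", "mean", "sd", "median", "q1", "q3", "min", "max")) {
      empty[[col]] <- numeric(0)
    }
    return(empty)
  }
  doses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$dose),
      sd = if (dplyr::n() > 1) stats::sd(.data$dose) else 0,
      median = stats::median(.data$dose),
      q1 = unname(stats::quantile(.data$dose, 0.25, type = 7)),
      q3 = unname(stats::quantile(.data$dose, 0.75, type = 7)),
      min = min(.data$dose),
      max = max(.data$dose),
      .groups = "drop"
    )
}

# two-sided permutation p-value with the add-one rule; never exactly zero
perm_pvalue <- function(perm_stats, observed) {
  (1 + sum(abs(perm_stats) >= abs(observed) - 1e-12)) /
    (length(perm_stats) + 1)
}

check_n_perm <- function(n_perm) {
  if (!is.numeric(n_perm) || length(n_perm) != 1 || n_perm < 99) {
    stop_irg("n_perm must be a single number >= 99",
      class = "irgdose_bad_input"
    )
  }
  as.integer(n_perm)
}

#' Active-versus-control dose contrast for one strategy
#'
#' Compares the mean dose of the settings assigned a strategy (IRG-Active)
#' with the mean dose of its controls, for one activity class and period.
#' By default the non-programme-driven activities dose is contrasted: it is
#' the only dose class defined on both arms. Inference is by a two-sided
#' permutation test that shuffles active/control labels at the setting
#' (cluster) level, with the add-one rule `(b + 1) / (n_perm + 1)`.
#'
#' @param doses Dose table from [compute_all_doses()].
#' @param strategy Intervention identifier to contrast.
#' @param activity_class `"NPDA"` (default) or `"PDA"`.
#' @param period Period identifier.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Optional integer seed; same seed, same p-value.
#'
#' @return One-row tibble: `strategy`, `activity_class`, `period`,
#'   `n_active`, `n_control`, `mean_active`, `mean_control`, `difference`,
#'   `p_value`, `n_perm`.
#' @export
compare_active_control <- function(doses, strategy, activity_class = "NPDA",
                                   period, n_perm = 999, seed = NULL) {
  check_columns(doses, c(
    "setting", "intervention", "status",
    "activity_class", "period", "dose"
  ), what = "doses")
  n_perm <- check_n_perm(n_perm)
  d <- dplyr::filter(
    doses,
    .data$intervention == strategy,
    .data$activity_class == !!activity_class,
    .data$period == !!period
  )
  act <- d$status == "active"
  if (sum(act) == 0 || sum(!act) == 0) {
    stop_irg(
      "both an active and a control arm are required for strategy '",
      strategy, "', class ", activity_class, ", period ", period,
      class = "irgdose_insufficient_group"
    )
  }
  vals <- d$dose
  n_a <- sum(act)
  observed <- mean(vals[act]) - mean(vals[!act])
  perm <- local_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(vals), n_a)
    mean(vals[idx]) - mean(vals[-idx])
  }, numeric(1)))
  tibble::tibble(
    strategy = strategy, activity_class = activity_class, period = period,
    n_active = n_a, n_control = sum(!act),
    mean_active = mean(vals[act]), mean_control = mean(vals[!act]),
    difference = observed,
    p_value = perm_pvalue(perm, observed),
    n_perm = n_perm
  )
}

#' Between-strategy interaction on the dose scale
#'
#' Settings are classified by their assignment to two strategies into the
#' four factorial cells (neither, A-only, B-only, both). The response is the
#' dose of `response` (default `strategy_a`) for the given activity class
#' and period, and the interaction is the departure of the "both" cell from
#' the additive expectation:
#'
#' \deqn{I = \bar d_{both} - (\bar d_{A\,only} + \bar d_{B\,only} - \bar d_{neither})}
#'
#' Negative values indicate sub-additivity (antagonism between the two
#' strategies), positive values synergy. Inference is by permutation of
#' strategy B's labels within the strata of strategy A, two-sided, add-one
#' rule.
#'
#' @param doses Dose table containing rows for both strategies (strategy B's
#'   rows supply its active/control status per setting).
#' @param strategy_a,strategy_b The two intervention identifiers.
#' @param activity_class,period Dose class and period of the response.
#' @param response Strategy whose dose is the response; default
#'   `strategy_a`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed.
#'
#' @return One-row tibble: strategies, class, period, cell means
#'   (`mean_neither`, `mean_a_only`, `mean_b_only`, `mean_both`), cell
#'   sizes, `interaction`, `p_value`, `n_perm`.
#' @export
interaction_analysis <- function(doses, strategy_a, strategy_b,
                                 activity_class = "NPDA", period,
                                 response = strategy_a,
                                 n_perm = 999, seed = NULL) {
  check_columns(doses, c(
    "setting", "intervention", "status",
    "activity_class", "period", "dose"
  ), what = "doses")
  n_perm <- check_n_perm(n_perm)
  resp <- dplyr::filter(
    doses,
    .data$intervention == response,
    .data$activity_class == !!activity_class,
    .data$period == !!period
  )
  status_of <- function(strategy) {
    s <- dplyr::distinct(
      dplyr::filter(doses, .data$intervention == strategy),
      .data$setting, .data$status
    )
    stats::setNames(s$status == "active", s$setting)
  }
  a_active <- status_of(strategy_a)
  b_active <- status_of(strategy_b)
  if (!all(resp$setting %in% names(a_active)) ||
    !all(resp$setting %in% names(b_active))) {
    stop_irg("dose table lacks assignment rows for one of the two strategies",
      class = "irgdose_bad_input"
    )
  }
  a <- unname(a_active[resp$setting])
  b <- unname(b_active[resp$setting])
  vals <- resp$dose
  cell_stat <- function(b_lab) {
    mean(vals[a & b_lab]) - mean(vals[a & !b_lab]) -
      mean(vals[!a & b_lab]) + mean(vals[!a & !b_lab])
  }
  cells <- table(factor(
    dplyr::case_when(
      a & b ~ "both", a ~ "a_only", b ~ "b_only", TRUE ~ "neither"
    ),
    levels = c("neither", "a_only", "b_only", "both")
  ))
  if (any(cells == 0)) {
    stop_irg(
      "degenerate design: empty factorial cell(s): ",
      paste(names(cells)[cells == 0], collapse = ", "),
      class = "irgdose_degenerate_design"
    )
  }
  observed <- cell_stat(b)
  perm <- local_seed(seed, vapply(seq_len(n_perm), function(i) {
    b_perm <- b
    b_perm[a] <- sample(b[a])
    b_perm[!a] <- sample(b[!a])
    cell_stat(b_perm)
  }, numeric(1)))
  tibble::tibble(
    strategy_a = strategy_a, strategy_b = strategy_b,
    response = response,
    activity_class = activity_class, period = period,
    n_neither = as.integer(cells[["neither"]]),
    n_a_only = as.integer(cells[["a_only"]]),
    n_b_only = as.integer(cells[["b_only"]]),
    n_both = as.integer(cells[["both"]]),
    mean_neither = mean(vals[!a & !b]),
    mean_a_only = mean(vals[a & !b]),
    mean_b_only = mean(vals[!a & b]),
    mean_both = mean(vals[a & b]),
    interaction = observed,
    p_value = perm_pvalue(perm, observed),
    n_perm = n_perm
  )
}
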