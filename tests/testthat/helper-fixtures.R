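# Shared fixtures: a small 3-setting x 2-intervention programme mirroring
# the worked IRG-identification example, and builders for toy score tables.

toy_programme <- function() {
  programme(
    settings = c("setting_1", "setting_2", "setting_3"),
    interventions = c("intervention_1", "intervention_2"),
    periods = "p1",
    mas = 20
  )
}

# intervention 1 active in settings 1-2, intervention 2 active in setting 3
toy_assignment <- function() {
  strategy_assignment(tibble::tibble(
    setting = rep(c("setting_1", "setting_2", "setting_3"), each = 2),
    intervention = rep(c("intervention_1", "intervention_2"), 3),
    status = c("active", "control", "active", "control", "control", "active")
  ))
}

# expert-score rows for a single cell
cell_scores <- function(values, round = 1, group_id = "g1",
                        setting = "setting_1",
                        intervention = "intervention_1",
                        activity_class = "NPDA", period = "p1",
                        domain = "delivery", declension = "quantity") {
  tibble::tibble(
    expert_id = sprintf("%s_e%d", group_id, seq_along(values)),
    group_id = group_id,
    setting = setting, intervention = intervention,
    activity_class = activity_class, period = period,
    domain = domain, declension = declension,
    round = round, value = values
  )
}

# a complete four-cell score table for one (IRG, class, period) triple,
# one value per cell scored by `n_experts` identical experts
full_triple_scores <- function(dqt, dql, pqt, pql, n_experts = 3, ...) {
  dplyr::bind_rows(
    cell_scores(rep(dqt, n_experts), domain = "delivery", declension = "quantity", ...),
    cell_scores(rep(dql, n_experts), domain = "delivery", declension = "quality", ...),
    cell_scores(rep(pqt, n_experts), domain = "participation", declension = "quantity", ...),
    cell_scores(rep(pql, n_experts), domain = "participation", declension = "quality", ...)
  )
}

expect_no_flags <- function(scores) {
  expect_false(any(summarize_scores(scores)$flagged))
}

# scratch paths under the session temp directory
scratch_file <- function(name) {
  file.path(tempdir(), paste0("irgdose-test-", name))
}

scratch_dir <- function() {
  path <- tempfile("irgdose-test-dir")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}
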