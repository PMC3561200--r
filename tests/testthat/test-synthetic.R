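test_that("programme generation respects the requested design", {
  gen <- generate_programme(preset = "pralimap")
  irgs <- enumerate_irgs(gen$programme, gen$assignment)
  expect_equal(nrow(irgs), 72)
  expect_equal(sum(irgs$status == "active"), 36)

  cfg <- simulation_config(
    n_settings = 5, interventions = c(x = 2, y = 4),
    n_periods = 1, group_offsets = c(0, 0, 0)
  )
  gen <- generate_programme(cfg, seed = 21)
  irgs <- enumerate_irgs(gen$programme, gen$assignment)
  expect_equal(nrow(irgs), 10)
  actives <- table(irgs$intervention[irgs$status == "active"])
  expect_equal(unname(actives[c("x", "y")]), c(2L, 4L), ignore_attr = TRUE)

  # same seed, same allocation
  gen2 <- generate_programme(cfg, seed = 21)
  expect_identical(gen$assignment, gen2$assignment)

  expect_error(
    simulation_config(n_settings = 3, interventions = c(x = 4)),
    class = "irgdose_invalid_config"
  )
  expect_error(
    simulation_config(group_offsets = c(1, 1, 1)),
    class = "irgdose_invalid_config"
  )
  expect_error(
    simulation_config(experts_per_group = 1),
    class = "irgdose_invalid_config"
  )
})

test_that("true scores follow the class/period means and are reproducible", {
  prog <- pralimap_programme()
  asg <- pralimap_assignment()
  # no variance, no decay: every cell equals its class mean
  cfg <- simulation_config(
    true_sd = 0, period_decay = 0,
    true_mean = c(NPDA = 9, PDA = 13), seed = 1
  )
  truth <- generate_true_scores(prog, asg, cfg)
  real <- dplyr::filter(truth, setting != FICTITIOUS_SETTING)
  expect_true(all(real$truth[real$activity_class == "NPDA"] == 9))
  expect_true(all(real$truth[real$activity_class == "PDA"] == 13))

  # decay lowers later periods by construction
  cfg <- simulation_config(true_sd = 0, period_decay = 2, seed = 1)
  truth <- generate_true_scores(prog, asg, cfg)
  real <- dplyr::filter(truth, setting != FICTITIOUS_SETTING, activity_class == "NPDA")
  expect_equal(
    unique(real$truth[real$period == "year_1"]) -
      unique(real$truth[real$period == "year_2"]),
    2
  )

  # interaction shift: combined-strategy settings sit 2 below additive
  cfg <- simulation_config(
    true_sd = 0, period_decay = 0, interaction = -2,
    interaction_pair = c("education", "environment"), seed = 1
  )
  truth <- generate_true_scores(prog, asg, cfg)
  both <- c("school_03", "school_04", "school_06", "school_09", "school_14", "school_18")
  hit <- dplyr::filter(
    truth, setting %in% both, intervention == "education",
    activity_class == "NPDA"
  )
  miss <- dplyr::filter(
    truth, setting == "school_01", intervention == "education",
    activity_class == "NPDA"
  )
  expect_equal(unique(hit$truth), unique(miss$truth) - 2)
  # screening untouched
  scr <- dplyr::filter(truth, setting %in% both, intervention == "screening")
  expect_equal(unique(scr$truth[scr$activity_class == "NPDA"]), unique(miss$truth))

  # seeded reproducibility
  cfg <- simulation_config(seed = 77)
  expect_identical(
    generate_true_scores(prog, asg, cfg),
    generate_true_scores(prog, asg, cfg)
  )
  # truth bounded by the score scale
  truth <- generate_true_scores(prog, asg, simulation_config(true_sd = 15, seed = 3))
  expect_true(all(truth$truth >= 0 & truth$truth <= 20))
})

test_that("expert scores are truth plus offset plus noise, clamped", {
  prog <- toy_programme()
  asg <- toy_assignment()
  cfg <- simulation_config(
    n_settings = 3, interventions = c(intervention_1 = 2, intervention_2 = 1),
    n_periods = 1, rater_sd = 0, group_offsets = c(0, 0, 0), seed = 4
  )
  truth <- generate_true_scores(prog, asg, cfg)
  scores <- generate_expert_scores(truth, cfg)
  # zero noise, zero offsets: every score equals its true score; nothing flagged
  joined <- dplyr::left_join(
    scores,
    dplyr::rename(truth, tv = truth),
    by = c("setting", "intervention", "status", "activity_class", "period", "domain", "declension")
  )
  expect_equal(joined$value, joined$tv)
  expect_true(all(scores$round == 1))

  # fictitious IRG scored by every group
  fict <- dplyr::filter(scores, setting == FICTITIOUS_SETTING)
  expect_equal(sort(unique(fict$group_id)), sprintf("group_%d", 1:3))

  # all outputs within [0, mas] even under huge noise
  cfg_noisy <- simulation_config(
    n_settings = 3, interventions = c(intervention_1 = 2, intervention_2 = 1),
    n_periods = 1, rater_sd = 15, seed = 4
  )
  noisy <- generate_expert_scores(generate_true_scores(prog, asg, cfg_noisy), cfg_noisy)
  expect_true(all(noisy$value >= 0 & noisy$value <= 20))
  # under heavy noise some cells get debated: round-2 rows exist
  expect_true(any(noisy$round == 2))

  # seeded reproducibility
  cfg5 <- simulation_config(seed = 5)
  t5 <- generate_true_scores(pralimap_programme(), pralimap_assignment(), cfg5)
  expect_identical(
    generate_expert_scores(t5, cfg5),
    generate_expert_scores(t5, cfg5)
  )
})

test_that("configured group offsets separate fictitious group means (large panel)", {
  prog <- toy_programme()
  asg <- toy_assignment()
  cfg <- simulation_config(
    n_settings = 3, interventions = c(intervention_1 = 2, intervention_2 = 1),
    n_periods = 1, experts_per_group = 500, rater_sd = 2,
    group_offsets = c(-2, 0, 2), fictitious_mean = 10, seed = 6
  )
  truth <- generate_true_scores(prog, asg, cfg)
  scores <- generate_expert_scores(truth, cfg)
  fict <- dplyr::filter(scores, setting == FICTITIOUS_SETTING, round == 1)
  means <- sort(tapply(fict$value, fict$group_id, mean))
  # by the law of large numbers the three means sit ~2 apart
  expect_equal(as.numeric(diff(means)), c(2, 2), tolerance = 0.1)
})

test_that("rosters enumerate unique targets per setting", {
  prog <- pralimap_programme()
  roster <- generate_roster(prog, 10)
  expect_equal(nrow(roster), 240)
  expect_false(anyDuplicated(roster$target_id) > 0)
  expect_equal(nrow(generate_roster(prog, 0)), 0)
  expect_identical(generate_roster(prog, 10), generate_roster(prog, 10))
})

test_that("noise-free pipeline reproduces the truth-implied doses exactly", {
  cfg <- simulation_config(rater_sd = 0, group_offsets = c(0, 0, 0), seed = 8)
  gen <- generate_programme(cfg, preset = "pralimap")
  truth <- generate_true_scores(gen$programme, gen$assignment, cfg)
  scores <- generate_expert_scores(truth, cfg)
  res <- dose_pipeline(scores, mas = cfg$mas)
  direct <- doses_from_truth(truth, mas = cfg$mas)
  keys <- c("setting", "intervention", "status", "activity_class", "period")
  merged <- dplyr::inner_join(res$doses, direct, by = keys, suffix = c("_pipe", "_direct"))
  expect_equal(nrow(merged), 216)
  expect_lt(max(abs(merged$dose_pipe - merged$dose_direct)), 1e-12)
  expect_equal(res$offsets$offset, rep(0, 3))
})
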