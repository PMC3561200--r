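test_that("IRG distribution over expert groups is balanced and reproducible", {
  irgs <- enumerate_irgs(pralimap_programme(), pralimap_assignment())
  alloc <- distribute_irgs(irgs, c("g1", "g2", "g3"), seed = 11)
  sizes <- table(alloc$group_id)
  expect_equal(unname(sizes), rep(24L, 3), ignore_attr = TRUE)
  expect_equal(nrow(alloc), 72) # every IRG allocated exactly once
  expect_identical(alloc, distribute_irgs(irgs, c("g1", "g2", "g3"), seed = 11))
  expect_false(identical(
    alloc$group_id,
    distribute_irgs(irgs, c("g1", "g2", "g3"), seed = 12)$group_id
  ))

  # sizes differ by at most one when not divisible
  alloc5 <- distribute_irgs(irgs[1:7, ], c("a", "b", "c"), seed = 1)
  expect_lte(diff(range(table(alloc5$group_id))), 1)
  # one group takes everything
  expect_equal(unique(distribute_irgs(irgs, "solo", seed = 1)$group_id), "solo")
  # empty list allocates nothing without error
  expect_equal(nrow(distribute_irgs(irgs[0, ], c("a", "b"))), 0)
})

test_that("cell summaries use the sample SD and max-minus-min range", {
  s <- summarize_cell(c(10, 12, 14, 16, 18, 20))
  expect_equal(s$mean, 15)
  expect_equal(s$sd, sqrt(14), tolerance = 1e-12) # 3.742 to 3 d.p.
  expect_equal(round(s$sd, 3), 3.742)
  expect_equal(s$range, 10)

  s <- summarize_cell(rep(13, 6))
  expect_equal(s$mean, 13)
  expect_equal(s$sd, 0)
  expect_equal(s$range, 0)

  expect_equal(summarize_cell(c(0, 20))$range, 20)
  expect_error(summarize_cell(5), class = "irgdose_insufficient_raters")
  mixed <- dplyr::bind_rows(
    cell_scores(c(1, 2)),
    cell_scores(c(3, 4), domain = "participation")
  )
  expect_error(summarize_cell(mixed), class = "irgdose_inconsistent_cell")
})

test_that("debate rule flags on strict SD or range threshold exceedance", {
  expect_true(flag_for_debate(sd = 2.6, range = 5))
  expect_false(flag_for_debate(sd = 2.5, range = 6)) # boundary: not flagged
  expect_true(flag_for_debate(sd = 0, range = 7)) # disjunction
  expect_false(flag_for_debate(sd = 0, range = 0))
  expect_error(flag_for_debate(1, 1, sd_threshold = 0), class = "irgdose_bad_input")
})

test_that("flagging is monotone in the spread of the scores", {
  set.seed(401)
  for (i in 1:50) {
    values <- round(runif(6, 0, 20), 1)
    s0 <- summarize_cell(values)
    f0 <- flag_for_debate(s0$sd, s0$range)
    # push the furthest-out score even further from the cell mean
    j <- which.max(abs(values - mean(values)))
    shifted <- values
    shifted[j] <- shifted[j] + sign(shifted[j] - mean(values) + 1e-9) * runif(1, 0, 5)
    s1 <- summarize_cell(shifted)
    expect_gte(s1$sd, s0$sd - 1e-9)
    expect_gte(s1$range, s0$range - 1e-9)
    if (f0) expect_true(flag_for_debate(s1$sd, s1$range))
  }
})

test_that("consolidation keeps the mean of the retained round", {
  expect_equal(consolidate_cell(c(8, 10, 12)), 10)
  expect_equal(consolidate_cell(c(2, 18, 7), round2 = c(14, 14, 14), flagged = TRUE), 14)
  # discrepant round-2 scores are preserved as their mean (no consensus needed)
  expect_equal(consolidate_cell(c(2, 18), round2 = c(10, 18), flagged = TRUE), 14)
  expect_error(
    consolidate_cell(c(8, 10), round2 = c(9, 9), flagged = FALSE),
    class = "irgdose_protocol_violation"
  )
})

test_that("consolidated scores stay within the contributing round's range", {
  set.seed(402)
  for (i in 1:50) {
    r1 <- runif(6, 0, 20)
    s <- summarize_cell(r1)
    flagged <- flag_for_debate(s$sd, s$range)
    r2 <- if (flagged) runif(6, 0, 20) else NULL
    final <- consolidate_cell(r1, r2, flagged)
    contributing <- if (is.null(r2)) r1 else r2
    expect_gte(final, min(contributing))
    expect_lte(final, max(contributing))
  }
})

test_that("table-level consolidation applies the protocol per cell and group", {
  tight <- cell_scores(c(10, 11, 12)) # sd 1, range 2: not flagged
  wide1 <- cell_scores(c(0, 10, 20), domain = "participation") # flagged
  wide2 <- dplyr::mutate(cell_scores(c(9, 9, 9), domain = "participation"), round = 2)
  cons <- consolidate_scores(dplyr::bind_rows(tight, wide1, wide2))
  expect_equal(nrow(cons), 2)
  expect_equal(cons$score[!cons$flagged], 11)
  expect_equal(cons$score[cons$flagged], 9)
  expect_true(all(cons$n_experts == 3))

  # round-2 rows on an unflagged cell violate the protocol
  bad <- dplyr::bind_rows(tight, dplyr::mutate(cell_scores(c(10, 10, 10)), round = 2))
  expect_error(consolidate_scores(bad), class = "irgdose_protocol_violation")
})

test_that("group offsets are deviations from the grand mean and sum to zero", {
  sc <- tibble::tibble(
    group_id = rep(c("g1", "g2", "g3"), each = 4),
    value = rep(c(12, 14, 16), each = 4)
  )
  off <- compute_group_offsets(sc)
  expect_equal(off$offset, c(-2, 0, 2))
  expect_equal(sum(off$offset), 0)

  two <- tibble::tibble(group_id = c("a", "a", "b", "b"), value = c(10, 10, 13, 13))
  expect_equal(compute_group_offsets(two)$offset, c(-1.5, 1.5))

  same <- tibble::tibble(group_id = c("a", "b"), value = c(9, 9))
  expect_equal(compute_group_offsets(same)$offset, c(0, 0))

  expect_error(
    compute_group_offsets(tibble::tibble(group_id = "only", value = 1)),
    class = "irgdose_incomplete_calibration"
  )
  # a group that skipped a fictitious cell breaks the calibration
  partial <- dplyr::bind_rows(
    cell_scores(c(10, 10), group_id = "g1", setting = FICTITIOUS_SETTING),
    cell_scores(c(12, 12),
      group_id = "g1", setting = FICTITIOUS_SETTING,
      domain = "participation"
    ),
    cell_scores(c(11, 11), group_id = "g2", setting = FICTITIOUS_SETTING)
  )
  expect_error(compute_group_offsets(partial),
    class = "irgdose_incomplete_calibration"
  )
})

test_that("calibration subtracts the group offset, clamps, and drops the fictitious IRG", {
  scores <- tibble::tibble(
    setting = c("s1", "s2", FICTITIOUS_SETTING),
    group_id = c("g1", "g2", "g1"),
    score = c(12, 1, 15)
  )
  offsets <- tibble::tibble(group_id = c("g1", "g2"), offset = c(2, 2))
  out <- apply_calibration(scores, offsets, mas = 20)
  expect_equal(nrow(out), 2) # fictitious row removed
  expect_equal(out$score, c(10, 0)) # 12-2 and clamp(1-2)
  # identity offsets leave scores unchanged
  out0 <- apply_calibration(scores, NULL, mas = 20)
  expect_equal(out0$score, c(12, 1))
  expect_error(
    apply_calibration(scores, tibble::tibble(group_id = "g1", offset = 0)),
    class = "irgdose_missing_offset"
  )
})

test_that("calibration equalises group means on the fictitious IRG", {
  set.seed(403)
  fict <- dplyr::bind_rows(lapply(c("g1", "g2", "g3"), function(g) {
    dplyr::bind_rows(
      cell_scores(runif(4, 0, 20), group_id = g, setting = FICTITIOUS_SETTING),
      cell_scores(runif(4, 0, 20),
        group_id = g, setting = FICTITIOUS_SETTING,
        domain = "participation"
      )
    )
  }))
  off <- compute_group_offsets(fict)
  calibrated <- dplyr::left_join(fict, off, by = "group_id")
  calibrated$value <- calibrated$value - calibrated$offset # no clamping here
  means <- tapply(calibrated$value, calibrated$group_id, mean)
  expect_equal(unname(diff(range(means))), 0, tolerance = 1e-12)
})

test_that("score sets gather the four cells and report incomplete triples", {
  cal <- dplyr::bind_rows(
    full_triple_scores(14, 12, 10, 8, n_experts = 1)
  )
  cal <- dplyr::rename(cal, score = value)[
    , c("setting", "intervention", "activity_class", "period", "domain", "declension", "score")
  ]
  sets <- build_score_sets(cal, mas = 20)
  expect_equal(nrow(sets), 1)
  expect_equal(unlist(sets[1, c("DQt", "DQl", "PQt", "PQl")], use.names = FALSE),
    c(14, 12, 10, 8))

  # 3 of 4 cells: skipped and reported
  expect_message(
    sets3 <- build_score_sets(cal[-1, ], mas = 20),
    "skipped"
  )
  expect_equal(nrow(sets3), 0)
  expect_equal(nrow(attr(sets3, "incomplete")), 1)

  # duplicate cells must be consolidated first
  expect_error(build_score_sets(dplyr::bind_rows(cal, cal[1, ])),
    class = "irgdose_bad_input"
  )
})

test_that("a complete study-scale score table yields one score set per triple", {
  # 72 NPDA + 36 PDA triples per period, two periods: 216 triples
  cfg <- simulation_config(rater_sd = 0, group_offsets = c(0, 0, 0), seed = 5)
  gen <- generate_programme(cfg, preset = "pralimap")
  truth <- generate_true_scores(gen$programme, gen$assignment, cfg)
  scores <- generate_expert_scores(truth, cfg)
  cons <- consolidate_scores(scores)
  cal <- apply_calibration(cons, compute_group_offsets(
    dplyr::filter(cons, setting == FICTITIOUS_SETTING)
  ))
  sets <- build_score_sets(cal)
  expect_equal(nrow(sets), 216)
  expect_equal(sum(sets$period == "year_1"), 108)
})
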