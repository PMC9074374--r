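test_that("degenerate cohorts honour their generating parameters", {
  p0 <- toy_params(margin_r0 = list(navigated = fx(1), standard = fx(1)))
  coh <- generate_cohort(p0, n_per_arm = 200, seed = 1)
  expect_true(all(coh$margin_status == "R0"))
  expect_true(all(is.na(coh$progression_cycle)))
  expect_true(all(is.na(coh$death_cycle)))
  expect_equal(nrow(coh), 400)

  # forced early-metastasis fraction
  pm <- toy_params()
  coh <- generate_cohort(pm, n_per_arm = 400, seed = 2, metastatic_fraction = 0.3)
  expect_true(all(coh$progression_cycle[!is.na(coh$progression_cycle)] == 1))
  expect_lt(abs(mean(!is.na(coh$progression_cycle)) - 0.3), 3 * sqrt(0.3 * 0.7 / 800))
})

test_that("cohort generation is reproducible by seed and respects invariants", {
  a <- generate_cohort(lrrc, n_per_arm = 500, seed = 10)
  b <- generate_cohort(lrrc, n_per_arm = 500, seed = 10)
  expect_identical(a, b)
  c <- generate_cohort(lrrc, n_per_arm = 500, seed = 11)
  expect_false(identical(a, c))
  # death after progression never precedes progression; cycles within horizon
  crc <- a[!is.na(a$death_cycle) & a$death_cause == "progression", ]
  expect_true(all(crc$death_cycle >= crc$progression_cycle))
  expect_true(all(a$death_cycle <= a$censor_cycle, na.rm = TRUE))
  expect_true(all(a$progression_cycle >= 1, na.rm = TRUE))
  # disjoint seeds give independent margin draws (chi-square sanity check,
  # within one arm so the arms' different R0 rates cannot masquerade as
  # dependence)
  nav_a <- a$margin_status[a$strategy == "navigated"]
  nav_c <- c$margin_status[c$strategy == "navigated"]
  expect_gt(suppressWarnings(chisq.test(table(nav_a, nav_c))$p.value), 1e-4)
})

test_that("count summaries match a hand tally on a hand-built cohort", {
  cohort <- tibble::tibble(
    patient_id = 1:5,
    indication = "TOY",
    strategy = c("navigated", "navigated", "standard", "standard", "standard"),
    margin_status = c("R0", "R1", "R0", "R0", "R1"),
    progression_cycle = c(2L, 6L, NA, 10L, 3L),
    death_cycle = c(7L, NA, 4L, NA, 12L),
    death_cause = c("progression", NA, "background", NA, "progression"),
    censor_cycle = 12L
  )
  counts <- summarize_counts(cohort)
  cell <- function(nm) counts[counts$cell == nm, ]
  expect_equal(cell("margin_r0_navigated")$events, 1)
  expect_equal(cell("margin_r0_navigated")$at_risk, 2)
  expect_equal(cell("margin_r0_standard")$events, 2)
  # R0 year 1: patients 1, 3, 4 start; patient 1 progresses (cycle 2)
  expect_equal(cell("progression_r0_year1")$events, 1)
  expect_equal(cell("progression_r0_year1")$at_risk, 3)
  # year 2: patient 3 died of background causes in year 1 (cycle 4), so only
  # patient 4 remains at risk and does not progress until year 3
  expect_equal(cell("progression_r0_year2")$at_risk, 1)
  expect_equal(cell("progression_r0_year2")$events, 0)
  expect_equal(cell("progression_r0_year3")$events, 1)
  # R1: patient 5 progresses in year 1, patient 2 in year 2
  expect_equal(cell("progression_r1_year1")$events, 1)
  expect_equal(cell("progression_r1_year1")$at_risk, 2)
  expect_equal(cell("progression_r1_year23")$events, 1)
  expect_equal(cell("progression_r1_year23")$at_risk, 1)
  # deaths: year-1 entrants are patients 1 (dies 5 cycles later) and 5
  # (dies 9 cycles later, outside the 8-cycle window)
  expect_equal(cell("death_after_progression_year1")$at_risk, 2)
  expect_equal(cell("death_after_progression_year1")$events, 1)
  # year-2/3 entrant window: patient 2 (cycle 6) never dies; patient 4
  # entered too late (cycle 10) for a full year of follow-up
  expect_equal(cell("death_after_progression_year23")$at_risk, 1)
  expect_equal(cell("death_after_progression_year23")$events, 0)
})

test_that("empty cohorts summarise to zero cells with zero risk sets", {
  empty <- generate_cohort(toy_params(), n_per_arm = 1, seed = 1)[0, ]
  counts <- summarize_counts(empty)
  expect_true(all(counts$events == 0))
  expect_true(all(counts$at_risk == 0))
})

test_that("risk sets are nested year on year", {
  coh <- generate_cohort(lrrc, n_per_arm = 5000, seed = 20)
  counts <- summarize_counts(coh)
  cell <- function(nm) counts[counts$cell == nm, ]
  for (tag in c("r0", "r1")) {
    y1 <- cell(sprintf("progression_%s_year1", tag))
    y2 <- cell(sprintf("progression_%s_year2", tag))
    # the year-2 risk set is the year-1 risk set minus year-1 progressions
    # and the (few) background deaths
    expect_lte(y2$at_risk, y1$at_risk - y1$events)
    expect_gt(y2$at_risk, (y1$at_risk - y1$events) * 0.95)
  }
})

test_that("the empirical year-1 progression fraction matches the generative risk", {
  n <- 50000
  coh <- generate_cohort(lrrc, n_per_arm = n, seed = 30)
  counts <- summarize_counts(coh)
  y1 <- counts[counts$cell == "progression_r0_year1", ]
  # closed-form oracle for the generator's marginal year-1 progression
  # probability with competing background mortality
  p <- 0.159
  bg <- 0.0044
  implied <- p * sum((1 - p - bg)^(0:3))
  se <- sqrt(implied * (1 - implied) / y1$at_risk)
  expect_lt(abs(y1$events / y1$at_risk - implied), 3 * se)
})

test_that("generation, summarising and conversion recover the parameters", {
  # background mortality is nationally sourced rather than cohort-estimated;
  # switching it off makes the annualised conversion exact in expectation
  p <- load_parameter_set(utils::modifyList(
    yaml::read_yaml(navcea_example("lrrc")),
    list(transitions = list(df_to_death = list(family = "fixed", mean = 0, se = 0)))
  ))
  n <- 50000
  coh <- generate_cohort(p, n_per_arm = n, seed = 40)
  counts <- summarize_counts(coh)
  recover <- function(nm) {
    row <- counts[counts$cell == nm, ]
    est <- observed_to_cycle_prob(row$events, row$at_risk, row$observation_time)
    chance <- row$events / row$at_risk
    se_chance <- sqrt(chance * (1 - chance) / row$at_risk)
    # delta method through the rate transform
    slope <- (0.25 / row$observation_time) *
      (1 - chance)^(0.25 / row$observation_time - 1)
    list(est = est, se = se_chance * slope)
  }
  truth <- c(
    progression_r0_year1 = 0.159, progression_r0_year23 = 0.100,
    progression_r1_year1 = 0.252, progression_r1_year23 = 0.159,
    death_after_progression_year1 = 0.135,
    death_after_progression_year23 = 0.089
  )
  # death cells use fixed post-entry windows (2y and 1y)
  obs_time <- c(1, 2, 1, 2, 2, 1)
  for (i in seq_along(truth)) {
    nm <- names(truth)[i]
    row <- counts[counts$cell == nm, ]
    expect_equal(row$observation_time, obs_time[i])
    r <- recover(nm)
    expect_lt(abs(r$est - truth[[nm]]), 3 * r$se)
  }
  # margin rates recover binomially
  for (s in c("navigated", "standard")) {
    row <- counts[counts$cell == paste0("margin_r0_", s), ]
    truth_m <- p$margin_r0[[s]]$mean
    se <- sqrt(truth_m * (1 - truth_m) / row$at_risk)
    expect_lt(abs(row$events / row$at_risk - truth_m), 3 * se)
  }
})
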