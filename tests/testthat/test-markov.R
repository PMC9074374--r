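test_that("degenerate hazards produce the expected traces", {
  p0 <- toy_params()
  tr <- run_markov_branch(p0, "R0")
  expect_equal(tr$disease_free, rep(1, 13))
  expect_equal(tr$dead, rep(0, 13))

  # absorbing flush: certain progression in year 1, no deaths
  pf <- toy_params(transitions = list(df_to_pd = list(
    R0 = list(year1 = fx(1), year2 = fx(0), year3 = fx(0))
  )))
  tr <- run_markov_branch(pf, "R0")
  expect_equal(tr$disease_free[2], 0)
  expect_equal(tr$pd_year1_entrants[2], 1)
  expect_equal(tr$new_progression[2], 1)
  expect_equal(tr$pd_year1_entrants[13], 1)
})

test_that("cohort occupancies conserve mass and death is absorbing", {
  for (p in list(larc, lrrc)) {
    for (mg in c("R0", "R1")) {
      tr <- run_markov_branch(p, mg)
      total <- tr$disease_free + tr$pd_year1_entrants +
        tr$pd_year23_entrants + tr$dead
      expect_lt(max(abs(total - 1)), 1e-12)
      expect_true(all(diff(tr$dead) >= 0))
      expect_true(all(as.matrix(tr[, 2:5]) >= 0))
      expect_equal(tr$disease_free[1], 1)
    }
  }
})

test_that("the trace matches the closed-form survival product for the LARC R0 branch", {
  tr <- run_markov_branch(larc, "R0")
  # independent oracle: DF occupancy is a product of per-cycle stay
  # probabilities (no re-entry into disease-free)
  stay <- c(rep(1 - 0.103 - 0.0028, 4), rep(1 - 0.047 - 0.0028, 4), rep(1 - 0.013 - 0.0028, 4))
  expect_equal(tr$disease_free[13], prod(stay), tolerance = 1e-12)
  expect_equal(round(tr$disease_free[13], 3), 0.489)
})

test_that("the engine agrees with a dense matrix-power oracle on random models", {
  set.seed(101)
  for (i in 1:20) {
    p_year <- runif(3, 0, 0.4)
    bg <- runif(1, 0, 0.05)
    d1 <- runif(1, 0, 0.5)
    d23 <- runif(1, 0, 0.5)
    params <- toy_params(transitions = list(
      df_to_pd = list(
        R0 = list(year1 = fx(p_year[1]), year2 = fx(p_year[2]), year3 = fx(p_year[3]))
      ),
      pd_to_death = list(entry_year1 = fx(d1), entry_year23 = fx(d23)),
      df_to_death = fx(bg)
    ))
    tr <- run_markov_branch(params, "R0")
    oracle <- matrix_power_trace(p_year, bg, d1, d23)
    expect_lt(max(abs(as.matrix(tr[, 2:5]) - oracle)), 1e-10)
  }
})

test_that("competing exits exceeding one are rejected with state and cycle", {
  bad <- toy_params(transitions = list(
    df_to_pd = list(R0 = list(year2 = fx(0.995))),
    df_to_death = fx(0.01)
  ))
  expect_error(run_markov_branch(bad, "R0"), "cycle 5")
})

test_that("accumulation satisfies closed-form identities", {
  # no deaths, utilities 1, no discounting: QALYs and LYs equal the horizon
  p0 <- toy_params()
  arm <- accumulate(run_markov_branch(p0, "R0"), p0, "standard")
  expect_equal(arm$qaly, 3)
  expect_equal(arm$ly, 3)
  expect_equal(arm$cost, 0)

  # single cycle fully disease-free at first-cycle utility 0.70
  p1 <- toy_params(horizon_cycles = 1, utilities = list(first_cycle = fx(0.70)))
  arm <- accumulate(run_markov_branch(p1, "R0"), p1, "standard")
  expect_equal(arm$qaly, 0.25 * 0.70)

  # discount-off equivalence: zero rates equal the plain sums of a toy trace
  p2 <- toy_params(
    transitions = list(df_to_pd = list(R0 = list(year1 = fx(0.2)))),
    utilities = list(
      first_cycle = fx(0.7), disease_free = fx(0.9),
      progressive_disease = fx(0.5)
    ),
    costs = list(state_df_per_cycle = fx(100), state_pd_per_cycle = fx(200), transition_df_to_pd = fx(1000))
  )
  tr <- run_markov_branch(p2, "R0")
  arm <- accumulate(tr, p2, "standard")
  df <- tr$disease_free[-1]
  pd <- tr$pd_year1_entrants[-1] + tr$pd_year23_entrants[-1]
  manual_q <- 0.25 * (0.7 * (df[1] + pd[1]) + sum(0.9 * df[-1] + 0.5 * pd[-1]))
  manual_c <- sum(100 * df + 200 * pd + 1000 * tr$new_progression[-1])
  expect_equal(arm$qaly, manual_q, tolerance = 1e-12)
  expect_equal(arm$cost, manual_c, tolerance = 1e-12)

  # intervention costs are charged once, undiscounted, per strategy
  p3 <- toy_params(costs = list(surgery = fx(10000), navigation_addition = fx(3000)))
  tr3 <- run_markov_branch(p3, "R0")
  expect_equal(accumulate(tr3, p3, "navigated")$cost, 13000)
  expect_equal(accumulate(tr3, p3, "standard")$cost, 10000)
})

test_that("QALYs never exceed life-years and life-years never exceed the horizon", {
  for (p in list(larc, lrrc)) {
    for (s in c("navigated", "standard")) {
      arm <- run_strategy(p, s)
      expect_lte(arm$qaly, arm$ly)
      expect_lte(arm$ly, p$horizon_cycles * p$cycle_length)
      expect_gte(arm$qaly, 0)
    }
  }
})

test_that("the decision tree mixes branches linearly in the margin rate", {
  # margin probability 1 reduces to the R0 branch
  p1 <- toy_params(
    margin_r0 = list(navigated = fx(1), standard = fx(1)),
    transitions = list(
      df_to_pd = list(
        R0 = list(year1 = fx(0.1)), R1 = list(year1 = fx(0.4))
      ),
      pd_to_death = list(entry_year1 = fx(0.2), entry_year23 = fx(0.1))
    ),
    utilities = list(progressive_disease = fx(0.5))
  )
  arm <- run_strategy(p1, "navigated")
  b0 <- accumulate(run_markov_branch(p1, "R0"), p1, "navigated")
  expect_equal(arm$cost, b0$cost)
  expect_equal(arm$qaly, b0$qaly)

  # identical branches make the mixture weight irrelevant
  p2 <- toy_params(
    margin_r0 = list(navigated = fx(0.5)),
    transitions = list(df_to_pd = list(
      R0 = list(year1 = fx(0.2)), R1 = list(year1 = fx(0.2))
    ))
  )
  arm <- run_strategy(p2, "navigated")
  expect_equal(arm$qaly, accumulate(run_markov_branch(p2, "R0"), p2, "navigated")$qaly)

  # general mixture: weighted average of the branch accumulations
  p3 <- toy_params(
    margin_r0 = list(standard = fx(0.7)),
    transitions = list(
      df_to_pd = list(R0 = list(year1 = fx(0.1)), R1 = list(year1 = fx(0.35))),
      pd_to_death = list(entry_year1 = fx(0.15), entry_year23 = fx(0.05))
    ),
    utilities = list(progressive_disease = fx(0.6)),
    costs = list(state_df_per_cycle = fx(100), state_pd_per_cycle = fx(300))
  )
  arm <- run_strategy(p3, "standard")
  b0 <- accumulate(run_markov_branch(p3, "R0"), p3, "standard")
  b1 <- accumulate(run_markov_branch(p3, "R1"), p3, "standard")
  expect_equal(arm$cost, 0.7 * b0$cost + 0.3 * b1$cost, tolerance = 1e-12)
  expect_equal(arm$qaly, 0.7 * b0$qaly + 0.3 * b1$qaly, tolerance = 1e-12)
})

test_that("QALYs respond monotonically to progression and margin inputs", {
  # raising any disease-free-to-progression probability weakly lowers QALYs
  base <- run_strategy(lrrc, "standard")$qaly
  for (id in c(
    "df_pd_r0_year1", "df_pd_r0_year2", "df_pd_r1_year1",
    "df_pd_r1_year3"
  )) {
    worse <- navcea:::override_params(lrrc, setNames(
      list(param_spec(lrrc, id)$mean + 0.08), id
    ))
    expect_lt(run_strategy(worse, "standard")$qaly, base)
  }
  # raising the R0 rate weakly raises QALYs when the R0 branch is better
  better <- navcea:::override_params(lrrc, list(margin_r0_standard = 0.8))
  expect_gt(run_strategy(better, "standard")$qaly, base)
})

test_that("strategy comparison classifies dominance and guards the ICER", {
  arm <- function(cost, qaly) tibble::tibble(strategy = "x", cost = cost, qaly = qaly, ly = qaly)
  same <- compare_arms(arm(100, 1), arm(100, 1))
  expect_equal(same$incremental_cost, 0)
  expect_true(is.na(same$icer))
  expect_equal(
    compare_arms(arm(90, 1.2), arm(100, 1))$dominance, "dominant"
  )
  expect_equal(
    compare_arms(arm(110, 0.9), arm(100, 1))$dominance, "dominated"
  )
  ne <- compare_arms(arm(110, 1.1), arm(100, 1))
  expect_equal(ne$dominance, "more costly, more effective")
  expect_equal(ne$icer, 10 / 0.1, tolerance = 1e-12)
  expect_equal(
    compare_arms(arm(90, 0.9), arm(100, 1))$dominance, "less costly, less effective"
  )
})

test_that("both accrual conventions run and bracket each other as expected", {
  b_end <- run_base_case(lrrc)
  b_beg <- run_base_case(lrrc, markov_conventions("beginning"))
  # beginning counting includes the intact first-cycle cohort, so totals rise
  expect_gt(b_beg$arms$qaly[1], b_end$arms$qaly[1])
  expect_gt(b_beg$arms$ly[2], b_end$arms$ly[2])
  # and the one-cycle lag shrinks the between-arm contrast
  expect_lt(
    b_beg$comparison$incremental_qaly,
    b_end$comparison$incremental_qaly
  )
  # discounting from the cycle end shrinks every total
  b_off <- run_base_case(lrrc, markov_conventions("end", discount_offset = 1))
  expect_lt(b_off$arms$cost[1], b_end$arms$cost[1])
  expect_lt(b_off$arms$qaly[1], b_end$arms$qaly[1])
  # undiscounted life-years exceed discounted ones
  b_ly <- run_base_case(lrrc, markov_conventions("end", discount_life_years = FALSE))
  expect_gt(b_ly$arms$ly[1], b_end$arms$ly[1])
})

test_that("published strategy-level outcomes are reproduced", {
  # LRRC QALYs: 1.73 navigated vs 1.67 standard
  b <- run_base_case(lrrc)
  expect_equal(b$arms$qaly[b$arms$strategy == "navigated"], 1.73, tolerance = 0.03)
  expect_equal(b$arms$qaly[b$arms$strategy == "standard"], 1.67, tolerance = 0.03)
  # LARC standard arm: total costs about 23238 EUR and 2.02 QALYs
  bl <- run_base_case(larc)
  expect_equal(bl$arms$cost[bl$arms$strategy == "standard"], 23238, tolerance = 0.03)
  expect_equal(bl$arms$qaly[bl$arms$strategy == "standard"], 2.02, tolerance = 0.03)
})
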