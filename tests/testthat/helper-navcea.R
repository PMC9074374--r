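# Shared fixtures and oracles for the test suite.

larc <- load_parameter_set(navcea_example("larc"))
lrrc <- load_parameter_set(navcea_example("lrrc"))

# Minimal valid configuration built in code; every uncertain quantity fixed so
# toy models are fully deterministic unless a test overrides the specs.
toy_config <- function(...) {
  fx <- function(mean) list(family = "fixed", mean = mean, se = 0)
  base <- list(
    indication = "TOY",
    cycle_length = 0.25,
    horizon_cycles = 12,
    discount_rate_costs = 0,
    discount_rate_effects = 0,
    wtp = 80000,
    annual_incidence = 100,
    voi_horizon_years = 10,
    voi_discount_rate = 0,
    margin_r0 = list(navigated = fx(1), standard = fx(1)),
    transitions = list(
      df_to_pd = list(
        R0 = list(year1 = fx(0), year2 = fx(0), year3 = fx(0)),
        R1 = list(year1 = fx(0), year2 = fx(0), year3 = fx(0))
      ),
      pd_to_death = list(entry_year1 = fx(0), entry_year23 = fx(0)),
      df_to_death = fx(0)
    ),
    costs = list(
      surgery = fx(0), navigation_addition = fx(0),
      state_df_per_cycle = fx(0), state_pd_per_cycle = fx(0),
      transition_df_to_pd = fx(0)
    ),
    utilities = list(
      first_cycle = fx(1), disease_free = fx(1), progressive_disease = fx(1)
    )
  )
  utils::modifyList(base, list(...))
}

toy_params <- function(...) load_parameter_set(toy_config(...))

fx <- function(mean) list(family = "fixed", mean = mean, se = 0)

# Independent dense-matrix oracle for the cohort trace: states ordered
# (DF, PD1, PD23, Dead); the cycle-k transition matrix is built explicitly
# and applied by left-multiplication of the occupancy row vector.
matrix_power_trace <- function(p_year, bg, d1, d23, n_cycles = 12) {
  v <- c(1, 0, 0, 0)
  out <- matrix(0, n_cycles + 1, 4)
  out[1, ] <- v
  for (k in seq_len(n_cycles)) {
    y <- min(ceiling(k / 4), 3)
    p <- p_year[y]
    M <- matrix(0, 4, 4)
    M[1, 1] <- 1 - p - bg
    M[1, if (y == 1) 2 else 3] <- p
    M[1, 4] <- bg
    M[2, 2] <- 1 - d1
    M[2, 4] <- d1
    M[3, 3] <- 1 - d23
    M[3, 4] <- d23
    M[4, 4] <- 1
    v <- as.vector(v %*% M)
    out[k + 1, ] <- v
  }
  out
}

# Construct a minimal PSA object from explicit per-draw outcomes, for oracle
# tests of the decision-analytic summaries.
fake_psa <- function(cost_nav, qaly_nav, cost_std, qaly_std, wtp = 80000) {
  n <- length(cost_nav)
  structure(
    list(
      draws = dplyr::bind_rows(
        tibble::tibble(
          draw = seq_len(n), strategy = "navigated",
          cost = cost_nav, qaly = qaly_nav
        ),
        tibble::tibble(
          draw = seq_len(n), strategy = "standard",
          cost = cost_std, qaly = qaly_std
        )
      ),
      parameter_draws = tibble::tibble(.rows = n),
      n_draws = n, seed = NA_integer_, wtp = wtp,
      indication = "TOY", conventions = markov_conventions()
    ),
    class = "navcea_psa"
  )
}
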