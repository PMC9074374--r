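#' Accrual and discounting conventions for the cohort model
#'
#' The published totals do not fully pin down the spreadsheet conventions of
#' the original model, so the engine exposes them as explicit switches.
#'
#' @param count_method Which occupancy a cycle's costs, utilities and
#'   life-years are accrued on: `"end"` (default) counts the cohort after the
#'   cycle's transitions have been applied; `"beginning"` counts the cohort
#'   that entered the cycle. No half-cycle correction is applied in either
#'   case. `"end"` reproduces the published per-strategy totals (costs,
#'   QALYs, life-years) most closely; `"beginning"` reproduces the published
#'   incremental quantities (incremental QALYs, ICERs, thresholds). The two
#'   cannot be reconciled by any single accrual rule; see the methods
#'   vignette.
#' @param discount_offset Discount exponent for cycle `k` is
#'   `(k - 1 + discount_offset) * cycle_length` years: with the default `0`
#'   the first cycle is undiscounted (spreadsheet convention); `1` discounts
#'   from the end of the first cycle.
#' @param discount_life_years Discount life-years at the effect rate, like
#'   QALYs (default `TRUE`); `FALSE` leaves them undiscounted.
#'
#' @return A list of class `navcea_conventions`.
#' @export
markov_conventions <- function(count_method = c("end", "beginning"),
                               discount_offset = 0,
                               discount_life_years = TRUE) {
  count_method <- arg_match(count_method)
  stopifnot(discount_offset %in% c(0, 1))
  structure(
    list(
      count_method = count_method,
      discount_offset = discount_offset,
      discount_life_years = discount_life_years
    ),
    class = "navcea_conventions"
  )
}

# Year class of model cycle k (1-based): cycles 1..4 are year 1 for a
# 3-month cycle, etc.
cycle_year <- function(k, cycle_length) ceiling(k * cycle_length)

# Vectorised cohort engine. `pv` is a named list of equal-length numeric
# vectors (draws) holding all model parameters in natural units; `params`
# supplies the structural constants. Returns per-strategy discounted totals.
# This is the single computational core behind the base case, the PSA, the
# tornado and the value-of-information loops.
eval_model_vec <- function(pv, params, conventions = markov_conventions()) {
  cl <- params$cycle_length
  H <- params$horizon_cycles
  rc <- params$discount_rate_costs
  re <- params$discount_rate_effects
  m <- max(lengths(pv))
  pv <- lapply(pv, function(v) if (length(v) == 1) rep(v, m) else v)

  branch <- function(p_year, label) {
    df <- rep(1, m)
    pd1 <- pd23 <- dead <- rep(0, m)
    cost <- qaly <- ly <- rep(0, m)
    for (k in seq_len(H)) {
      y <- min(cycle_year(k, cl), 3)
      p_prog <- p_year[[y]]
      exit <- p_prog + pv$df_death
      if (any(exit > 1)) {
        abort(sprintf(
          "competing exit probabilities from disease-free exceed 1 in cycle %d (branch %s).",
          k, label
        ))
      }
      if (any(pv$pd_death_entry_year1 > 1) || any(pv$pd_death_entry_year23 > 1)) {
        abort(sprintf(
          "progressive-disease death probability exceeds 1 in cycle %d (branch %s).",
          k, label
        ))
      }
      inflow <- df * p_prog
      df_new <- df - inflow - df * pv$df_death
      if (y == 1) {
        pd1_new <- pd1 * (1 - pv$pd_death_entry_year1) + inflow
        pd23_new <- pd23 * (1 - pv$pd_death_entry_year23)
      } else {
        pd1_new <- pd1 * (1 - pv$pd_death_entry_year1)
        pd23_new <- pd23 * (1 - pv$pd_death_entry_year23) + inflow
      }
      dead_new <- dead + df * pv$df_death +
        pd1 * pv$pd_death_entry_year1 + pd23 * pv$pd_death_entry_year23
      if (conventions$count_method == "end") {
        df_c <- df_new
        pd_c <- pd1_new + pd23_new
      } else {
        df_c <- df
        pd_c <- pd1 + pd23
      }
      t_disc <- (k - 1 + conventions$discount_offset) * cl
      wc <- (1 + rc)^(-t_disc)
      we <- (1 + re)^(-t_disc)
      cost <- cost + wc * (df_c * pv$cost_state_df + pd_c * pv$cost_state_pd +
        inflow * pv$cost_transition_df_pd)
      u <- if (k == 1) {
        (df_c + pd_c) * pv$util_first_cycle
      } else {
        df_c * pv$util_disease_free + pd_c * pv$util_progressive_disease
      }
      qaly <- qaly + we * cl * u
      ly <- ly + (if (conventions$discount_life_years) we else 1) * cl * (df_c + pd_c)
      df <- df_new
      pd1 <- pd1_new
      pd23 <- pd23_new
      dead <- dead_new
    }
    list(cost = cost, qaly = qaly, ly = ly)
  }

  b0 <- branch(
    list(pv$df_pd_r0_year1, pv$df_pd_r0_year2, pv$df_pd_r0_year3), "R0"
  )
  b1 <- branch(
    list(pv$df_pd_r1_year1, pv$df_pd_r1_year2, pv$df_pd_r1_year3), "R1"
  )
  mix <- function(r0, field, intervention) {
    r0 * b0[[field]] + (1 - r0) * b1[[field]] +
      if (field == "cost") intervention else 0
  }
  tibble(
    cost_navigated = mix(pv$margin_r0_navigated, "cost", pv$cost_surgery + pv$cost_navigation_addition),
    qaly_navigated = mix(pv$margin_r0_navigated, "qaly", 0),
    ly_navigated = mix(pv$margin_r0_navigated, "ly", 0),
    cost_standard = mix(pv$margin_r0_standard, "cost", pv$cost_surgery),
    qaly_standard = mix(pv$margin_r0_standard, "qaly", 0),
    ly_standard = mix(pv$margin_r0_standard, "ly", 0)
  )
}

#' Run one margin branch of the Markov cohort model
#'
#' Propagates a cohort that starts 100% disease-free through the three-state
#' model with tunnel states. In cycle `k` (year class `ceiling(k / 4)` for
#' three-month cycles) the disease-free state sends its year-class
#' progression probability to progressive disease (the year-1 entrant tunnel
#' if progression occurs in the first year, otherwise the year-2/3 entrant
#' tunnel) and the background mortality to death; each tunnel sends its
#' entry-class death probability to death. All transitions are applied
#' simultaneously from start-of-cycle occupancies.
#'
#' @param params A `navcea_params` object.
#' @param margin_status `"R0"` (tumour-negative margin) or `"R1"`.
#' @return A tibble of class `navcea_trace` with one row per cycle `0..H`:
#'   occupancy fractions `disease_free`, `pd_year1_entrants`,
#'   `pd_year23_entrants`, `dead`, and `new_progression`, the fraction of the
#'   cohort that moved from disease-free to progressive disease during the
#'   cycle.
#' @examples
#' params <- load_parameter_set(navcea_example("larc"))
#' run_markov_branch(params, "R0")
#' @export
run_markov_branch <- function(params, margin_status = c("R0", "R1")) {
  margin_status <- arg_match(margin_status)
  stopifnot(inherits(params, "navcea_params"))
  pm <- param_means(params)
  cl <- params$cycle_length
  H <- params$horizon_cycles
  pre <- if (margin_status == "R0") "df_pd_r0_" else "df_pd_r1_"
  p_year <- c(
    pm[[paste0(pre, "year1")]], pm[[paste0(pre, "year2")]],
    pm[[paste0(pre, "year3")]]
  )
  bg <- pm$df_death
  d1 <- pm$pd_death_entry_year1
  d23 <- pm$pd_death_entry_year23
  df <- 1
  pd1 <- pd23 <- dead <- 0
  rows <- vector("list", H + 1)
  rows[[1]] <- tibble(
    cycle = 0L, disease_free = 1, pd_year1_entrants = 0,
    pd_year23_entrants = 0, dead = 0, new_progression = 0
  )
  for (k in seq_len(H)) {
    y <- min(cycle_year(k, cl), 3)
    if (p_year[y] + bg > 1) {
      abort(sprintf(
        "competing exit probabilities from disease-free sum to %.3f > 1 in cycle %d.",
        p_year[y] + bg, k
      ))
    }
    inflow <- df * p_year[y]
    dead <- dead + df * bg + pd1 * d1 + pd23 * d23
    if (y == 1) {
      pd1 <- pd1 * (1 - d1) + inflow
      pd23 <- pd23 * (1 - d23)
    } else {
      pd1 <- pd1 * (1 - d1)
      pd23 <- pd23 * (1 - d23) + inflow
    }
    df <- df - inflow - df * bg
    rows[[k + 1]] <- tibble(
      cycle = k, disease_free = df, pd_year1_entrants = pd1,
      pd_year23_entrants = pd23, dead = dead, new_progression = inflow
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("navcea_trace", class(out))
  attr(out, "margin_status") <- margin_status
  attr(out, "indication") <- params$indication
  out
}

#' Accumulate discounted costs, QALYs and life-years over a cohort trace
#'
#' Cycle `k` accrues state costs (disease-free and progressive-disease
#' occupants at their per-cycle state costs), the one-time progression
#' transition cost on the cycle's new progression inflow, utilities
#' (first-cycle utility for every alive occupant in cycle 1, thereafter the
#' state utilities) and life-years. Cycle `k` amounts are discounted by
#' `(1 + rate)^-((k - 1) * cycle_length)` at the cost or effect rate; the
#' intervention cost (surgery, plus the navigation addition for the navigated
#' strategy) is charged up front, undiscounted.
#'
#' @param trace A `navcea_trace` from [run_markov_branch()].
#' @param params The `navcea_params` the trace was generated from.
#' @param strategy `"navigated"` or `"standard"` (determines the intervention
#'   cost).
#' @param conventions A [markov_conventions()] object.
#' @return A one-row tibble: `strategy`, `cost`, `qaly`, `ly`.
#' @export
accumulate <- function(trace, params, strategy = c("navigated", "standard"),
                       conventions = markov_conventions()) {
  strategy <- arg_match(strategy)
  stopifnot(inherits(trace, "navcea_trace"))
  cl <- params$cycle_length
  pm <- param_means(params)
  k <- trace$cycle[-1]
  occ_row <- if (conventions$count_method == "end") k + 1 else k
  df <- trace$disease_free[occ_row]
  pd <- trace$pd_year1_entrants[occ_row] + trace$pd_year23_entrants[occ_row]
  inflow <- trace$new_progression[k + 1]
  t_disc <- (k - 1 + conventions$discount_offset) * cl
  wc <- (1 + params$discount_rate_costs)^(-t_disc)
  we <- (1 + params$discount_rate_effects)^(-t_disc)
  intervention <- pm$cost_surgery +
    if (strategy == "navigated") pm$cost_navigation_addition else 0
  cost <- intervention + sum(wc * (df * pm$cost_state_df +
    pd * pm$cost_state_pd + inflow * pm$cost_transition_df_pd))
  u <- df * pm$util_disease_free + pd * pm$util_progressive_disease
  u[1] <- (df[1] + pd[1]) * pm$util_first_cycle
  qaly <- sum(we * cl * u)
  wl <- if (conventions$discount_life_years) we else rep(1, length(k))
  ly <- sum(wl * cl * (df + pd))
  tibble(strategy = strategy, cost = cost, qaly = qaly, ly = ly)
}

#' Run one treatment strategy through decision tree and Markov model
#'
#' Evaluates the R0 and R1 branches and mixes them by the strategy's
#' probability of achieving a tumour-negative (R0) resection margin.
#'
#' @inheritParams accumulate
#' @param params A `navcea_params` object.
#' @return A one-row tibble (`strategy`, `cost`, `qaly`, `ly`) with the
#'   per-branch results attached as attribute `"branches"`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' run_strategy(params, "navigated")
#' @export
run_strategy <- function(params, strategy = c("navigated", "standard"),
                         conventions = markov_conventions()) {
  strategy <- arg_match(strategy)
  r0 <- params$margin_r0[[strategy]]$mean
  branches <- bind_rows(
    accumulate(run_markov_branch(params, "R0"), params, strategy, conventions) %>%
      mutate(margin_status = "R0", weight = r0),
    accumulate(run_markov_branch(params, "R1"), params, strategy, conventions) %>%
      mutate(margin_status = "R1", weight = 1 - r0)
  )
  out <- tibble(
    strategy = strategy,
    cost = sum(branches$weight * branches$cost),
    qaly = sum(branches$weight * branches$qaly),
    ly = sum(branches$weight * branches$ly)
  )
  attr(out, "branches") <- branches
  out
}

#' Compare two strategy results
#'
#' Computes incremental cost, QALYs and life-years (navigated minus
#' standard), the incremental cost-effectiveness ratio, and a dominance
#' classification. The ICER is `NA` (not silently infinite) when the
#' incremental QALYs are zero.
#'
#' @param navigated,standard One-row tibbles as returned by [run_strategy()].
#' @return A one-row tibble: `incremental_cost`, `incremental_qaly`,
#'   `incremental_ly`, `icer`, `dominance`.
#' @export
compare_arms <- function(navigated, standard) {
  dc <- navigated$cost - standard$cost
  dq <- navigated$qaly - standard$qaly
  dl <- navigated$ly - standard$ly
  dominance <- case_when(
    dq > 0 & dc > 0 ~ "more costly, more effective",
    dq >= 0 & dc <= 0 & (dq > 0 | dc < 0) ~ "dominant",
    dq < 0 & dc >= 0 ~ "dominated",
    dq < 0 & dc < 0 ~ "less costly, less effective",
    TRUE ~ "equivalent"
  )
  tibble(
    incremental_cost = dc,
    incremental_qaly = dq,
    incremental_ly = dl,
    icer = ifelse(dq != 0, dc / dq, NA_real_),
    dominance = dominance
  )
}

#' Run the deterministic base case for one indication
#'
#' Evaluates both strategies at the parameter means and compares them.
#'
#' @inheritParams run_strategy
#' @return An object of class `navcea_ce`: list with `arms` (two-row tibble),
#'   `comparison` (one-row tibble from [compare_arms()]), the indication and
#'   the conventions used.
#' @examples
#' params <- load_parameter_set(navcea_example("larc"))
#' base <- run_base_case(params)
#' glance(base)
#' @export
run_base_case <- function(params, conventions = markov_conventions()) {
  nav <- run_strategy(params, "navigated", conventions)
  std <- run_strategy(params, "standard", conventions)
  structure(
    list(
      arms = bind_rows(nav, std),
      comparison = compare_arms(nav, std),
      indication = params$indication,
      wtp = params$wtp,
      conventions = conventions
    ),
    class = "navcea_ce"
  )
}

#' @export
print.navcea_ce <- function(x, ...) {
  cat(sprintf("<navcea base case: %s>\n", x$indication))
  print(as.data.frame(x$arms), row.names = FALSE, digits = 4)
  cmp <- x$comparison
  icer_txt <- if (is.na(cmp$icer)) cmp$dominance else {
    sprintf("%.0f per QALY (%s)", cmp$icer, cmp$dominance)
  }
  cat(sprintf(
    "incremental: cost %.0f, QALY %.4f, ICER %s\n",
    cmp$incremental_cost, cmp$incremental_qaly, icer_txt
  ))
  invisible(x)
}

#' @rdname run_base_case
#' @param x A `navcea_ce` object.
#' @param ... Unused.
#' @export
tidy.navcea_ce <- function(x, ...) {
  x$arms %>% mutate(indication = x$indication, .before = 1)
}

#' @rdname run_base_case
#' @export
glance.navcea_ce <- function(x, ...) {
  x$comparison %>%
    mutate(
      indication = x$indication, .before = 1
    ) %>%
    mutate(
      wtp = x$wtp,
      net_monetary_benefit = x$wtp * .data$incremental_qaly - .data$incremental_cost
    )
}

#' Plot a cohort trace
#'
#' @param object A `navcea_trace`.
#' @param ... Unused.
#' @return A ggplot of state occupancy over time.
#' @export
autoplot.navcea_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c(
      "cycle", "disease_free", "pd_year1_entrants",
      "pd_year23_entrants", "dead"
    )],
    -"cycle",
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(
    long$state,
    levels = c("disease_free", "pd_year1_entrants", "pd_year23_entrants", "dead"),
    labels = c(
      "Disease-free", "PD (year-1 entrants)", "PD (year-2/3 entrants)", "Dead"
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cycle * 0.25, y = .data$occupancy, fill = .data$state
  )) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Years since surgery", y = "Cohort fraction",
      fill = NULL,
      title = sprintf(
        "%s cohort, %s margin", attr(object, "indication"),
        attr(object, "margin_status")
      )
    ) +
    ggplot2::theme_minimal()
}
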