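# Per-draw net monetary benefit matrix (draws x strategies) from a PSA.
nmb_matrix <- function(psa, wtp) {
  inc <- psa_incrementals(psa)
  cbind(
    navigated = wtp * inc$qaly_navigated - inc$cost_navigated,
    standard = wtp * inc$qaly_standard - inc$cost_standard
  )
}

#' Expected value of perfect information per patient
#'
#' The expected gain of deciding with perfect knowledge of all model
#' parameters: the mean over Monte Carlo draws of the best strategy's net
#' monetary benefit, minus the net monetary benefit of the strategy that is
#' best on average. Non-negative by construction.
#'
#' @param psa A `navcea_psa` object.
#' @param wtp Willingness to pay (EUR/QALY); defaults to the value stored in
#'   the PSA.
#' @return EVPI in EUR per patient (scalar).
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' psa <- run_psa(params, n_draws = 500, seed = 1)
#' evpi(psa)
#' @export
evpi <- function(psa, wtp = psa$wtp) {
  nmb <- nmb_matrix(psa, wtp)
  mean(pmax(nmb[, 1], nmb[, 2])) - max(colMeans(nmb))
}

#' Discounted size of the population that can benefit from the decision
#'
#' Sums the yearly incidence over the decision horizon, discounting future
#' cohorts. By default the first year's cohort is undiscounted (exponents
#' `0 .. years - 1`); set `first_year_discounted = TRUE` for exponents
#' `1 .. years`.
#'
#' @param annual_incidence New patients per year.
#' @param years Decision horizon in years.
#' @param discount_rate Annual discount rate for the population.
#' @param first_year_discounted Whether the first year's cohort is already
#'   discounted.
#' @return Effective (discounted) number of patients.
#' @examples
#' effective_population(250, 10, 0.04)
#' @export
effective_population <- function(annual_incidence, years, discount_rate,
                                 first_year_discounted = FALSE) {
  stopifnot(annual_incidence > 0, years > 0, discount_rate >= 0)
  t <- seq_len(years) - 1 + as.integer(first_year_discounted)
  sum(annual_incidence * (1 + discount_rate)^(-t))
}

#' Population expected value of perfect information
#'
#' @param evpi_per_patient EVPI per patient (EUR), from [evpi()].
#' @param effective_population Discounted number of patients affected by the
#'   decision, from [effective_population()].
#' @return Population EVPI in EUR.
#' @export
population_evpi <- function(evpi_per_patient, effective_population) {
  evpi_per_patient * effective_population
}

#' Expected value of partial perfect information for a parameter group
#'
#' Nested two-level Monte Carlo estimator: the outer loop samples the group
#' of interest, the inner loop samples the remaining uncertain parameters and
#' evaluates both strategies; the EVPPI is the mean over outer samples of the
#' best inner-mean net monetary benefit, minus the overall best mean. The
#' same inner sample of the complement parameters is reused across outer
#' iterations (common random numbers), which reduces Monte Carlo variance and
#' makes the estimate exactly zero for groups without uncertainty.
#'
#' @param params A `navcea_params` object.
#' @param group Character vector of parameter ids, or the name of one of the
#'   predefined groups in [navcea_groups()].
#' @param wtp Willingness to pay (EUR/QALY); defaults to the configuration's
#'   value.
#' @param outer_draws,inner_draws Outer and inner Monte Carlo sample sizes.
#' @param seed Integer seed.
#' @param conventions A [markov_conventions()] object.
#' @return One-row tibble: `group`, `evppi`, `outer_draws`, `inner_draws`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' evppi_group(params, "margin_rates", outer_draws = 50, inner_draws = 50, seed = 1)
#' @export
evppi_group <- function(params, group, wtp = params$wtp,
                        outer_draws = 500, inner_draws = 500, seed = NULL,
                        conventions = markov_conventions()) {
  stopifnot(outer_draws >= 2, inner_draws >= 2)
  groups <- navcea_groups(params)
  label <- if (length(group) == 1 && group %in% names(groups)) group else "custom"
  ids <- if (label == "custom") group else groups[[group]]
  tbl <- tidy(params)
  unknown <- setdiff(ids, tbl$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter id(s): ", paste(unknown, collapse = ", "), "."))
  }
  if (outer_draws < 50 || inner_draws < 50) {
    warn("small EVPPI draw budget; the estimate may be dominated by Monte Carlo noise.")
  }
  if (!is.null(seed)) set.seed(seed)
  # outer samples (group) first, then the shared inner sample (complement),
  # each in the documented parameter order
  outer_vals <- setNames(
    lapply(tbl$id, function(id) {
      if (id %in% ids) draw_from_spec(param_spec(params, id), outer_draws) else NULL
    }),
    tbl$id
  )
  inner_vals <- setNames(
    lapply(tbl$id, function(id) {
      if (id %in% ids) NULL else draw_from_spec(param_spec(params, id), inner_draws)
    }),
    tbl$id
  )
  pv <- setNames(
    lapply(tbl$id, function(id) {
      if (id %in% ids) {
        rep(outer_vals[[id]], each = inner_draws)
      } else {
        rep(inner_vals[[id]], times = outer_draws)
      }
    }),
    tbl$id
  )
  res <- eval_model_vec(pv, params, conventions)
  nmb_nav <- wtp * res$qaly_navigated - res$cost_navigated
  nmb_std <- wtp * res$qaly_standard - res$cost_standard
  m_nav <- colMeans(matrix(nmb_nav, nrow = inner_draws))
  m_std <- colMeans(matrix(nmb_std, nrow = inner_draws))
  out <- mean(pmax(m_nav, m_std)) - max(mean(nmb_nav), mean(nmb_std))
  tibble(
    group = label, evppi = out,
    outer_draws = outer_draws, inner_draws = inner_draws
  )
}

#' Regression-based single-loop EVPPI estimator
#'
#' Cross-check for [evppi_group()]: regresses the per-draw incremental net
#' monetary benefit of an existing PSA on the group's sampled parameter
#' values with an additive spline model (one smooth per parameter), and reads
#' the EVPPI off the fitted conditional expectations.
#'
#' @param psa A `navcea_psa` object.
#' @param group Character vector of parameter ids or a predefined group name
#'   (see [navcea_groups()]).
#' @param wtp Willingness to pay (EUR/QALY).
#' @return One-row tibble: `group`, `evppi`, `n_draws`.
#' @export
evppi_regression <- function(psa, group, wtp = psa$wtp) {
  groups <- navcea_groups()
  label <- if (length(group) == 1 && group %in% names(groups)) group else "custom"
  ids <- if (label == "custom") group else groups[[group]]
  unknown <- setdiff(ids, names(psa$parameter_draws))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter id(s): ", paste(unknown, collapse = ", "), "."))
  }
  dat <- psa$parameter_draws[, ids, drop = FALSE]
  dat <- dat[, vapply(dat, function(v) var(v) > 0, logical(1)), drop = FALSE]
  nmb <- nmb_matrix(psa, wtp)
  inb <- nmb[, "navigated"] - nmb[, "standard"]
  if (ncol(dat) == 0) {
    return(tibble(group = label, evppi = 0, n_draws = psa$n_draws))
  }
  form <- stats::as.formula(paste(
    "inb ~", paste(sprintf("s(%s)", colnames(dat)), collapse = " + ")
  ))
  fit <- mgcv::gam(form, data = cbind(dat, inb = inb))
  g <- stats::fitted(fit)
  tibble(
    group = label,
    evppi = mean(pmax(g, 0)) - max(mean(g), 0),
    n_draws = psa$n_draws
  )
}

#' Full value-of-information analysis
#'
#' Combines per-patient EVPI from a PSA, the discounted beneficiary
#' population, the population EVPI, and nested-Monte-Carlo EVPPI for each
#' predefined parameter group.
#'
#' @param params A `navcea_params` object.
#' @param psa Optional `navcea_psa`; if missing one is run with `n_draws`
#'   draws.
#' @param wtp Willingness to pay (EUR/QALY).
#' @param n_draws Draws for the PSA when `psa` is not supplied.
#' @param outer_draws,inner_draws EVPPI draw budget per group.
#' @param seed Integer seed.
#' @param groups Named list of parameter-id groups (default
#'   [navcea_groups()]).
#' @param conventions A [markov_conventions()] object.
#' @return An object of class `navcea_voi`: list with `summary` (one-row
#'   tibble: wtp, evpi per patient, effective population, population EVPI)
#'   and `evppi` (tibble with one row per group, sorted by EVPPI).
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' voi <- voi_analysis(params,
#'   n_draws = 200, outer_draws = 50,
#'   inner_draws = 50, seed = 1
#' )
#' voi
#' @export
voi_analysis <- function(params, psa = NULL, wtp = params$wtp, n_draws = 2000,
                         outer_draws = 500, inner_draws = 500, seed = NULL,
                         groups = navcea_groups(params),
                         conventions = markov_conventions()) {
  if (is.null(psa)) {
    psa <- run_psa(params, n_draws = n_draws, seed = seed, conventions = conventions)
  }
  per_patient <- evpi(psa, wtp)
  pop <- effective_population(
    params$annual_incidence, params$voi_horizon_years, params$voi_discount_rate
  )
  empty_evppi <- tibble(
    group = character(), evppi = double(),
    outer_draws = integer(), inner_draws = integer()
  )
  evppi_tbl <- purrr::imap_dfr(groups, function(ids, label) {
    row <- evppi_group(
      params, ids,
      wtp = wtp, outer_draws = outer_draws,
      inner_draws = inner_draws,
      seed = if (is.null(seed)) NULL else seed + match(label, names(groups)),
      conventions = conventions
    )
    row$group <- label
    row
  })
  note <- if (identical(params$indication, "LARC")) {
    paste(
      "standard surgery is preferred at the WTP threshold in the LARC base",
      "case; the EVPI is reported here for completeness."
    )
  } else {
    NA_character_
  }
  structure(
    list(
      summary = tibble(
        indication = params$indication, wtp = wtp,
        evpi_per_patient = per_patient,
        effective_population = pop,
        population_evpi = population_evpi(per_patient, pop),
        note = note
      ),
      evppi = if (nrow(evppi_tbl) == 0) empty_evppi else arrange(evppi_tbl, desc(.data$evppi))
    ),
    class = "navcea_voi"
  )
}

#' @export
print.navcea_voi <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<navcea value of information: %s at WTP %s>\n",
    s$indication, format(s$wtp, big.mark = ",")))
  cat(sprintf(
    "  EVPI %.0f EUR/patient x %.0f patients = %.2f M EUR\n",
    s$evpi_per_patient, s$effective_population, s$population_evpi / 1e6
  ))
  if (!is.na(s$note)) cat("  note:", s$note, "\n")
  cat("  EVPPI by parameter group (EUR/patient):\n")
  print(as.data.frame(x$evppi[, c("group", "evppi")]),
    row.names = FALSE, digits = 4
  )
  invisible(x)
}

#' @rdname voi_analysis
#' @param x A `navcea_voi` object.
#' @param ... Unused.
#' @export
tidy.navcea_voi <- function(x, ...) x$evppi

#' @rdname voi_analysis
#' @export
glance.navcea_voi <- function(x, ...) x$summary

#' Bar chart of EVPPI by parameter group
#'
#' @param object A `navcea_voi` from [voi_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.navcea_voi <- function(object, ...) {
  dat <- object$evppi
  dat$group <- factor(dat$group, levels = rev(dat$group))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$evppi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = object$summary$evpi_per_patient, linetype = "dashed"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "EVPPI (EUR/patient)",
      title = sprintf(
        "Partial perfect information by parameter group, %s",
        object$summary$indication
      ),
      subtitle = "dashed line: overall EVPI per patient"
    ) +
    ggplot2::theme_minimal()
}
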