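# Resolve a scenario argument to a modified parameter set. A scenario is
# either the name of a scenario block in the configuration (which replaces
# the navigation-addition cost distribution) or a named list of parameter
# overrides (numbers replace the mean, dist_spec() objects replace the whole
# distribution).
apply_scenario <- function(params, scenario) {
  if (is.character(scenario)) {
    stopifnot(length(scenario) == 1)
    sc <- params$scenarios[[scenario]]
    if (is.null(sc)) {
      abort(paste0(
        "unknown scenario `", scenario, "`; configuration defines: ",
        paste(names(params$scenarios), collapse = ", "), "."
      ))
    }
    return(override_params(
      params,
      list(cost_navigation_addition = sc$navigation_addition)
    ))
  }
  if (is.list(scenario)) {
    return(override_params(params, scenario))
  }
  abort("`scenario` must be a scenario name or a named list of overrides.")
}

#' Run a scenario analysis
#'
#' Re-runs the deterministic model with scenario constants substituted. The
#' packaged configurations define three scenarios on the navigation addition
#' cost: `"hybrid_or"` (construction of a hybrid operating room included,
#' 6363 EUR), `"utilization_50"` (navigation system utilisation raised from
#' 12% to 50%, 1670 EUR) and `"combined"` (both, 4644.28 EUR). A named list
#' of parameter overrides may be supplied instead.
#'
#' @param params A `navcea_params` object.
#' @param scenario Scenario name or named list of overrides.
#' @param conventions A [markov_conventions()] object.
#' @return A `navcea_ce` object (see [run_base_case()]).
#' @examples
#' params <- load_parameter_set(navcea_example("larc"))
#' glance(run_scenario(params, "utilization_50"))
#' @export
run_scenario <- function(params, scenario, conventions = markov_conventions()) {
  out <- run_base_case(apply_scenario(params, scenario), conventions)
  out$scenario <- if (is.character(scenario)) scenario else "custom"
  out
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each uncertain parameter is set in turn to its lower and upper limit
#' (default: mean +/- 1.96 standard errors, clipped to `[0, 1]` for
#' probabilities and utilities and to `[0, Inf)` for costs) with all other
#' parameters at base-case values, and the ICER is recomputed. Parameters
#' with no standard error produce zero-width bars. Entries are sorted by
#' decreasing bar width (absolute ICER range).
#'
#' @param params A `navcea_params` object.
#' @param z Half-width of the input interval in standard errors (default
#'   1.96, a 95% normal-approximation interval).
#' @param conventions A [markov_conventions()] object.
#' @return A tibble of class `navcea_tornado`: `parameter`, `group`, `low`,
#'   `high` (input values), `icer_low`, `icer_high`, `width`; the base-case
#'   ICER is attached as attribute `"icer_base"`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' tornado(params)
#' @export
tornado <- function(params, z = 1.96, conventions = markov_conventions()) {
  stopifnot(inherits(params, "navcea_params"))
  pm <- param_means(params)
  icer_at <- function(pm) {
    res <- eval_model_vec(pm, params, conventions)
    (res$cost_navigated - res$cost_standard) /
      (res$qaly_navigated - res$qaly_standard)
  }
  base_icer <- icer_at(pm)
  tbl <- tidy(params)
  rows <- purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    spec <- param_spec(params, tbl$id[i])
    bounds <- spec_interval(spec, z)
    icers <- purrr::map_dbl(bounds, function(v) {
      pm2 <- pm
      pm2[[tbl$id[i]]] <- v
      icer_at(pm2)
    })
    tibble(
      parameter = tbl$id[i], group = tbl$group[i],
      low = bounds[["low"]], high = bounds[["high"]],
      icer_low = icers[[1]], icer_high = icers[[2]],
      width = abs(icers[[2]] - icers[[1]])
    )
  })
  out <- arrange(rows, desc(.data$width))
  class(out) <- c("navcea_tornado", class(out))
  attr(out, "icer_base") <- base_icer
  attr(out, "indication") <- params$indication
  out
}

#' Tornado diagram
#'
#' @param object A `navcea_tornado` from [tornado()].
#' @param n_top Number of widest bars to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.navcea_tornado <- function(object, n_top = 10, ...) {
  dat <- utils::head(as_tibble(object), n_top)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  dat$ymin <- pmin(dat$icer_low, dat$icer_high)
  dat$ymax <- pmax(dat$icer_low, dat$icer_high)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$parameter)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_hline(
      yintercept = attr(object, "icer_base"), linetype = "dashed"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "ICER (EUR/QALY)",
      title = sprintf(
        "One-way sensitivity, %s (dashed: base-case ICER)",
        attr(object, "indication")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Threshold analysis on the navigation cost
#'
#' Finds the maximum incremental cost per patient at which navigated surgery
#' remains cost-effective at the given willingness to pay, i.e.
#' `wtp * incremental QALYs`, and translates it into the corresponding
#' navigation addition cost through the linear cost relationship
#' (incremental cost = downstream incremental cost + navigation addition).
#'
#' @param params A `navcea_params` object.
#' @param wtp Willingness to pay (EUR/QALY); defaults to the configuration's
#'   value.
#' @param conventions A [markov_conventions()] object.
#' @return One-row tibble: `wtp`, `incremental_qaly`,
#'   `max_incremental_cost`, `navigation_cost_at_threshold`.
#' @examples
#' params <- load_parameter_set(navcea_example("larc"))
#' threshold_navigation_cost(params)
#' @export
threshold_navigation_cost <- function(params, wtp = params$wtp,
                                      conventions = markov_conventions()) {
  base <- run_base_case(params, conventions)
  dq <- base$comparison$incremental_qaly
  if (dq <= 0) {
    abort("threshold undefined: incremental QALYs are not positive.")
  }
  nav_cost <- params$costs$navigation_addition$mean
  downstream <- base$comparison$incremental_cost - nav_cost
  tibble(
    wtp = wtp,
    incremental_qaly = dq,
    max_incremental_cost = wtp * dq,
    navigation_cost_at_threshold = wtp * dq - downstream
  )
}
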