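#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the model by Monte Carlo
#' simulation. Every uncertain parameter is drawn independently from its
#' method-of-moments distribution (beta for probabilities and utilities,
#' gamma for costs); parameters shared between the strategies (downstream
#' transition probabilities, state and transition costs, utilities, surgery
#' cost) use the same sampled value for both strategies within a draw, while
#' the margin rates are sampled per strategy and the navigation addition is
#' charged to the navigated strategy only. Draw order follows the documented
#' parameter ordering of [tidy.navcea_params()], so results are reproducible
#' given the seed.
#'
#' @param params A `navcea_params` object.
#' @param n_draws Number of Monte Carlo samples (the published analysis used
#'   2000).
#' @param seed Integer seed for the random number generator.
#' @param scenario Optional scenario to apply before sampling; see
#'   [run_scenario()].
#' @param conventions A [markov_conventions()] object.
#' @return An object of class `navcea_psa`: list with `draws` (long tibble:
#'   `draw`, `strategy`, `cost`, `qaly`), `parameter_draws` (tibble of the
#'   sampled parameter values, one column per parameter), `n_draws`, `seed`,
#'   `wtp`, `indication`, `conventions`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' psa <- run_psa(params, n_draws = 200, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(params, n_draws = 2000, seed = NULL, scenario = NULL,
                    conventions = markov_conventions()) {
  stopifnot(inherits(params, "navcea_params"), n_draws >= 1)
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  if (!is.null(seed)) set.seed(seed)
  tbl <- tidy(params)
  pv <- setNames(
    lapply(seq_len(nrow(tbl)), function(i) {
      draw_from_spec(param_spec(params, tbl$id[i]), n_draws)
    }),
    tbl$id
  )
  res <- eval_model_vec(pv, params, conventions)
  draws <- bind_rows(
    tibble(
      draw = seq_len(n_draws), strategy = "navigated",
      cost = res$cost_navigated, qaly = res$qaly_navigated
    ),
    tibble(
      draw = seq_len(n_draws), strategy = "standard",
      cost = res$cost_standard, qaly = res$qaly_standard
    )
  )
  structure(
    list(
      draws = draws,
      parameter_draws = as_tibble(pv),
      n_draws = n_draws,
      seed = seed,
      wtp = params$wtp,
      indication = params$indication,
      conventions = conventions
    ),
    class = "navcea_psa"
  )
}

# Wide per-draw incremental pairs.
psa_incrementals <- function(psa) {
  wide <- tidyr::pivot_wider(
    psa$draws,
    names_from = "strategy", values_from = c("cost", "qaly")
  )
  wide %>%
    mutate(
      incremental_cost = .data$cost_navigated - .data$cost_standard,
      incremental_qaly = .data$qaly_navigated - .data$qaly_standard
    )
}

#' Quadrant fractions of the cost-effectiveness plane
#'
#' Fraction of Monte Carlo draws falling in each quadrant of the plane of
#' incremental QALYs (x) versus incremental costs (y) for navigated versus
#' standard surgery. `NE` is more effective and more costly, `SE` dominant
#' (more effective, cheaper), `NW` dominated, `SW` less effective and
#' cheaper. Boundary draws are assigned so the four fractions always sum
#' to 1.
#'
#' @param psa A `navcea_psa` object.
#' @return A tibble with columns `quadrant` and `fraction`.
#' @export
ce_plane_quadrants <- function(psa) {
  inc <- psa_incrementals(psa)
  ne <- inc$incremental_qaly > 0 & inc$incremental_cost > 0
  se <- inc$incremental_qaly > 0 & inc$incremental_cost <= 0
  nw <- inc$incremental_qaly <= 0 & inc$incremental_cost > 0
  sw <- !(ne | se | nw)
  tibble(
    quadrant = c("NE", "SE", "NW", "SW"),
    fraction = c(mean(ne), mean(se), mean(nw), mean(sw))
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' maximises net monetary benefit (`NMB = wtp * QALY - cost`) across the
#' Monte Carlo draws. At each willingness-to-pay the probabilities sum to 1
#' over the strategies; ties are credited to standard surgery (the
#' incumbent).
#'
#' @param psa A `navcea_psa` object.
#' @param wtp_grid Numeric vector of willingness-to-pay values (EUR/QALY).
#' @return A tibble: `wtp`, `strategy`, `probability`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' psa <- run_psa(params, n_draws = 200, seed = 1)
#' ceac(psa, wtp_grid = c(0, 40000, 80000, 120000))
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa, "navcea_psa"), length(wtp_grid) >= 1)
  inc <- psa_incrementals(psa)
  purrr::map_dfr(wtp_grid, function(w) {
    p_nav <- mean(w * inc$incremental_qaly - inc$incremental_cost > 0)
    tibble(
      wtp = w,
      strategy = c("navigated", "standard"),
      probability = c(p_nav, 1 - p_nav)
    )
  })
}

#' @rdname run_psa
#' @param x A `navcea_psa` object.
#' @param ... Unused.
#' @export
tidy.navcea_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.navcea_psa <- function(x, ...) {
  inc <- psa_incrementals(x)
  quad <- ce_plane_quadrants(x)
  p_nav <- mean(x$wtp * inc$incremental_qaly - inc$incremental_cost > 0)
  tibble(
    indication = x$indication,
    n_draws = x$n_draws,
    seed = x$seed %||% NA_integer_,
    mean_incremental_cost = mean(inc$incremental_cost),
    mean_incremental_qaly = mean(inc$incremental_qaly),
    frac_ne = quad$fraction[quad$quadrant == "NE"],
    frac_se = quad$fraction[quad$quadrant == "SE"],
    frac_nw = quad$fraction[quad$quadrant == "NW"],
    frac_sw = quad$fraction[quad$quadrant == "SW"],
    wtp = x$wtp,
    prob_navigated_cost_effective = p_nav
  )
}

#' @export
print.navcea_psa <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<navcea PSA: %s, %d draws%s>\n", x$indication, x$n_draws,
    if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""
  ))
  cat(sprintf(
    "  mean incremental cost %.0f, QALY %.4f\n",
    g$mean_incremental_cost, g$mean_incremental_qaly
  ))
  cat(sprintf(
    "  NE/SE/NW/SW quadrant fractions: %.2f/%.2f/%.2f/%.2f\n",
    g$frac_ne, g$frac_se, g$frac_nw, g$frac_sw
  ))
  cat(sprintf(
    "  P(navigated cost-effective at WTP %s): %.2f\n",
    format(x$wtp, big.mark = ","), g$prob_navigated_cost_effective
  ))
  invisible(x)
}

#' Cost-effectiveness plane of a probabilistic sensitivity analysis
#'
#' @param object A `navcea_psa` object.
#' @param wtp Willingness-to-pay line to draw (defaults to the
#'   configuration's value).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.navcea_psa <- function(object, wtp = object$wtp, ...) {
  inc <- psa_incrementals(object)
  ggplot2::ggplot(inc, ggplot2::aes(
    x = .data$incremental_qaly, y = .data$incremental_cost
  )) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(
      slope = wtp, intercept = 0, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental costs (EUR)",
      title = sprintf(
        "%s: navigated vs standard surgery (%d draws)",
        object$indication, object$n_draws
      ),
      subtitle = sprintf("dashed line: WTP %s/QALY", format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param psa A `navcea_psa` object.
#' @param wtp_grid Willingness-to-pay grid passed to [ceac()].
#' @return A ggplot.
#' @export
plot_ceac <- function(psa, wtp_grid = seq(0, 200000, by = 5000)) {
  curves <- ceac(psa, wtp_grid)
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$wtp, y = .data$probability, colour = .data$strategy
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = psa$wtp, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (EUR/QALY)",
      y = "Probability cost-effective", colour = NULL,
      title = sprintf("Cost-effectiveness acceptability, %s", psa$indication)
    ) +
    ggplot2::theme_minimal()
}
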