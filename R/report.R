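#' Run the full analysis for one or more indications
#'
#' Orchestrates the complete evaluation: deterministic base case, scenario
#' analyses, threshold analysis, probabilistic sensitivity analysis with
#' quadrant fractions and acceptability curves, tornado analysis and
#' (optionally) value-of-information analysis, for each supplied model
#' configuration. Deterministic sections are identical across reruns;
#' stochastic sections are identical given the seed. Every numeric cell in
#' the report is produced by the corresponding analysis function; the
#' reporting layer only assembles tables.
#'
#' @param configs Character vector of configuration paths (or a list of
#'   `navcea_params`). Defaults to the two packaged indications.
#' @param n_draws Monte Carlo draws for the PSA.
#' @param seed Integer seed used for all stochastic sections.
#' @param wtp Willingness-to-pay override (EUR/QALY); `NULL` uses each
#'   configuration's value.
#' @param scenarios Scenario names to evaluate (must exist in each
#'   configuration).
#' @param include_psa Include the stochastic sections (PSA, CEAC, EVPI)?
#' @param include_voi Include the (slower) EVPPI-by-group analysis?
#' @param outer_draws,inner_draws EVPPI draw budget.
#' @param out_dir Optional directory; when given, every table is written as a
#'   CSV (plain decimal numbers) together with a `manifest.csv` recording the
#'   configuration paths, options, seed, package version and timestamp.
#' @param conventions A [markov_conventions()] object.
#' @return A list of class `navcea_report`: tibbles `base_case`, `scenarios`,
#'   `thresholds`, and (with PSA) `psa_summary`, `ceac`, `ce_plane`,
#'   `tornado`, `voi_summary`, `evppi`; plus `manifest`.
#' @examples
#' report <- run_full_analysis(
#'   navcea_example("lrrc"),
#'   n_draws = 100, seed = 1, include_voi = FALSE
#' )
#' report$base_case
#' @export
run_full_analysis <- function(configs = c(navcea_example("larc"), navcea_example("lrrc")),
                              n_draws = 2000, seed = 42, wtp = NULL,
                              scenarios = c("hybrid_or", "utilization_50", "combined"),
                              include_psa = TRUE, include_voi = include_psa,
                              outer_draws = 500, inner_draws = 500,
                              out_dir = NULL,
                              conventions = markov_conventions()) {
  params_list <- purrr::map(configs, function(cfg) {
    if (inherits(cfg, "navcea_params")) cfg else load_parameter_set(cfg)
  })
  stage <- function(what, ind, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", what, "` failed for ", ind, ": ", conditionMessage(e)))
    })
  }
  sections <- purrr::map(params_list, function(params) {
    ind <- params$indication
    if (!is.null(wtp)) params$wtp <- wtp
    base <- stage("base_case", ind, run_base_case(params, conventions))
    base_tbl <- tidy(base) %>%
      left_join(
        glance(base) %>%
          select(
            "indication", "incremental_cost", "incremental_qaly",
            "icer", "dominance"
          ),
        by = "indication"
      )
    scen_tbl <- purrr::map_dfr(scenarios, function(sc) {
      res <- stage(paste0("scenario_", sc), ind, run_scenario(params, sc, conventions))
      glance(res) %>% mutate(scenario = sc, .after = "indication")
    })
    thr_tbl <- stage(
      "threshold", ind,
      threshold_navigation_cost(params, conventions = conventions)
    ) %>%
      mutate(indication = ind, .before = 1)
    out <- list(
      base_case = base_tbl, scenarios = scen_tbl, thresholds = thr_tbl
    )
    if (include_psa) {
      psa <- stage(
        "psa", ind,
        run_psa(params, n_draws = n_draws, seed = seed, conventions = conventions)
      )
      out$psa_summary <- glance(psa)
      out$ce_plane <- psa_incrementals(psa) %>% mutate(indication = ind, .before = 1)
      out$ceac <- ceac(psa) %>% mutate(indication = ind, .before = 1)
      out$tornado <- as_tibble(stage("tornado", ind, tornado(params, conventions = conventions))) %>%
        mutate(indication = ind, .before = 1)
      voi <- stage("voi", ind, voi_analysis(
        params,
        psa = psa, seed = seed,
        outer_draws = if (include_voi) outer_draws else 2,
        inner_draws = if (include_voi) inner_draws else 2,
        groups = if (include_voi) navcea_groups(params) else list(),
        conventions = conventions
      ))
      out$voi_summary <- glance(voi)
      if (include_voi) out$evppi <- tidy(voi) %>% mutate(indication = ind, .before = 1)
    }
    out
  })
  tables <- purrr::map(
    setNames(
      unique(unlist(purrr::map(sections, names))),
      unique(unlist(purrr::map(sections, names)))
    ),
    function(nm) bind_rows(purrr::map(sections, nm))
  )
  tables$manifest <- tibble(
    config = purrr::map_chr(configs, function(cfg) {
      if (inherits(cfg, "navcea_params")) paste0("<in-memory:", cfg$indication, ">") else cfg
    }),
    n_draws = n_draws, seed = seed,
    wtp = if (is.null(wtp)) NA_real_ else wtp,
    include_psa = include_psa, include_voi = include_voi,
    outer_draws = outer_draws, inner_draws = inner_draws,
    count_method = conventions$count_method,
    discount_offset = conventions$discount_offset,
    package_version = as.character(utils::packageVersion("navcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
        row.names = FALSE
      )
    }
  }
  structure(tables, class = c("navcea_report", class(tables)))
}

#' @export
print.navcea_report <- function(x, ...) {
  cat("<navcea report>\n  tables:", paste(names(x), collapse = ", "), "\n")
  cat("base case:\n")
  print(as.data.frame(x$base_case), row.names = FALSE, digits = 4)
  invisible(x)
}
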