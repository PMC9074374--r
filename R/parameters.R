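#' Path to a packaged model configuration
#'
#' The package ships complete model configurations for both indications:
#' locally advanced (`"larc"`) and locally recurrent (`"lrrc"`) rectal cancer,
#' encoding the margin rates, transition probabilities, costs, utilities,
#' discounting and value-of-information settings of the published early
#' evaluation.
#'
#' @param indication `"larc"` or `"lrrc"`.
#' @return Path to the packaged YAML file.
#' @examples
#' params <- load_parameter_set(navcea_example("larc"))
#' @export
navcea_example <- function(indication = c("larc", "lrrc")) {
  indication <- arg_match(indication)
  system.file("extdata", paste0(indication, ".yaml"),
    package = "navcea", mustWork = TRUE
  )
}

param_required_fields <- c(
  "indication", "cycle_length", "horizon_cycles", "discount_rate_costs",
  "discount_rate_effects", "wtp", "annual_incidence", "voi_horizon_years",
  "voi_discount_rate", "margin_r0", "transitions", "costs", "utilities"
)

# field -> path into the nested configuration list, one row per uncertain (or
# fixed) model parameter, in the documented sampling order.
param_index <- tibble::tribble(
  ~id, ~group, ~arm, ~path,
  "margin_r0_navigated", "margin_navigated", "navigated", list(c("margin_r0", "navigated")),
  "margin_r0_standard", "margin_standard", "standard", list(c("margin_r0", "standard")),
  "df_pd_r0_year1", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R0", "year1")),
  "df_pd_r0_year2", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R0", "year2")),
  "df_pd_r0_year3", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R0", "year3")),
  "df_pd_r1_year1", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R1", "year1")),
  "df_pd_r1_year2", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R1", "year2")),
  "df_pd_r1_year3", "transition_probabilities", "shared", list(c("transitions", "df_to_pd", "R1", "year3")),
  "pd_death_entry_year1", "transition_probabilities", "shared", list(c("transitions", "pd_to_death", "entry_year1")),
  "pd_death_entry_year23", "transition_probabilities", "shared", list(c("transitions", "pd_to_death", "entry_year23")),
  "df_death", "transition_probabilities", "shared", list(c("transitions", "df_to_death")),
  "cost_surgery", "treatment_costs", "shared", list(c("costs", "surgery")),
  "cost_navigation_addition", "treatment_costs", "navigated", list(c("costs", "navigation_addition")),
  "cost_state_df", "treatment_costs", "shared", list(c("costs", "state_df_per_cycle")),
  "cost_state_pd", "treatment_costs", "shared", list(c("costs", "state_pd_per_cycle")),
  "cost_transition_df_pd", "treatment_costs", "shared", list(c("costs", "transition_df_to_pd")),
  "util_first_cycle", "utilities", "shared", list(c("utilities", "first_cycle")),
  "util_disease_free", "utilities", "shared", list(c("utilities", "disease_free")),
  "util_progressive_disease", "utilities", "shared", list(c("utilities", "progressive_disease"))
)
param_index$path <- lapply(param_index$path, function(p) {
  if (is.list(p)) p[[1]] else p
})

as_dist <- function(x, field) {
  if (inherits(x, "navcea_dist")) {
    return(x)
  }
  if (!is.list(x) || is.null(x$mean)) {
    abort(paste0("field `", field, "` must be a {family, mean, se} triple."))
  }
  family <- x$family %||% "fixed"
  if (!family %in% c("beta", "gamma", "fixed")) {
    abort(paste0("field `", field, "`: unknown distribution family `", family, "`."))
  }
  withCallingHandlers(
    dist_spec(family, x$mean, x$se %||% 0),
    error = function(e) {
      abort(paste0("field `", field, "`: ", conditionMessage(e)))
    }
  )
}

pluck_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

assign_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
  } else {
    x[[path[1]]] <- assign_path(x[[path[1]]], path[-1], value)
  }
  x
}

#' Load and validate a model configuration
#'
#' Reads a YAML model configuration (see [navcea_example()] for the packaged
#' ones) and validates it: all required fields present, every uncertain
#' parameter a feasible `{family, mean, se}` triple, probabilities and
#' utilities in `[0, 1]`, costs and rates non-negative.
#'
#' @param config Path to a YAML file, or an already-parsed nested list.
#' @return An object of class `navcea_params`.
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' params
#' @export
load_parameter_set <- function(config) {
  x <- if (is.character(config)) yaml::read_yaml(config) else config
  missing <- setdiff(param_required_fields, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing field(s): ", paste(missing, collapse = ", "), "."))
  }
  for (field in c(
    "cycle_length", "horizon_cycles", "discount_rate_costs",
    "discount_rate_effects", "wtp", "annual_incidence", "voi_horizon_years",
    "voi_discount_rate"
  )) {
    v <- x[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("field `", field, "` must be a single finite number."))
    }
  }
  if (x$cycle_length <= 0) abort("field `cycle_length` must be positive.")
  if (x$horizon_cycles < 1) abort("field `horizon_cycles` must be at least 1.")
  if (x$discount_rate_costs < 0 || x$discount_rate_effects < 0) {
    abort("discount rates must be non-negative.")
  }
  for (i in seq_len(nrow(param_index))) {
    path <- param_index$path[[i]]
    node <- tryCatch(pluck_path(x, path), error = function(e) NULL)
    if (is.null(node)) {
      abort(paste0("missing field `", paste(path, collapse = "$"), "`."))
    }
    x <- assign_path(x, path, as_dist(node, paste(path, collapse = "$")))
  }
  # role-based range checks (families alone do not constrain fixed values)
  for (i in seq_len(nrow(param_index))) {
    id <- param_index$id[i]
    spec <- pluck_path(x, param_index$path[[i]])
    is_prob <- grepl("^(margin_|df_pd_|pd_death_|df_death|util_)", id)
    if (is_prob && (spec$mean < 0 || spec$mean > 1)) {
      abort(paste0("field `", id, "`: probability/utility must lie in [0, 1], got ", spec$mean, "."))
    }
    if (!is_prob && spec$mean < 0) {
      abort(paste0("field `", id, "`: cost must be non-negative, got ", spec$mean, "."))
    }
  }
  if (!is.null(x$scenarios)) {
    for (sc in names(x$scenarios)) {
      ov <- x$scenarios[[sc]]$navigation_addition
      if (!is.null(ov)) {
        x$scenarios[[sc]]$navigation_addition <-
          as_dist(ov, paste0("scenarios$", sc, "$navigation_addition"))
      }
    }
  }
  if (!is.null(x$observed_counts)) {
    for (cell in names(x$observed_counts)) {
      oc <- x$observed_counts[[cell]]
      if (oc$events < 0 || oc$events > oc$at_risk || oc$at_risk <= 0) {
        abort(paste0(
          "field `observed_counts$", cell,
          "`: requires 0 <= events <= at_risk and at_risk > 0."
        ))
      }
    }
  }
  structure(x, class = "navcea_params")
}

#' Write a model configuration back to YAML
#'
#' The written file loads back to an identical parameter set, so
#' configurations can be edited programmatically and persisted.
#'
#' @param params A `navcea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "navcea_params"))
  plain <- rapply(unclass(params),
    f = function(x) x, how = "replace"
  )
  strip <- function(x) {
    if (inherits(x, "navcea_dist")) {
      return(list(family = x$family, mean = x$mean, se = x$se))
    }
    if (is.list(x)) {
      return(lapply(x, strip))
    }
    x
  }
  yaml::write_yaml(strip(plain), path, precision = 15)
  invisible(path)
}

#' @export
print.navcea_params <- function(x, ...) {
  cat(sprintf(
    "<navcea parameter set: %s>\n  horizon %d cycles of %.2f years; WTP %s/QALY\n",
    x$indication, x$horizon_cycles, x$cycle_length,
    format(x$wtp, big.mark = ",")
  ))
  cat(sprintf(
    "  R0 margin rate: navigated %.2f, standard %.2f\n",
    x$margin_r0$navigated$mean, x$margin_r0$standard$mean
  ))
  cat(sprintf(
    "  discounting: costs %.1f%%, effects %.1f%% per year\n",
    100 * x$discount_rate_costs, 100 * x$discount_rate_effects
  ))
  cat("  use tidy() for the full parameter table\n")
  invisible(x)
}

#' Tabulate the uncertain parameters of a model configuration
#'
#' @param x A `navcea_params` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `id`, `group`, `arm`
#'   (which strategy the parameter applies to), `family`, `mean`, `se`.
#' @export
tidy.navcea_params <- function(x, ...) {
  specs <- purrr::map(param_index$path, ~ pluck_path(x, .x))
  tibble(
    id = param_index$id,
    group = param_index$group,
    arm = param_index$arm,
    family = purrr::map_chr(specs, "family"),
    mean = purrr::map_dbl(specs, "mean"),
    se = purrr::map_dbl(specs, "se")
  )
}

# Named list of parameter means in the documented order; the deterministic
# model is evaluated at these values.
param_means <- function(params) {
  tbl <- tidy(params)
  setNames(as.list(tbl$mean), tbl$id)
}

param_spec <- function(params, id) {
  i <- match(id, param_index$id)
  if (is.na(i)) abort(paste0("unknown parameter id `", id, "`."))
  pluck_path(params, param_index$path[[i]])
}

# Replace the distribution spec (or just the mean) of named parameters.
# `overrides` is a named list: values may be numbers (mean replaced, se kept)
# or navcea_dist objects (spec replaced).
override_params <- function(params, overrides) {
  for (id in names(overrides)) {
    i <- match(id, param_index$id)
    if (is.na(i)) abort(paste0("unknown override key `", id, "`."))
    path <- param_index$path[[i]]
    old <- pluck_path(params, path)
    v <- overrides[[id]]
    new <- if (inherits(v, "navcea_dist")) {
      v
    } else {
      if (!is.numeric(v) || length(v) != 1) {
        abort(paste0("override `", id, "` must be a number or a dist_spec()."))
      }
      # moving a mean can make the stored se infeasible for a beta; keep the
      # spec valid by shrinking se to the feasible range when needed
      se <- old$se
      if (old$family == "beta" && se > 0 && se^2 >= v * (1 - v)) {
        se <- sqrt(v * (1 - v)) * 0.99
      }
      dist_spec(old$family, v, if (old$family == "fixed") 0 else se)
    }
    params <- assign_path(params, path, new)
  }
  params
}

#' Default parameter groups for value-of-information analysis
#'
#' Groups mirror the grouping used when reporting partial perfect information:
#' the resection-margin rates, the health-state transition probabilities, the
#' utilities, and the treatment costs (including the navigation addition).
#'
#' @param params A `navcea_params` object (unused, present for future
#'   indication-specific grouping).
#' @return Named list of character vectors of parameter ids.
#' @export
navcea_groups <- function(params = NULL) {
  tbl <- param_index
  list(
    margin_rates = tbl$id[tbl$group %in% c("margin_navigated", "margin_standard")],
    transition_probabilities = tbl$id[tbl$group == "transition_probabilities"],
    treatment_costs = tbl$id[tbl$group == "treatment_costs"],
    utilities = tbl$id[tbl$group == "utilities"]
  )
}

#' Compare stored per-cycle probabilities with their observed counts
#'
#' Converts each observed-count cell of the configuration to a per-cycle
#' probability with [observed_to_cycle_prob()] and sets it against the
#' canonical per-cycle mean stored in the configuration. Several published
#' cells cannot be re-derived exactly from the published counts (the at-risk
#' corrections used are not stated); those rows are reported as inconsistent
#' but the canonical means are never altered.
#'
#' @param params A `navcea_params` object.
#' @param tolerance Absolute tolerance on the per-cycle probability below
#'   which a cell counts as consistent (default `5e-4`, i.e. agreement at the
#'   printed 3-decimal precision).
#' @return A tibble with columns `cell`, `events`, `at_risk`,
#'   `observation_time`, `from_counts`, `canonical`, `consistent`. Margin
#'   cells are plain proportions and have `observation_time` `NA`.
#' @export
check_fixture_consistency <- function(params, tolerance = 5e-4) {
  oc <- params$observed_counts
  if (is.null(oc)) abort("configuration has no `observed_counts` block.")
  canonical <- c(
    margin_r0_navigated = params$margin_r0$navigated$mean,
    margin_r0_standard = params$margin_r0$standard$mean,
    progression_r0_year1 = params$transitions$df_to_pd$R0$year1$mean,
    progression_r0_year2 = params$transitions$df_to_pd$R0$year2$mean,
    progression_r0_year3 = params$transitions$df_to_pd$R0$year3$mean,
    progression_r0_year23 = params$transitions$df_to_pd$R0$year2$mean,
    progression_r1_year1 = params$transitions$df_to_pd$R1$year1$mean,
    progression_r1_year23 = params$transitions$df_to_pd$R1$year2$mean,
    death_after_progression_year1 = params$transitions$pd_to_death$entry_year1$mean,
    death_after_progression_year23 = params$transitions$pd_to_death$entry_year23$mean
  )
  rows <- purrr::map(names(oc), function(cell) {
    c0 <- oc[[cell]]
    margin <- is.null(c0$observation_time)
    from_counts <- if (margin) {
      c0$events / c0$at_risk
    } else {
      observed_to_cycle_prob(
        c0$events, c0$at_risk, c0$observation_time, params$cycle_length
      )
    }
    tibble(
      cell = cell, events = c0$events, at_risk = c0$at_risk,
      observation_time = c0$observation_time %||% NA_real_,
      from_counts = from_counts,
      canonical = unname(canonical[cell])
    )
  })
  out <- bind_rows(rows)
  out$consistent <- abs(out$from_counts - out$canonical) < tolerance
  out
}
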