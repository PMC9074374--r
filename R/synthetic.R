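#' Generate a synthetic patient-level cohort
#'
#' Simulates individual patients from the model's own generative process, so
#' that the count-to-probability estimation workflow can be tested end to end
#' by parameter recovery. Each patient draws a resection-margin status from
#' the strategy's R0 probability and then walks through the cohort model's
#' per-cycle hazards: in every cycle spent disease-free the patient
#' progresses with the margin- and year-class-specific probability or dies of
#' background causes with the background probability (a single uniform draw
#' decides among the competing exits, mirroring the cohort model's
#' simultaneous transitions); after progression the patient faces the
#' entry-class-specific per-cycle death probability until the horizon.
#'
#' A configurable fraction of patients can be forced to enter progressive
#' disease in cycle 1, emulating patients with limited metastatic disease
#' already present at surgery.
#'
#' @param params A `navcea_params` object.
#' @param n_per_arm Patients per strategy arm.
#' @param seed Integer seed.
#' @param metastatic_fraction Fraction of patients entering progressive
#'   disease in cycle 1 regardless of the progression hazards (default 0).
#' @return A tibble with one row per patient: `patient_id`, `indication`,
#'   `strategy`, `margin_status`, `progression_cycle` (integer or `NA`),
#'   `death_cycle` (integer or `NA`), `death_cause` (`"progression"`,
#'   `"background"` or `NA`), `censor_cycle` (the horizon).
#' @examples
#' params <- load_parameter_set(navcea_example("lrrc"))
#' cohort <- generate_cohort(params, n_per_arm = 100, seed = 1)
#' dplyr::count(cohort, strategy, margin_status)
#' @export
generate_cohort <- function(params, n_per_arm = 1000, seed = NULL,
                            metastatic_fraction = 0) {
  stopifnot(inherits(params, "navcea_params"), n_per_arm >= 1)
  stopifnot(metastatic_fraction >= 0, metastatic_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  pm <- param_means(params)
  H <- params$horizon_cycles
  cl <- params$cycle_length
  one_arm <- function(strategy) {
    n <- n_per_arm
    r0 <- params$margin_r0[[strategy]]$mean
    margin <- ifelse(runif(n) < r0, "R0", "R1")
    prog <- rep(NA_integer_, n)
    death <- rep(NA_integer_, n)
    cause <- rep(NA_character_, n)
    forced <- runif(n) < metastatic_fraction
    prog[forced] <- 1L
    in_df <- !forced
    for (k in seq_len(H)) {
      y <- min(cycle_year(k, cl), 3)
      p <- ifelse(
        margin == "R0",
        pm[[paste0("df_pd_r0_year", y)]],
        pm[[paste0("df_pd_r1_year", y)]]
      )
      u <- runif(n)
      progressed <- in_df & u < p
      bg_died <- in_df & !progressed & u < p + pm$df_death
      prog[progressed] <- k
      death[bg_died] <- k
      cause[bg_died] <- "background"
      in_df <- in_df & !progressed & !bg_died
    }
    # per-cycle death hazard after progression, by entry class
    has_prog <- !is.na(prog)
    d <- ifelse(prog[has_prog] <= 1 / cl, pm$pd_death_entry_year1,
      pm$pd_death_entry_year23
    )
    # geometric number of cycles survived in PD before death (no CRC death
    # possible when the hazard is zero)
    ttd <- rep(NA_integer_, sum(has_prog))
    pos <- d > 0
    ttd[pos] <- stats::rgeom(sum(pos), prob = d[pos]) + 1L
    dc <- prog[has_prog] + ttd
    dc[is.na(ttd) | dc > H] <- NA_integer_
    death[has_prog] <- dc
    cause[has_prog][!is.na(dc)] <- "progression"
    tibble(
      strategy = strategy, margin_status = margin,
      progression_cycle = prog, death_cycle = death,
      death_cause = cause, censor_cycle = H
    )
  }
  out <- bind_rows(one_arm("navigated"), one_arm("standard"))
  out %>%
    mutate(
      patient_id = row_number(),
      indication = params$indication,
      .before = 1
    )
}

#' Summarise a cohort into observed-count cells
#'
#' Tallies a patient-level cohort into the count cells the estimation
#' workflow consumes: R0 margins per strategy; progression events per margin
#' status and year class, with year-on-year nested risk sets (the year-2
#' risk set is the year-1 risk set minus year-1 progressions and background
#' deaths); and deaths after progression by progression-entry class. Death
#' cells use fixed post-entry observation windows so that the count-to-
#' probability conversion is exact under the model's constant per-cycle
#' hazards: two years for year-1 entrants, and one year for year-2/3
#' entrants restricted to those entering early enough to have a full year of
#' potential follow-up.
#'
#' @param cohort A tibble as produced by [generate_cohort()] (columns
#'   `strategy`, `margin_status`, `progression_cycle`, `death_cycle`,
#'   `death_cause`, `censor_cycle`).
#' @param cycles_per_year Cycles per year (4 for a three-month cycle).
#' @return A tibble with columns `cell`, `events`, `at_risk`,
#'   `observation_time` (years; `NA` for the margin proportions). Cell names
#'   match the `observed_counts` block of the model configurations, with
#'   additionally `progression_*_year2`/`year3` split out.
#' @export
summarize_counts <- function(cohort, cycles_per_year = 4) {
  needed <- c(
    "strategy", "margin_status", "progression_cycle", "death_cycle",
    "censor_cycle"
  )
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(missing, collapse = ", "), "."))
  }
  cpy <- cycles_per_year
  rows <- list()
  add <- function(cell, events, at_risk, obs = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble(
      cell = cell, events = as.integer(events),
      at_risk = as.integer(at_risk), observation_time = obs
    )
  }
  for (s in c("navigated", "standard")) {
    arm <- cohort[cohort$strategy == s, ]
    add(
      paste0("margin_r0_", s), sum(arm$margin_status == "R0"), nrow(arm)
    )
  }
  prog_year <- ceiling(cohort$progression_cycle / cpy)
  death_year <- ceiling(cohort$death_cycle / cpy)
  for (mg in c("R0", "R1")) {
    sel <- cohort$margin_status == mg
    tag <- tolower(mg)
    for (y in 1:3) {
      # in disease-free at the start of year y: neither progressed nor died
      # of background causes in an earlier year
      at_risk <- sel &
        !(sel & !is.na(prog_year) & prog_year < y) &
        !(sel & !is.na(cohort$death_cause) & cohort$death_cause == "background" &
          death_year < y)
      events <- at_risk & !is.na(prog_year) & prog_year == y
      add(
        sprintf("progression_%s_year%d", tag, y),
        sum(events), sum(at_risk), 1
      )
      if (y == 2) {
        events23 <- at_risk & !is.na(prog_year) & prog_year >= 2
        add(
          sprintf("progression_%s_year23", tag),
          sum(events23), sum(at_risk), 2
        )
      }
    }
  }
  # deaths after progression, fixed post-entry windows (see details)
  crc_death <- !is.na(cohort$death_cycle) &
    !is.na(cohort$progression_cycle) &
    cohort$death_cycle >= cohort$progression_cycle
  y1 <- !is.na(cohort$progression_cycle) & cohort$progression_cycle <= cpy
  add(
    "death_after_progression_year1",
    sum(y1 & crc_death &
      cohort$death_cycle - cohort$progression_cycle <= 2 * cpy),
    sum(y1), 2
  )
  horizon <- cohort$censor_cycle
  y23 <- !is.na(cohort$progression_cycle) &
    cohort$progression_cycle > cpy &
    cohort$progression_cycle <= horizon - cpy
  add(
    "death_after_progression_year23",
    sum(y23 & crc_death &
      cohort$death_cycle - cohort$progression_cycle <= cpy),
    sum(y23), 1
  )
  bind_rows(rows)
}
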