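#' Intervention scenario
#'
#' A proportional reduction of episode PM2.5 exposure for a target
#' population. Reduction fractions map from measured indoor infiltration
#' factors (exposure reduction ~ 1 - I/O_inf): sheltering with windows
#' open ~10\%, windows closed ~40\%, a DIY box fan with a MERV 13 filter
#' ~70\%, a HEPA portable air cleaner ~80\%.
#'
#' @param reduction_fraction fraction of episode exposure removed, in
#'   `[0, 1]`.
#' @param target `"total_population"` or `"poverty_population"`.
#' @param label free-text label (e.g. `"windows-closed"`).
#' @return Object of class `intervention_scenario`.
#' @export
intervention_scenario <- function(reduction_fraction,
                                  target = c("total_population",
                                             "poverty_population"),
                                  label = sprintf("%.0f%%",
                                                  100 * reduction_fraction)) {
  target <- match.arg(target)
  if (!is.numeric(reduction_fraction) || reduction_fraction < 0 ||
      reduction_fraction > 1)
    stop("reduction_fraction must lie in [0, 1]", call. = FALSE)
  structure(list(reduction_fraction = reduction_fraction, target = target,
                 label = label),
            class = "intervention_scenario")
}

#' Scale episode exposures under an intervention
#'
#' Multiplies episode concentrations by `1 - f` — interventions act on
#' what people breathe, so the whole episode concentration is scaled, not
#' just its increment over baseline. The concentration change and the
#' smoke-day flag are recomputed from the scaled concentrations, so large
#' reductions can de-classify smoke days (driving the step changes of the
#' odds-ratio approach). Baseline exposures are left untouched.
#'
#' @param deltas an [compute_deltas()] table.
#' @param f reduction fraction in `[0, 1]`.
#' @return A new `exposure_deltas` table.
#' @export
apply_reduction <- function(deltas, f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1)
    stop("reduction fraction must lie in [0, 1]", call. = FALSE)
  thr <- attr(deltas, "smoke_threshold")
  deltas$episode_pm25 <- (1 - f) * deltas$episode_pm25
  deltas$delta_c <- deltas$episode_pm25 - deltas$baseline_pm25
  deltas$smoke_day <- classify_smoke_day(deltas$episode_pm25, thr)
  deltas
}

#' Avoided mortality under an exposure-reduction scenario
#'
#' Runs the acute burden with and without the reduction and differences
#' them at each response level: avoided = burden(original) -
#' burden(reduced). For a poverty-targeted scenario both runs use the
#' poverty population as the exposed population — the reduction reaches
#' only that subgroup, and the untreated remainder cancels in the
#' difference.
#'
#' @param deltas an [compute_deltas()] table.
#' @param demo demographics table (needs `poverty_population` for
#'   poverty-targeted scenarios).
#' @param rf a [response_function()] (acute kind).
#' @param scenario an [intervention_scenario()].
#' @param beta_form passed to [run_acute()].
#' @return A `burden_estimate` data.frame of avoided deaths (columns named
#'   `excess_deaths_*` hold avoided deaths; attribute `scenario` carries
#'   the scenario).
#' @export
avoided_mortality <- function(deltas, demo, rf, scenario,
                              beta_form = "log") {
  stopifnot(inherits(scenario, "intervention_scenario"))
  if (scenario$target == "poverty_population") {
    stopifnot("poverty_population" %in% names(demo))
    demo$population <- demo$poverty_population
  }
  orig <- run_acute(deltas, demo, rf, beta_form)
  red <- run_acute(apply_reduction(deltas, scenario$reduction_fraction),
                   demo, rf, beta_form)
  out <- orig
  for (col in c("excess_deaths_central", "excess_deaths_low",
                "excess_deaths_high"))
    out[[col]] <- orig[[col]] - red[[col]]
  out$per_100k <- out$excess_deaths_central * 1e5 / out$population
  attr(out, "scenario") <- scenario
  out
}

#' Avoided-mortality table across reduction levels
#'
#' Statewide avoided deaths for each reduction fraction and each acute
#' response function — the standard intervention summary (rows =
#' reduction level, one response function per row group).
#'
#' @param deltas an [compute_deltas()] table.
#' @param demo demographics table.
#' @param rfs list of acute [response_function()]s.
#' @param reductions numeric vector of reduction fractions.
#' @param target scenario target population.
#' @param beta_form passed through.
#' @return data.frame with columns reduction, approach, endpoint,
#'   avoided_central/low/high.
#' @export
scenario_table <- function(deltas, demo, rfs,
                           reductions = c(0.10, 0.40, 0.70, 0.80, 1.00),
                           target = "total_population", beta_form = "log") {
  rfs <- Filter(function(r) r$kind != "annual_crf_percent_per_10", rfs)
  rows <- lapply(reductions, function(f) {
    do.call(rbind, lapply(rfs, function(rf) {
      av <- avoided_mortality(deltas, demo, rf,
                              intervention_scenario(f, target),
                              beta_form)
      st <- av[av$scope == "statewide", ]
      data.frame(reduction = f, approach = st$approach,
                 endpoint = st$endpoint,
                 avoided_central = st$excess_deaths_central,
                 avoided_low = st$excess_deaths_low,
                 avoided_high = st$excess_deaths_high,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cost model for a portable air cleaner program
#'
#' @param unit_cost USD per HEPA portable air cleaner (default 150).
#' @param household_size average persons per household (default 2.55).
#' @return Object of class `cost_model`.
#' @export
cost_model <- function(unit_cost = 150, household_size = 2.55) {
  stopifnot(unit_cost > 0, household_size > 0)
  structure(list(unit_cost = unit_cost, household_size = household_size),
            class = "cost_model")
}

#' Cost of a poverty-targeted portable air cleaner program
#'
#' One air cleaner per household below the poverty level: households =
#' the poverty population divided by the average household size, rounded
#' to the nearest integer; total cost = households times the unit cost.
#'
#' @param total_poverty_population persons below the poverty level.
#' @param cost a [cost_model()].
#' @return list with `households` and `total_cost_usd`.
#' @examples
#' pac_program_cost(785244) # 307,939 households, $46.19M
#' @export
pac_program_cost <- function(total_poverty_population,
                             cost = cost_model()) {
  stopifnot(inherits(cost, "cost_model"), total_poverty_population >= 0)
  households <- round(total_poverty_population / cost$household_size)
  list(households = households,
       total_cost_usd = households * cost$unit_cost)
}
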