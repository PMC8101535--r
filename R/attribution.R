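#' Response function for mortality attribution
#'
#' Wraps a literature exposure-response estimate with its 95\% confidence
#' bounds. Three kinds are supported: a daily concentration-response
#' function expressed as percent excess mortality per 10 ug/m3 of total
#' PM2.5 (`"crf_percent_per_10"`), an odds ratio of wildfire smoke days
#' (`"smoke_day_or"`), and an annual-average CRF for chronic burden
#' (`"annual_crf_percent_per_10"`).
#'
#' @param kind one of `"crf_percent_per_10"`, `"smoke_day_or"`,
#'   `"annual_crf_percent_per_10"`.
#' @param endpoint mortality endpoint, e.g. `"all_cause"`,
#'   `"respiratory"`, `"cardiorespiratory"`; must match a
#'   `rate_<endpoint>` demographics column.
#' @param central,ci_low,ci_high central estimate and 95\% CI bounds
#'   (percent for CRFs, dimensionless for odds ratios).
#' @return An object of class `response_function`.
#' @seealso [default_response_functions()]
#' @export
response_function <- function(kind, endpoint, central, ci_low, ci_high) {
  kind <- match.arg(kind, c("crf_percent_per_10", "smoke_day_or",
                            "annual_crf_percent_per_10"))
  stopifnot(ci_low <= central, central <= ci_high)
  if (kind == "smoke_day_or") {
    stopifnot(ci_low > 0)
    if (central < 1)
      warning("odds ratio below 1 yields a negative attributable fraction",
              call. = FALSE)
  } else {
    stopifnot(ci_low > -100)
  }
  structure(list(kind = kind, endpoint = endpoint, central = central,
                 ci_low = ci_low, ci_high = ci_high),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  unit <- if (x$kind == "smoke_day_or") "odds ratio"
          else "% per 10 ug/m3"
  cat(sprintf("<response_function> %s, %s: %.3g (95%% CI %.3g, %.3g) %s\n",
              x$kind, x$endpoint, x$central, x$ci_low, x$ci_high, unit))
  invisible(x)
}

#' Standard response-function set for wildfire smoke mortality
#'
#' The literature estimates used throughout: acute all-cause mortality
#' 0.50\% (95\% CI 0.00, 1.01) per 10 ug/m3 of total PM2.5 (West-coast
#' time-series CRF); smoke-day odds ratios 1.02 (1.00, 1.05) for all-cause
#' and 1.09 (1.00, 1.18) for respiratory mortality (Washington
#' case-crossover); chronic annual-average CRFs 5.60\% (3.50, 7.80) for
#' all-cause and 12.90\% (9.50, 16.40) for cardiorespiratory mortality per
#' 10 ug/m3 (American Cancer Society cohort extension). The null lower
#' bounds (0.00\% and OR 1.00) are what make the burden CIs floor at
#' exactly zero deaths.
#'
#' @return Named list of [response_function()] objects.
#' @export
default_response_functions <- function() {
  list(
    acute_crf_all_cause =
      response_function("crf_percent_per_10", "all_cause", 0.50, 0.00, 1.01),
    acute_or_all_cause =
      response_function("smoke_day_or", "all_cause", 1.02, 1.00, 1.05),
    acute_or_respiratory =
      response_function("smoke_day_or", "respiratory", 1.09, 1.00, 1.18),
    chronic_crf_all_cause =
      response_function("annual_crf_percent_per_10", "all_cause",
                        5.60, 3.50, 7.80),
    chronic_crf_cardiorespiratory =
      response_function("annual_crf_percent_per_10", "cardiorespiratory",
                        12.90, 9.50, 16.40))
}

#' Convert a percent-per-10-ug/m3 CRF to a log-linear coefficient
#'
#' `beta = log(1 + p/100) / 10` per ug/m3, the coefficient consistent with
#' the exponential attributable-fraction model `AF = 1 - exp(-beta * dc)`.
#' A linear conversion (`p / 1000`) is available for sensitivity analyses.
#'
#' @param percent_per_10 percent excess per 10 ug/m3 (> -100).
#' @param form `"log"` (default) or `"linear"`.
#' @return beta, per ug/m3.
#' @export
beta_from_percent <- function(percent_per_10, form = c("log", "linear")) {
  form <- match.arg(form)
  stopifnot(all(percent_per_10 > -100))
  if (form == "log") log(1 + percent_per_10 / 100) / 10
  else percent_per_10 / 1000
}

#' Attributable fraction from a concentration-response function
#'
#' `AF = 1 - exp(-beta * delta_c)`. For non-negative beta and delta_c the
#' result lies in `[0, 1)` and is approximately `beta * delta_c` for small
#' arguments. `delta_c` is expected to be already floored at 0 under the
#' acute attribution policy.
#'
#' @param beta log-linear CRF coefficient per ug/m3
#'   (see [beta_from_percent()]).
#' @param delta_c concentration change, ug/m3.
#' @return attributable fraction(s).
#' @export
af_crf <- function(beta, delta_c) {
  1 - exp(-beta * delta_c)
}

#' Attributable fraction from a smoke-day odds ratio
#'
#' `AF = (OR - 1) / OR`, the attributable fraction among days classified
#' as wildfire smoke days. Odds ratios below 1 give a negative fraction
#' and are flagged with a warning.
#'
#' @param or_value odds ratio (> 0).
#' @return attributable fraction(s).
#' @export
af_or <- function(or_value) {
  if (any(or_value <= 0))
    stop("odds ratio must be positive", call. = FALSE)
  if (any(or_value < 1))
    warning("odds ratio below 1 yields a negative attributable fraction",
            call. = FALSE)
  (or_value - 1) / or_value
}

#' Daily excess deaths from an attributable fraction
#'
#' `deltaY = AF * (annual_rate / 365) * population`: the annual
#' cause-specific mortality rate is converted to a daily rate and scaled
#' by the exposed population.
#'
#' @param af attributable fraction in (-1, 1).
#' @param annual_rate annual mortality rate, deaths per person-year.
#' @param population exposed persons.
#' @return expected excess deaths per day.
#' @export
excess_daily <- function(af, annual_rate, population) {
  stopifnot(all(af > -1), all(af < 1), all(annual_rate >= 0),
            all(population >= 0))
  af * (annual_rate / 365) * population
}

rate_column <- function(demo, endpoint) {
  col <- paste0("rate_", endpoint)
  if (!col %in% names(demo))
    stop("demographics table lacks column ", col, call. = FALSE)
  demo[[col]]
}

check_demo_coverage <- function(deltas, demo) {
  missing <- setdiff(unique(deltas$county_id), demo$county_id)
  if (length(missing))
    stop("missing demographics for county ",
         paste(missing, collapse = ", "), call. = FALSE)
}

rf_levels <- function(rf) c(central = rf$central, low = rf$ci_low,
                            high = rf$ci_high)

# shared assembly of the per-county + statewide burden table
burden_table <- function(county_ids, deaths, demo, endpoint, approach,
                         horizon) {
  i <- match(county_ids, demo$county_id)
  pop <- demo$population[i]
  df <- data.frame(scope = "county", county_id = county_ids,
                   endpoint = endpoint, approach = approach,
                   horizon = horizon,
                   excess_deaths_central = deaths[, "central"],
                   excess_deaths_low = deaths[, "low"],
                   excess_deaths_high = deaths[, "high"],
                   population = pop,
                   per_100k = deaths[, "central"] * 1e5 / pop,
                   stringsAsFactors = FALSE)
  tot <- colSums(deaths)
  state <- data.frame(scope = "statewide", county_id = "TOTAL",
                      endpoint = endpoint, approach = approach,
                      horizon = horizon,
                      excess_deaths_central = tot["central"],
                      excess_deaths_low = tot["low"],
                      excess_deaths_high = tot["high"],
                      population = sum(pop),
                      per_100k = tot["central"] * 1e5 / sum(pop),
                      stringsAsFactors = FALSE)
  out <- rbind(df, state)
  rownames(out) <- NULL
  class(out) <- c("burden_estimate", "data.frame")
  out
}

#' Acute episode mortality burden
#'
#' Computes excess deaths over the smoke episode, per county and
#' statewide, under one response function. With a CRF, the attributable
#' fraction on each county-day uses that day's concentration change
#' floored at 0 (`AF = 1 - exp(-beta * max(delta_c, 0))`); with a
#' smoke-day odds ratio, `AF = (OR - 1)/OR` is applied only on county-days
#' classified as smoke days. Daily excess deaths
#' `AF * annual_rate/365 * population` are summed over the episode days
#' and then over counties. The interval comes from re-running the whole
#' computation at the response function's CI bounds — with a null lower
#' bound (0.00\% or OR 1.00) the burden lower bound is exactly zero.
#'
#' @param deltas an [compute_deltas()] table.
#' @param demo demographics (county_id, population, `rate_*` columns).
#' @param rf a [response_function()] of kind `"crf_percent_per_10"` or
#'   `"smoke_day_or"`.
#' @param beta_form passed to [beta_from_percent()].
#' @return A `burden_estimate` data.frame: one row per county plus a
#'   statewide total row, with central/low/high excess deaths and deaths
#'   per 100,000 persons.
#' @export
run_acute <- function(deltas, demo, rf, beta_form = "log") {
  stopifnot(inherits(rf, "response_function"),
            rf$kind %in% c("crf_percent_per_10", "smoke_day_or"))
  check_demo_coverage(deltas, demo)
  i <- match(deltas$county_id, demo$county_id)
  rate <- rate_column(demo, rf$endpoint)[i]
  pop <- demo$population[i]
  ids <- sort(unique(deltas$county_id))
  dc <- pmax(deltas$delta_c, 0)

  deaths <- vapply(rf_levels(rf), function(v) {
    af <- if (rf$kind == "crf_percent_per_10")
      af_crf(beta_from_percent(v, beta_form), dc)
    else
      af_or(v) * as.numeric(deltas$smoke_day)
    daily <- excess_daily(af, rate, pop)
    as.numeric(tapply(daily, deltas$county_id, sum)[ids])
  }, numeric(length(ids)))
  if (length(ids) == 1L) deaths <- matrix(deaths, nrow = 1,
                                          dimnames = list(NULL, names(rf_levels(rf))))

  approach <- if (rf$kind == "crf_percent_per_10") "crf" else "or"
  burden_table(ids, deaths, demo, rf$endpoint, approach, "acute_episode")
}

#' Annual increment in average PM2.5 implied by the episode
#'
#' Averages the episode's (floored) daily concentration increases over the
#' whole year: `sum_k max(delta_c_k, 0) / 365` per county.
#'
#' @param deltas an [compute_deltas()] table.
#' @return named numeric vector of annual-average increments (ug/m3) per
#'   county.
#' @export
annual_increment <- function(deltas) {
  x <- tapply(pmax(deltas$delta_c, 0), deltas$county_id, sum) / 365
  stats::setNames(as.numeric(x), names(x))
}

#' Chronic mortality burden from episode-driven annual exposure
#'
#' Treats the episode's concentration increase, averaged over the entire
#' year, as a sustained increment in annual-average PM2.5 and applies an
#' annual CRF: per county,
#' `AF = 1 - exp(-beta * annual_increment)` and
#' `deltaY = AF * annual_rate * population` (the rate stays annual — no
#' division by 365).
#'
#' @param deltas an [compute_deltas()] table.
#' @param demo demographics table.
#' @param rf a [response_function()] of kind
#'   `"annual_crf_percent_per_10"`.
#' @param beta_form passed to [beta_from_percent()].
#' @return A `burden_estimate` data.frame (horizon `"chronic_annual"`).
#' @export
run_chronic <- function(deltas, demo, rf, beta_form = "log") {
  stopifnot(inherits(rf, "response_function"),
            rf$kind == "annual_crf_percent_per_10")
  check_demo_coverage(deltas, demo)
  inc <- annual_increment(deltas)
  ids <- names(inc)
  i <- match(ids, demo$county_id)
  rate <- rate_column(demo, rf$endpoint)[i]
  pop <- demo$population[i]

  deaths <- vapply(rf_levels(rf), function(v) {
    af_crf(beta_from_percent(v, beta_form), as.numeric(inc)) * rate * pop
  }, numeric(length(ids)))
  if (length(ids) == 1L) deaths <- matrix(deaths, nrow = 1,
                                          dimnames = list(NULL, names(rf_levels(rf))))

  burden_table(ids, deaths, demo, rf$endpoint, "crf", "chronic_annual")
}

#' @export
print.burden_estimate <- function(x, digits = 1, ...) {
  tot <- x[x$scope == "statewide", ]
  cat(sprintf("Burden estimate (%s, %s approach, %s):\n",
              tot$endpoint[1], tot$approach[1], tot$horizon[1]))
  cat(sprintf("  statewide excess deaths: %.*f (95%% CI %.*f, %.*f)\n",
              digits, tot$excess_deaths_central, digits,
              tot$excess_deaths_low, digits, tot$excess_deaths_high))
  cat(sprintf("  %d counties; largest per-100k burden: %s\n",
              sum(x$scope == "county"),
              x$county_id[x$scope == "county"][
                which.max(x$per_100k[x$scope == "county"])]))
  invisible(x)
}

#' Health impact assessment of a wildfire smoke episode
#'
#' High-level wrapper running the full pipeline: optional nephelometer
#' recalibration, county-day aggregation, neighbor imputation, baseline
#' matching, acute burden under both attribution conventions, and chronic
#' annualized burden. Returns a classed object with print, summary and
#' plot methods.
#'
#' @param readings monitor reading table with a `period` column, or a
#'   `synth_study` (then `demographics`/`adjacency` default to its
#'   tables).
#' @param demographics county demographics table.
#' @param adjacency county adjacency table.
#' @param response_functions list of [response_function()]s; acute and
#'   chronic kinds are dispatched automatically.
#' @param smoke_threshold smoke-day threshold, ug/m3.
#' @param correct_neph apply the nephelometer recalibration first?
#' @param calibration a [neph_calibration()].
#' @param beta_form CRF conversion, `"log"` or `"linear"`.
#' @return Object of class `smoke_hia`: list with `deltas`,
#'   `exposure_summary`, `acute` and `chronic` burden tables (rows bound
#'   across response functions), `demographics`, `response_functions`,
#'   `smoke_threshold` and the matched `call`.
#' @examples
#' study <- generate_study(synth_config(n_counties = 6, seed = 42))
#' fit <- smoke_hia(study)
#' fit
#' summary(fit)
#' @export
smoke_hia <- function(readings, demographics = NULL, adjacency = NULL,
                      response_functions = default_response_functions(),
                      smoke_threshold = 20.4, correct_neph = FALSE,
                      calibration = neph_calibration(),
                      beta_form = "log") {
  if (inherits(readings, "synth_study")) {
    if (is.null(demographics)) demographics <- readings$counties
    if (is.null(adjacency)) adjacency <- readings$adjacency
    readings <- readings$readings
  }
  deltas <- build_exposure(readings, adjacency,
                           county_ids = demographics$county_id,
                           correct_neph = correct_neph,
                           calibration = calibration,
                           smoke_threshold = smoke_threshold)
  acute_rfs <- Filter(function(r) r$kind != "annual_crf_percent_per_10",
                      response_functions)
  chronic_rfs <- Filter(function(r) r$kind == "annual_crf_percent_per_10",
                        response_functions)
  acute <- do.call(rbind, lapply(acute_rfs, run_acute, deltas = deltas,
                                 demo = demographics,
                                 beta_form = beta_form))
  chronic <- if (length(chronic_rfs))
    do.call(rbind, lapply(chronic_rfs, run_chronic, deltas = deltas,
                          demo = demographics, beta_form = beta_form))
  structure(list(deltas = deltas,
                 exposure_summary = summarize_exposure(deltas),
                 acute = acute, chronic = chronic,
                 demographics = demographics,
                 response_functions = response_functions,
                 smoke_threshold = smoke_threshold,
                 call = match.call()),
            class = "smoke_hia")
}

#' @export
print.smoke_hia <- function(x, digits = 1, ...) {
  cat("Wildfire smoke health impact assessment\n")
  es <- x$exposure_summary
  cat(sprintf("  exposure: baseline mean %.1f, episode mean %.1f, mean increase %.1f ug/m3\n",
              es$mean[es$period == "baseline"],
              es$mean[es$period == "episode"],
              es$mean[es$period == "increases"]))
  st <- x$acute[x$acute$scope == "statewide", ]
  for (j in seq_len(nrow(st)))
    cat(sprintf("  acute %-12s (%s): %.*f (95%% CI %.*f, %.*f) deaths\n",
                st$endpoint[j], st$approach[j],
                digits, st$excess_deaths_central[j],
                digits, st$excess_deaths_low[j],
                digits, st$excess_deaths_high[j]))
  if (!is.null(x$chronic)) {
    st <- x$chronic[x$chronic$scope == "statewide", ]
    for (j in seq_len(nrow(st)))
      cat(sprintf("  chronic %-10s (crf): %.*f (95%% CI %.*f, %.*f) deaths/yr\n",
                  st$endpoint[j], digits, st$excess_deaths_central[j],
                  digits, st$excess_deaths_low[j],
                  digits, st$excess_deaths_high[j]))
  }
  invisible(x)
}

#' @export
summary.smoke_hia <- function(object, ...) {
  out <- list(exposure = object$exposure_summary,
              acute_statewide =
                object$acute[object$acute$scope == "statewide", ],
              chronic_statewide = if (!is.null(object$chronic))
                object$chronic[object$chronic$scope == "statewide", ],
              ranking = rank_per_capita(object$acute))
  class(out) <- "summary.smoke_hia"
  out
}

#' @export
print.summary.smoke_hia <- function(x, ...) {
  cat("Exposure summary (county period means, ug/m3):\n")
  print(x$exposure, row.names = FALSE, digits = 3)
  cat("\nStatewide acute burden (episode deaths):\n")
  print(x$acute_statewide[, c("endpoint", "approach",
                              "excess_deaths_central", "excess_deaths_low",
                              "excess_deaths_high")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$chronic_statewide)) {
    cat("\nStatewide chronic burden (annualized deaths):\n")
    print(x$chronic_statewide[, c("endpoint", "excess_deaths_central",
                                  "excess_deaths_low",
                                  "excess_deaths_high")],
          row.names = FALSE, digits = 4)
  }
  cat("\nTop counties by per-capita burden (deaths per 100,000):\n")
  print(utils::head(x$ranking[, c("county_id", "endpoint", "approach",
                                  "excess_deaths_central", "per_100k")], 5),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.smoke_hia <- function(x, top = 15, ...) {
  r <- rank_per_capita(x$acute)
  r <- r[r$approach == r$approach[1] & r$endpoint == r$endpoint[1], ]
  r <- utils::head(r, top)
  graphics::barplot(rev(r$per_100k), names.arg = rev(r$county_id),
                    horiz = TRUE, las = 1,
                    xlab = "excess deaths per 100,000 persons",
                    main = "Acute burden per capita", ...)
  invisible(x)
}
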