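#' Configuration for the synthetic study generator
#'
#' Defines the statistical structure of a synthetic wildfire-smoke study:
#' a monitored county network, a low stable baseline window, and a smoke
#' episode that raises county-level daily means by a large, spatially
#' variable increment. Defaults emulate a 39-county state with a 13-day
#' episode: baseline daily means around 6.0 ug/m3 (SD 4.6), episode
#' increases around 97.1 ug/m3 with cross-county SD 28.5, and right-skewed
#' (log-normal) monitor readings around each county-day mean.
#'
#' @param n_counties number of counties.
#' @param monitors_per_county integer range `c(min, max)` of regulatory
#'   monitors per county; `min` may be 0 (such counties are imputed from
#'   neighbors downstream).
#' @param episode_days length of the smoke episode (and of the matched
#'   baseline window), in days.
#' @param baseline_mean,baseline_sd mean and SD (ug/m3) of the county-day
#'   true means in the baseline window.
#' @param episode_increase_mean,episode_increase_cross_county_sd mean and
#'   cross-county SD (ug/m3) of the county-level episode increment; the
#'   increment is drawn once per county and truncated at 0 by redraw.
#' @param within_county_rsd relative standard deviation (SD/mean) of
#'   monitor readings around the county-day true mean; readings are drawn
#'   from a moment-matched log-normal.
#' @param population_range,poverty_fraction_range ranges for county
#'   resident population (drawn log-uniformly, mimicking the right-skewed
#'   size distribution of real county populations) and for the uniform
#'   fraction of it below the poverty level.
#' @param mortality_rate_ranges named list of `c(min, max)` uniform ranges
#'   for annual cause-specific mortality rates (deaths per person-year);
#'   names become `rate_<endpoint>` demographic columns.
#' @param episode_start,baseline_start first calendar day of each window
#'   (the baseline window is the same dates one year earlier by default).
#' @param neph_fraction probability that a generated monitor is a
#'   nephelometer rather than an FRM-like instrument.
#' @param seed integer seed; the same configuration always regenerates
#'   byte-identical tables.
#' @return An object of class `synth_config`.
#' @seealso [generate_counties()], [generate_series()], [generate_study()]
#' @export
synth_config <- function(n_counties = 39L,
                         monitors_per_county = c(0L, 8L),
                         episode_days = 13L,
                         baseline_mean = 6.0,
                         baseline_sd = 4.6,
                         episode_increase_mean = 97.1,
                         episode_increase_cross_county_sd = 28.5,
                         within_county_rsd = 0.25,
                         population_range = c(2200, 2250000),
                         poverty_fraction_range = c(0.07, 0.20),
                         mortality_rate_ranges = list(
                           all_cause = c(0.0060, 0.0120),
                           respiratory = c(0.0005, 0.0012),
                           cardiorespiratory = c(0.0020, 0.0045)),
                         episode_start = as.Date("2020-09-07"),
                         baseline_start = as.Date("2019-09-07"),
                         neph_fraction = 0.5,
                         seed = 123L) {
  cfg <- list(n_counties = as.integer(n_counties),
              monitors_per_county = as.integer(monitors_per_county),
              episode_days = as.integer(episode_days),
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              episode_increase_mean = episode_increase_mean,
              episode_increase_cross_county_sd = episode_increase_cross_county_sd,
              within_county_rsd = within_county_rsd,
              population_range = population_range,
              poverty_fraction_range = poverty_fraction_range,
              mortality_rate_ranges = mortality_rate_ranges,
              episode_start = as.Date(episode_start),
              baseline_start = as.Date(baseline_start),
              neph_fraction = neph_fraction,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_counties >= 1L, cfg$episode_days >= 1L,
            length(cfg$monitors_per_county) == 2L,
            cfg$monitors_per_county[1] <= cfg$monitors_per_county[2],
            cfg$monitors_per_county[1] >= 0L,
            cfg$baseline_mean > 0, cfg$baseline_sd >= 0,
            cfg$episode_increase_mean >= 0,
            cfg$episode_increase_cross_county_sd >= 0,
            cfg$within_county_rsd >= 0,
            cfg$population_range[1] > 0,
            cfg$population_range[1] <= cfg$population_range[2],
            cfg$poverty_fraction_range[1] >= 0,
            cfg$poverty_fraction_range[2] <= 1,
            cfg$poverty_fraction_range[1] <= cfg$poverty_fraction_range[2],
            cfg$neph_fraction >= 0, cfg$neph_fraction <= 1,
            length(cfg$mortality_rate_ranges) >= 1)
  for (r in cfg$mortality_rate_ranges)
    stopifnot(length(r) == 2L, r[1] >= 0, r[2] < 1, r[1] <= r[2])
  if (cfg$monitors_per_county[2] == 0L)
    stop("impossible configuration: every county forced to zero monitors, ",
         "so no county could ever be imputed", call. = FALSE)
  if (cfg$n_counties == 1L && cfg$monitors_per_county[1] == 0L &&
      cfg$monitors_per_county[2] == 0L)
    stop("impossible configuration: a single unmonitored county has no ",
         "neighbor to impute from", call. = FALSE)
  invisible(cfg)
}

# normal draw truncated strictly above `lower` by redraw (no point mass)
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw from a log-normal parameterized by arithmetic mean and RSD
#'
#' Method-of-moments parameterization: for target mean `m` and relative
#' standard deviation `r`, sigma^2 = log(1 + r^2) and
#' mu = log(m) - sigma^2 / 2, so the draws have exactly the requested
#' arithmetic mean and RSD. `rsd = 0` degenerates to the constant `m`.
#'
#' @param n number of draws.
#' @param mean target arithmetic mean (> 0).
#' @param rsd target relative standard deviation (SD/mean, >= 0).
#' @return numeric vector of positive draws.
#' @export
rlnorm_mean_rsd <- function(n, mean, rsd) {
  stopifnot(all(mean > 0), all(rsd >= 0))
  if (length(rsd) == 1L) rsd <- rep(rsd, length.out = max(n, length(mean)))
  sigma2 <- log(1 + rsd^2)
  out <- stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2,
                       sdlog = sqrt(sigma2))
  # degenerate components: rlnorm with sdlog 0 already returns the mean,
  # but guard against 0*Inf edge cases from vector recycling
  zero <- rsd == 0
  if (any(zero)) out[zero] <- rep(mean, length.out = length(out))[zero]
  out
}

#' Generate a synthetic county network with demographics
#'
#' Builds county ids, a symmetric ring adjacency, a monitor roster and
#' county demographics (population, poverty population, annual
#' cause-specific mortality rates). When the configured monitor range
#' permits, at least one county is left unmonitored and at least one has
#' two or more monitors, so that both neighbor imputation and RSD
#' estimation are exercised downstream; every unmonitored county is
#' guaranteed a monitored neighbor.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `synth_counties` with elements `counties`
#'   (county_id, population, poverty_population, `rate_*` columns,
#'   n_monitors), `monitors` (county_id, monitor_id, monitor_type) and
#'   `adjacency` (county_id, neighbor_id; both directions present).
#' @export
generate_counties <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_counties
  ids <- sprintf("C%03d", seq_len(n))

  # ring adjacency: county i borders i-1 and i+1
  if (n >= 3L) {
    adjacency <- data.frame(
      county_id = rep(ids, each = 2L),
      neighbor_id = as.vector(vapply(seq_len(n), function(i)
        ids[c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)],
        character(2))),
      stringsAsFactors = FALSE)
  } else if (n == 2L) {
    adjacency <- data.frame(county_id = ids, neighbor_id = rev(ids),
                            stringsAsFactors = FALSE)
  } else {
    adjacency <- data.frame(county_id = character(0),
                            neighbor_id = character(0))
  }

  mn <- cfg$monitors_per_county[1]; mx <- cfg$monitors_per_county[2]
  n_mon <- sample(seq.int(mn, mx), n, replace = TRUE)
  # honor the structural guarantees the range permits
  if (mn == 0L && n >= 2L && !any(n_mon == 0L))
    n_mon[which.min(n_mon)] <- 0L
  if (mx >= 2L && !any(n_mon >= 2L)) {
    cand <- if (any(n_mon > 0L)) which(n_mon > 0L)[1] else n
    n_mon[cand] <- 2L
  }
  if (all(n_mon == 0L))
    stop("impossible configuration: no county received a monitor",
         call. = FALSE)
  # each unmonitored county needs a monitored neighbor to impute from
  if (n >= 2L) {
    repeat {
      fixed <- FALSE
      for (i in which(n_mon == 0L)) {
        nb <- match(adjacency$neighbor_id[adjacency$county_id == ids[i]], ids)
        if (all(n_mon[nb] == 0L)) { n_mon[nb[1]] <- 1L; fixed <- TRUE }
      }
      if (!fixed) break
    }
  }

  monitors <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (n_mon[i] == 0L) return(NULL)
    data.frame(county_id = ids[i],
               monitor_id = sprintf("%s_M%d", ids[i], seq_len(n_mon[i])),
               monitor_type = sample(c("frm", "neph"), n_mon[i],
                                     replace = TRUE,
                                     prob = c(1 - cfg$neph_fraction,
                                              cfg$neph_fraction)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(monitors))
    monitors <- data.frame(county_id = character(0), monitor_id = character(0),
                           monitor_type = character(0))

  # county populations are strongly right-skewed (few metro counties,
  # many small rural ones): draw log-uniformly over the range
  pop <- round(exp(stats::runif(n, log(cfg$population_range[1]),
                                log(cfg$population_range[2]))))
  pov <- round(pop * stats::runif(n, cfg$poverty_fraction_range[1],
                                  cfg$poverty_fraction_range[2]))
  counties <- data.frame(county_id = ids, population = pop,
                         poverty_population = pov, n_monitors = n_mon,
                         stringsAsFactors = FALSE)
  for (ep in names(cfg$mortality_rate_ranges)) {
    r <- cfg$mortality_rate_ranges[[ep]]
    counties[[paste0("rate_", ep)]] <- stats::runif(n, r[1], r[2])
  }

  structure(list(counties = counties, monitors = monitors,
                 adjacency = adjacency, cfg = cfg),
            class = "synth_counties")
}

#' Generate daily monitor readings for the baseline and episode windows
#'
#' For each county, a true daily mean is drawn for every baseline day
#' (normal around `baseline_mean`, truncated above 0 by redraw) and every
#' episode day (an independent baseline-like daily level plus a single
#' county-level episode increment drawn around `episode_increase_mean`
#' with the configured cross-county SD, truncated at 0 by redraw). Each
#' monitor-day reading is then drawn from a log-normal with that true mean
#' and the configured within-county RSD. The true county-day means and the
#' analytically implied burden (computed directly from the attribution
#' arithmetic on the true means, for the standard acute response
#' functions) are returned as a ground-truth sidecar for recovery tests.
#'
#' @param cfg a [synth_config()].
#' @param counties result of [generate_counties()].
#' @return A list of class `synth_series` with `readings` (county_id,
#'   monitor_id, monitor_type, date, period, pm25), `truth` (county_id,
#'   period, day_index, date, true_mean) and `truth_burden` (statewide
#'   deaths implied by the true means; columns approach, endpoint, level,
#'   deaths).
#' @export
generate_series <- function(cfg, counties) {
  stopifnot(inherits(counties, "synth_counties"))
  validate_synth_config(cfg)
  set.seed(cfg$seed + 1L)
  k <- cfg$episode_days
  ids <- counties$counties$county_id
  n <- length(ids)

  base_dates <- cfg$baseline_start + 0:(k - 1)
  epi_dates <- cfg$episode_start + 0:(k - 1)

  increase <- if (cfg$episode_increase_mean == 0 &&
                  cfg$episode_increase_cross_county_sd == 0) rep(0, n)
              else if (cfg$episode_increase_cross_county_sd == 0)
                rep(cfg$episode_increase_mean, n)
              else rnorm_trunc(n, cfg$episode_increase_mean,
                               cfg$episode_increase_cross_county_sd,
                               lower = 0)
  base_mean <- matrix(rnorm_trunc(n * k, cfg$baseline_mean, cfg$baseline_sd),
                      nrow = n)
  epi_mean <- matrix(rnorm_trunc(n * k, cfg$baseline_mean, cfg$baseline_sd),
                     nrow = n) + increase

  truth <- rbind(
    data.frame(county_id = rep(ids, each = k), period = "baseline",
               day_index = rep(seq_len(k), n),
               date = rep(base_dates, n),
               true_mean = as.vector(t(base_mean)),
               stringsAsFactors = FALSE),
    data.frame(county_id = rep(ids, each = k), period = "episode",
               day_index = rep(seq_len(k), n),
               date = rep(epi_dates, n),
               true_mean = as.vector(t(epi_mean)),
               stringsAsFactors = FALSE))

  mon <- counties$monitors
  readings <- NULL
  if (nrow(mon) > 0) {
    rows <- merge(mon,
                  truth[, c("county_id", "period", "date", "true_mean")],
                  by = "county_id")
    rows <- rows[order(rows$monitor_id, rows$date), , drop = FALSE]
    rows$pm25 <- rlnorm_mean_rsd(nrow(rows), rows$true_mean,
                                 cfg$within_county_rsd)
    readings <- rows[, c("county_id", "monitor_id", "monitor_type",
                         "date", "period", "pm25")]
    rownames(readings) <- NULL
  }

  structure(list(readings = readings, truth = truth,
                 truth_burden = truth_burden_table(truth, counties$counties),
                 cfg = cfg),
            class = "synth_series")
}

# analytic statewide burden implied by the true county-day means, written
# as direct arithmetic (deliberately independent of run_acute) so it can
# serve as the oracle in end-to-end recovery tests
truth_burden_table <- function(truth, demo, smoke_threshold = 20.4) {
  base <- truth[truth$period == "baseline", ]
  epi <- truth[truth$period == "episode", ]
  key <- function(d) paste(d$county_id, d$day_index)
  epi <- epi[order(epi$county_id, epi$day_index), ]
  base <- base[match(key(epi), key(base)), ]
  delta <- pmax(epi$true_mean - base$true_mean, 0)
  smoke <- epi$true_mean > smoke_threshold
  i <- match(epi$county_id, demo$county_id)
  pop <- demo$population[i]

  rfs <- list(
    list(approach = "crf", endpoint = "all_cause",
         values = c(central = 0.50, low = 0.00, high = 1.01)),
    list(approach = "or", endpoint = "all_cause",
         values = c(central = 1.02, low = 1.00, high = 1.05)),
    list(approach = "or", endpoint = "respiratory",
         values = c(central = 1.09, low = 1.00, high = 1.18)))

  out <- do.call(rbind, lapply(rfs, function(rf) {
    rate <- demo[[paste0("rate_", rf$endpoint)]][i]
    deaths <- vapply(rf$values, function(v) {
      af <- if (rf$approach == "crf") 1 - exp(-log(1 + v / 100) / 10 * delta)
            else (v - 1) / v * as.numeric(smoke)
      sum(af * rate / 365 * pop)
    }, numeric(1))
    data.frame(approach = rf$approach, endpoint = rf$endpoint,
               level = names(deaths), deaths = unname(deaths),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_counties()] then
#' [generate_series()] under the configuration's single seed.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `synth_study` with `counties`, `monitors`,
#'   `adjacency`, `readings`, `truth`, `truth_burden` and the `cfg` used.
#' @examples
#' study <- generate_study(synth_config(n_counties = 8, seed = 1))
#' head(study$readings)
#' @export
generate_study <- function(cfg = synth_config()) {
  counties <- generate_counties(cfg)
  series <- generate_series(cfg, counties)
  structure(list(counties = counties$counties, monitors = counties$monitors,
                 adjacency = counties$adjacency, readings = series$readings,
                 truth = series$truth, truth_burden = series$truth_burden,
                 cfg = cfg),
            class = "synth_study")
}

#' Write a synthetic study to CSV files
#'
#' Emits the same schemas the pipeline reads: `monitor_readings.csv`
#' (county_id, monitor_id, monitor_type, date, period, pm25),
#' `demographics.csv`, `adjacency.csv`, plus the ground-truth sidecars
#' `truth_county_day.csv` and `truth_burden.csv`.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(monitor_readings = "monitor_readings.csv",
             demographics = "demographics.csv",
             adjacency = "adjacency.csv",
             truth_county_day = "truth_county_day.csv",
             truth_burden = "truth_burden.csv")
  tabs <- list(study$readings, study$counties, study$adjacency,
               study$truth, study$truth_burden)
  paths <- file.path(dir, files)
  for (j in seq_along(tabs))
    utils::write.csv(tabs[[j]], paths[j], row.names = FALSE)
  invisible(paths)
}
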