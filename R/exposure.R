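#' Nephelometer calibration parameters
#'
#' During dense smoke plumes, nephelometers calibrated against
#' FRM gravimetric measurements under ordinary conditions systematically
#' overestimate PM2.5. The recalibration divides affected readings by
#' `1 + overestimation_fraction`, and only applies above a concentration
#' threshold because the wildfire-season calibration is defined there.
#'
#' @param overestimation_fraction fractional overestimate of nephelometer
#'   readings relative to the original calibration (default 0.207, i.e.
#'   20.7\%).
#' @param apply_above concentration (ug/m3) above which the correction
#'   applies (default 20).
#' @return An object of class `neph_calibration`.
#' @export
neph_calibration <- function(overestimation_fraction = 0.207,
                             apply_above = 20) {
  stopifnot(overestimation_fraction > -1, apply_above >= 0)
  structure(list(overestimation_fraction = overestimation_fraction,
                 apply_above = apply_above),
            class = "neph_calibration")
}

#' Recalibrate nephelometer readings for wildfire smoke bias
#'
#' Divides every nephelometer reading above the calibration threshold by
#' `1 + overestimation_fraction`; FRM-like readings and readings at or
#' below the threshold are unchanged. Applied per reading, before any
#' county averaging, because the bias is instrument-level.
#'
#' @param readings monitor reading table with columns `monitor_type`
#'   (values `"frm"`/`"neph"`) and `pm25`.
#' @param calib a [neph_calibration()].
#' @return The reading table with corrected `pm25`.
#' @export
correct_nephelometers <- function(readings, calib = neph_calibration()) {
  stopifnot(inherits(calib, "neph_calibration"),
            all(c("monitor_type", "pm25") %in% names(readings)))
  idx <- readings$monitor_type == "neph" & readings$pm25 > calib$apply_above
  readings$pm25[idx] <- readings$pm25[idx] / (1 + calib$overestimation_fraction)
  readings
}

#' Average monitor readings to county-day exposures
#'
#' Per county and day, the exposure is the arithmetic mean over that
#' county's reporting monitors. Counties listed in `county_ids` without a
#' reading on a given day are emitted with `pm25 = NA`, `n_monitors = 0`
#' and provenance `"pending"`, to be filled by [impute_unmonitored()].
#'
#' @param readings monitor reading table (county_id, monitor_id, date,
#'   pm25, optionally period).
#' @param county_ids character vector of all study counties; defaults to
#'   the counties present in `readings` (then no pending rows appear).
#' @return County-day exposure data.frame (county_id, date, period if
#'   available, pm25, n_monitors, provenance), one row per county per day.
#' @export
aggregate_county_day <- function(readings, county_ids = NULL) {
  if (is.null(county_ids)) county_ids <- sort(unique(readings$county_id))
  empty <- data.frame(county_id = character(0), date = as.Date(character(0)),
                      period = character(0), pm25 = numeric(0),
                      n_monitors = integer(0), provenance = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(readings) == 0) return(empty)
  stopifnot(all(readings$pm25 >= 0),
            !anyDuplicated(readings[c("monitor_id", "date")]))

  dates <- sort(unique(readings$date))
  grid <- expand.grid(county_id = county_ids, date = dates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(readings$county_id, readings$date)
  gkey <- paste(grid$county_id, grid$date)
  grid$pm25 <- as.numeric(tapply(readings$pm25, key, mean)[gkey])
  grid$n_monitors <- as.integer(tapply(readings$pm25, key, length)[gkey])
  grid$n_monitors[is.na(grid$n_monitors)] <- 0L
  grid$provenance <- ifelse(grid$n_monitors > 0, "monitored", "pending")
  if ("period" %in% names(readings)) {
    pmap <- tapply(readings$period, readings$date, function(x) x[1])
    grid$period <- as.character(pmap[as.character(grid$date)])
    grid <- grid[, c("county_id", "date", "period", "pm25",
                     "n_monitors", "provenance")]
  }
  grid <- grid[order(grid$county_id, grid$date), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Impute unmonitored county-days from adjacent monitored counties
#'
#' Each pending county-day receives the unweighted mean of its adjacent
#' counties' same-day monitored values, with provenance
#' `"neighbor-imputed"`. Already-resolved rows are untouched, so the
#' operation is idempotent. Only directly monitored neighbors donate;
#' imputed values never propagate.
#'
#' @param county_days output of [aggregate_county_day()].
#' @param adjacency data.frame (county_id, neighbor_id), symmetric.
#' @return The county-day table with no pending rows.
#' @export
impute_unmonitored <- function(county_days, adjacency) {
  pend <- which(county_days$provenance == "pending")
  if (length(pend) == 0) return(county_days)
  for (i in pend) {
    cid <- county_days$county_id[i]
    d <- county_days$date[i]
    nb <- adjacency$neighbor_id[adjacency$county_id == cid]
    donor <- county_days$pm25[county_days$county_id %in% nb &
                              county_days$date == d &
                              county_days$provenance == "monitored"]
    if (length(donor) == 0)
      stop(sprintf(
        "imputation failure: county %s has no monitored neighbor on %s",
        cid, format(d)), call. = FALSE)
    county_days$pm25[i] <- mean(donor)
    county_days$provenance[i] <- "neighbor-imputed"
  }
  county_days
}

#' Classify a wildfire smoke day
#'
#' A day counts as a wildfire smoke day when its daily PM2.5 strictly
#' exceeds the threshold (default 20.4 ug/m3, the concentration criterion
#' of the odds-ratio source study). Secondary criteria for intermediate
#' concentrations are not implemented; supply a custom classifier to the
#' pipeline functions if needed.
#'
#' @param pm25 daily PM2.5 concentration(s), ug/m3.
#' @param threshold classification threshold, ug/m3.
#' @return logical vector.
#' @export
classify_smoke_day <- function(pm25, threshold = 20.4) {
  stopifnot(all(pm25 >= 0, na.rm = TRUE))
  pm25 > threshold
}

#' Pair episode and baseline exposures into daily deltas
#'
#' Pairs county-days by day index within each window (episode day k
#' against baseline day k, i.e. identical calendar dates one year apart
#' under the default windows). The concentration change
#' `delta_c = episode - baseline` is retained with its sign; flooring of
#' negative changes is an attribution-stage policy, not an exposure fact.
#' Smoke-day status is classified on the episode concentration.
#'
#' @param episode,baseline county-day exposure tables with equal per-county
#'   lengths (no pending rows).
#' @param smoke_threshold passed to [classify_smoke_day()].
#' @param smoke_classifier optional function(pm25) replacing the default
#'   threshold rule.
#' @return data.frame of class `exposure_deltas` (county_id, day_index,
#'   baseline_pm25, episode_pm25, delta_c, smoke_day) with the threshold
#'   stored as attribute `smoke_threshold`.
#' @export
compute_deltas <- function(episode, baseline, smoke_threshold = 20.4,
                           smoke_classifier = NULL) {
  stopifnot(!any(episode$provenance == "pending"),
            !any(baseline$provenance == "pending"))
  episode <- episode[order(episode$county_id, episode$date), ]
  baseline <- baseline[order(baseline$county_id, baseline$date), ]
  ne <- table(episode$county_id); nb <- table(baseline$county_id)
  if (!identical(sort(names(ne)), sort(names(nb))) ||
      !all(ne == nb[names(ne)]))
    stop("episode and baseline windows must cover the same counties with ",
         "equal numbers of days", call. = FALSE)
  idx <- stats::ave(seq_len(nrow(episode)), episode$county_id,
                    FUN = seq_along)
  out <- data.frame(county_id = episode$county_id, day_index = idx,
                    baseline_pm25 = baseline$pm25, episode_pm25 = episode$pm25,
                    stringsAsFactors = FALSE)
  out$delta_c <- out$episode_pm25 - out$baseline_pm25
  out$smoke_day <- if (is.null(smoke_classifier))
    classify_smoke_day(out$episode_pm25, smoke_threshold)
  else smoke_classifier(out$episode_pm25)
  attr(out, "smoke_threshold") <- smoke_threshold
  class(out) <- c("exposure_deltas", "data.frame")
  out
}

#' Summarize exposures at the county-period-mean level
#'
#' Statistics (mean, SD, median, range, min, max) are computed over the
#' county-level period means — one value per county per period — matching
#' the granularity of a state-level exposure summary table. The
#' "increases" row summarizes the per-county difference of period means.
#'
#' @param deltas an [compute_deltas()] result.
#' @return data.frame with rows baseline / episode / increases.
#' @export
summarize_exposure <- function(deltas) {
  stopifnot(nrow(deltas) > 0)
  base <- tapply(deltas$baseline_pm25, deltas$county_id, mean)
  epi <- tapply(deltas$episode_pm25, deltas$county_id, mean)
  inc <- epi - base
  stat_row <- function(x) {
    s <- if (length(x) > 1) stats::sd(x) else 0
    data.frame(mean = mean(x), sd = s, median = stats::median(x),
               range = max(x) - min(x), min = min(x), max = max(x))
  }
  out <- rbind(stat_row(base), stat_row(epi), stat_row(inc))
  out <- cbind(period = c("baseline", "episode", "increases"), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# split a resolved county-day table into its baseline/episode windows
split_periods <- function(county_days) {
  stopifnot("period" %in% names(county_days))
  list(baseline = county_days[county_days$period == "baseline", ],
       episode = county_days[county_days$period == "episode", ])
}

#' Build county-day exposure deltas from monitor readings
#'
#' The full exposure stage: optional nephelometer recalibration (per
#' reading, before averaging), county-day aggregation, neighbor imputation
#' of unmonitored counties, and pairing of episode against baseline days.
#'
#' @param readings monitor reading table with a `period` column
#'   (`"baseline"`/`"episode"`).
#' @param adjacency county adjacency table.
#' @param county_ids all study counties (defaults to those in `readings`
#'   plus those in `adjacency`).
#' @param correct_neph apply [correct_nephelometers()] first?
#' @param calibration a [neph_calibration()].
#' @param smoke_threshold,smoke_classifier passed to [compute_deltas()].
#' @return An `exposure_deltas` table.
#' @export
build_exposure <- function(readings, adjacency, county_ids = NULL,
                           correct_neph = FALSE,
                           calibration = neph_calibration(),
                           smoke_threshold = 20.4, smoke_classifier = NULL) {
  if (is.null(county_ids))
    county_ids <- sort(unique(c(readings$county_id, adjacency$county_id)))
  if (correct_neph) readings <- correct_nephelometers(readings, calibration)
  cd <- aggregate_county_day(readings, county_ids)
  cd <- impute_unmonitored(cd, adjacency)
  p <- split_periods(cd)
  compute_deltas(p$episode, p$baseline, smoke_threshold, smoke_classifier)
}
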