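# Shared fixtures, all generated in code.

# small synthetic state: fast but still exercises zero-monitor and
# multi-monitor counties
small_cfg <- function(seed = 7, ...) {
  synth_config(n_counties = 10, monitors_per_county = c(0, 3),
               seed = seed, ...)
}

# hand-built two-county deltas table with known numbers
tiny_deltas <- function(delta = c(100, 50), baseline = c(3, 3),
                        n_days = 2, smoke_threshold = 20.4) {
  ids <- sprintf("A%d", seq_along(delta))
  out <- data.frame(
    county_id = rep(ids, each = n_days),
    day_index = rep(seq_len(n_days), length(delta)),
    baseline_pm25 = rep(baseline, each = n_days),
    episode_pm25 = rep(baseline + delta, each = n_days),
    stringsAsFactors = FALSE)
  out$delta_c <- out$episode_pm25 - out$baseline_pm25
  out$smoke_day <- out$episode_pm25 > smoke_threshold
  attr(out, "smoke_threshold") <- smoke_threshold
  class(out) <- c("exposure_deltas", "data.frame")
  out
}

tiny_demo <- function(pop = c(1e5, 5e4), pov_frac = 0.1,
                      rate_all_cause = c(0.009, 0.010),
                      rate_respiratory = c(0.0008, 0.0009)) {
  data.frame(county_id = sprintf("A%d", seq_along(pop)),
             population = pop,
             poverty_population = round(pop * pov_frac),
             rate_all_cause = rate_all_cause,
             rate_respiratory = rate_respiratory,
             stringsAsFactors = FALSE)
}

crf_all_cause <- function()
  response_function("crf_percent_per_10", "all_cause", 0.50, 0.00, 1.01)
or_all_cause <- function()
  response_function("smoke_day_or", "all_cause", 1.02, 1.00, 1.05)
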