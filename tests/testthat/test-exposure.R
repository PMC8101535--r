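readings_df <- function(pm25, type = "frm", county = "C1",
                        date = as.Date("2020-09-07")) {
  data.frame(county_id = county,
             monitor_id = sprintf("%s_M%d", county, seq_along(pm25)),
             monitor_type = type, date = date, pm25 = pm25,
             stringsAsFactors = FALSE)
}

test_that("nephelometer correction rescales only affected readings", {
  r <- readings_df(c(120.7, 15.0, 120.7),
                   type = c("neph", "neph", "frm"))
  out <- correct_nephelometers(r)
  expect_equal(out$pm25, c(100.0, 15.0, 120.7))
  # exactly at the threshold: untouched (strictly above applies)
  at <- correct_nephelometers(readings_df(20, type = "neph"))
  expect_equal(at$pm25, 20)
  # custom calibration
  out2 <- correct_nephelometers(readings_df(50, type = "neph"),
                                neph_calibration(0.25, 30))
  expect_equal(out2$pm25, 40)
})

test_that("county-day aggregation averages monitors and flags gaps", {
  r <- rbind(readings_df(c(90, 110), county = "C1"),
             readings_df(42, county = "C2"))
  cd <- aggregate_county_day(r, county_ids = c("C1", "C2", "C3"))
  expect_equal(cd$pm25[cd$county_id == "C1"], 100.0)
  expect_equal(cd$n_monitors[cd$county_id == "C1"], 2L)
  expect_equal(cd$pm25[cd$county_id == "C2"], 42.0)
  expect_true(is.na(cd$pm25[cd$county_id == "C3"]))
  expect_equal(cd$provenance[cd$county_id == "C3"], "pending")
  # empty input is empty output, not an error
  expect_equal(nrow(aggregate_county_day(r[0, ])), 0)
})

test_that("unmonitored counties take the mean of monitored neighbors", {
  r <- rbind(readings_df(80, county = "C1"), readings_df(120, county = "C2"))
  adj <- data.frame(county_id = c("C3", "C3", "C1", "C2"),
                    neighbor_id = c("C1", "C2", "C3", "C3"))
  cd <- impute_unmonitored(aggregate_county_day(r, c("C1", "C2", "C3")), adj)
  i <- cd$county_id == "C3"
  expect_equal(cd$pm25[i], 100.0)
  expect_equal(cd$provenance[i], "neighbor-imputed")
  expect_equal(cd$n_monitors[i], 0L)
  # single donor
  adj1 <- data.frame(county_id = c("C3", "C1"), neighbor_id = c("C1", "C3"))
  cd1 <- impute_unmonitored(aggregate_county_day(
    readings_df(55, county = "C1"), c("C1", "C3")), adj1)
  expect_equal(cd1$pm25[cd1$county_id == "C3"], 55.0)
  # isolated unmonitored county errors with county and date
  adj0 <- data.frame(county_id = character(0), neighbor_id = character(0))
  expect_error(impute_unmonitored(aggregate_county_day(
    readings_df(55, county = "C1"), c("C1", "C3")), adj0),
    "C3.*2020-09-07")
})

test_that("aggregation + imputation is idempotent", {
  study <- generate_study(small_cfg())
  cd <- impute_unmonitored(
    aggregate_county_day(study$readings, study$counties$county_id),
    study$adjacency)
  expect_identical(impute_unmonitored(cd, study$adjacency), cd)
})

test_that("raising a single reading never lowers its county-day mean", {
  set.seed(3)
  r <- readings_df(runif(5, 5, 50))
  base <- aggregate_county_day(r)$pm25
  for (i in seq_len(nrow(r))) {
    r2 <- r
    r2$pm25[i] <- r2$pm25[i] + runif(1, 0, 100)
    expect_gte(aggregate_county_day(r2)$pm25, base)
  }
})

test_that("deltas pair by day index and keep their sign", {
  mk <- function(pm, period, start) {
    data.frame(county_id = "C1", date = start + seq_along(pm) - 1,
               period = period, pm25 = pm,
               n_monitors = 1L, provenance = "monitored",
               stringsAsFactors = FALSE)
  }
  epi <- mk(c(100.1, 2.0, 5.0), "episode", as.Date("2020-09-07"))
  base <- mk(c(3.1, 5.0, 5.0), "baseline", as.Date("2019-09-07"))
  d <- compute_deltas(epi, base)
  expect_equal(d$delta_c, c(97.0, -3.0, 0.0))
  expect_equal(d$smoke_day, c(TRUE, FALSE, FALSE))
  expect_equal(d$day_index, 1:3)
  # length mismatch errors
  expect_error(compute_deltas(epi[1:2, ], base), "equal numbers of days")
})

test_that("smoke-day classification is strictly above the threshold", {
  expect_true(classify_smoke_day(215.5))
  expect_false(classify_smoke_day(20.4))
  expect_false(classify_smoke_day(0))
  expect_equal(classify_smoke_day(c(20.4, 20.41)), c(FALSE, TRUE))
  expect_error(classify_smoke_day(-1))
})

test_that("exposure summary works at county-period-mean granularity", {
  d <- tiny_deltas(delta = c(100, 50), baseline = c(3, 5))
  s <- summarize_exposure(d)
  inc <- s[s$period == "increases", ]
  expect_equal(inc$mean, 75)
  expect_equal(inc$sd, sd(c(100, 50)))
  expect_equal(inc$range, 50)
  expect_equal(inc$min, 50); expect_equal(inc$max, 100)
  expect_equal(s$mean[s$period == "episode"] -
               s$mean[s$period == "baseline"], inc$mean)
  # single county, constant series
  d1 <- tiny_deltas(delta = 7, baseline = 2)
  s1 <- summarize_exposure(d1)
  epi <- s1[s1$period == "episode", ]
  expect_equal(epi$mean, 9); expect_equal(epi$median, 9)
  expect_equal(epi$sd, 0); expect_equal(epi$range, 0)
})

test_that("the pipeline applies nephelometer correction before averaging", {
  # one FRM at 100 and one nephelometer at 120.7 on the same day: per
  # reading correction gives (100 + 100)/2 = 100; correcting the county
  # mean (110.35 / 1.207) would give 91.4 instead
  r <- readings_df(c(100, 120.7), type = c("frm", "neph"))
  r$period <- "episode"
  b <- readings_df(c(3, 3), type = c("frm", "neph"),
                   date = as.Date("2019-09-07"))
  b$period <- "baseline"
  adj <- data.frame(county_id = character(0), neighbor_id = character(0))
  d <- build_exposure(rbind(r, b), adj, correct_neph = TRUE)
  expect_equal(d$episode_pm25, 100.0)
})
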