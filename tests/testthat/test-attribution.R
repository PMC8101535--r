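test_that("CRF percent converts to the log-linear coefficient", {
  expect_equal(beta_from_percent(0.50), 4.987541511038968e-4, tolerance = 1e-12)
  expect_equal(beta_from_percent(5.60), 5.448818528406977e-3, tolerance = 1e-12)
  expect_identical(beta_from_percent(0), 0)
  expect_equal(beta_from_percent(0.50, form = "linear"), 5e-4)
  expect_error(beta_from_percent(-100))
})

test_that("attributable fractions match their closed forms", {
  expect_equal(af_crf(beta_from_percent(0.50), 97.1), 0.04727504636691948,
               tolerance = 1e-12)
  expect_identical(af_crf(beta_from_percent(0.50), 0), 0)
  expect_equal(af_or(1.09), 0.08256880733944962, tolerance = 1e-12)
  expect_equal(af_or(1.02), 0.01960784313725492, tolerance = 1e-12)
  expect_identical(af_or(1.0), 0)
  expect_error(af_or(0), "positive")
  expect_warning(af_or(0.9), "negative attributable fraction")
  # small-argument regime: AF ~ beta * delta_c within 1%
  set.seed(1)
  b <- runif(20, 1e-5, 2e-4)
  dc <- runif(20, 1, 90)
  keep <- b * dc < 0.02
  expect_true(all(abs(af_crf(b, dc)[keep] / (b * dc)[keep] - 1) < 0.01))
})

test_that("daily excess deaths follow AF x daily rate x population", {
  expect_equal(excess_daily(0.02, 0.00913, 1e5), 0.05002739726027397,
               tolerance = 1e-12)
  expect_identical(excess_daily(0, 0.009, 1e5), 0)
  expect_equal(excess_daily(0.02, 0.00913, 2e5),
               2 * excess_daily(0.02, 0.00913, 1e5))
})

test_that("acute burden reproduces hand-computed county totals", {
  d <- tiny_deltas(delta = c(100, 10), baseline = c(3, 3), n_days = 2)
  demo <- tiny_demo()
  # independent arithmetic for the expected values
  expect_crf <- function(pct, delta, rate, pop, days = 2)
    days * (1 - exp(-log(1 + pct / 100) / 10 * delta)) * rate / 365 * pop
  b <- run_acute(d, demo, crf_all_cause())
  expect_equal(b$excess_deaths_central[b$county_id == "A1"],
               expect_crf(0.50, 100, 0.009, 1e5))
  expect_equal(b$excess_deaths_central[b$county_id == "A2"],
               expect_crf(0.50, 10, 0.010, 5e4))
  # statewide = sum of counties
  expect_equal(b$excess_deaths_central[b$scope == "statewide"],
               sum(b$excess_deaths_central[b$scope == "county"]))
  expect_equal(b$per_100k[b$county_id == "A1"],
               b$excess_deaths_central[b$county_id == "A1"] * 1e5 / 1e5)
  # null CRF lower bound floors the interval at exactly zero
  expect_identical(b$excess_deaths_low, rep(0, 3))

  # OR approach counts smoke days only: A1 (episode 103) smoke, A2 (13) not
  bo <- run_acute(d, demo, or_all_cause())
  expect_equal(bo$excess_deaths_central[bo$county_id == "A1"],
               2 * (0.02 / 1.02) * 0.009 / 365 * 1e5)
  expect_identical(bo$excess_deaths_central[bo$county_id == "A2"], 0)
  expect_identical(bo$excess_deaths_low, rep(0, 3))
})

test_that("negative concentration changes are floored in acute attribution", {
  d <- tiny_deltas(delta = c(-5, 0), baseline = c(10, 10))
  b <- run_acute(d, tiny_demo(), crf_all_cause())
  expect_identical(b$excess_deaths_central, rep(0, 3))
  expect_identical(b$excess_deaths_high, rep(0, 3))
})

test_that("attributable fractions are monotone in exposure and odds", {
  dc <- seq(0, 300, by = 10)
  expect_true(all(diff(af_crf(beta_from_percent(0.5), dc)) > 0))
  ors <- seq(1, 2, by = 0.05)
  expect_true(all(diff(af_or(ors)) > 0))
})

test_that("missing demographics are reported by county", {
  d <- tiny_deltas()
  expect_error(run_acute(d, tiny_demo()[1, ], crf_all_cause()), "A2")
  expect_error(run_acute(d, tiny_demo()[, -4], crf_all_cause()),
               "rate_all_cause")
})

test_that("chronic annualization matches the 13/365 arithmetic", {
  d <- tiny_deltas(delta = c(97.1, 97.1), baseline = c(3, 3), n_days = 13)
  inc <- annual_increment(d)
  expect_equal(unname(inc), rep(13 * 97.1 / 365, 2))
  expect_equal(unname(round(inc, 3)), rep(3.458, 2))

  rf <- response_function("annual_crf_percent_per_10", "all_cause",
                          5.60, 3.50, 7.80)
  b <- run_chronic(d, tiny_demo(), rf)
  af <- 0.01866751782070419  # 1 - exp(-log(1.056)/10 * 13*97.1/365)
  expect_equal(b$excess_deaths_central[b$county_id == "A1"],
               af * 0.009 * 1e5, tolerance = 1e-9)
  expect_equal(b$excess_deaths_central[b$scope == "statewide"],
               sum(b$excess_deaths_central[b$scope == "county"]))
  # no exposure change, no chronic burden
  b0 <- run_chronic(tiny_deltas(delta = c(0, 0)), tiny_demo(), rf)
  expect_identical(b0$excess_deaths_central, rep(0, 3))
})

test_that("pipeline on true county means recovers the analytic sidecar burden", {
  study <- generate_study(small_cfg(seed = 21))
  tr <- study$truth
  cd <- data.frame(county_id = tr$county_id, date = tr$date,
                   period = tr$period, pm25 = tr$true_mean,
                   n_monitors = 1L, provenance = "monitored",
                   stringsAsFactors = FALSE)
  p <- list(baseline = cd[cd$period == "baseline", ],
            episode = cd[cd$period == "episode", ])
  d <- compute_deltas(p$episode, p$baseline)
  for (rf in list(crf_all_cause(), or_all_cause(),
                  response_function("smoke_day_or", "respiratory",
                                    1.09, 1.00, 1.18))) {
    b <- run_acute(d, study$counties, rf)
    appr <- if (rf$kind == "crf_percent_per_10") "crf" else "or"
    tb <- study$truth_burden
    tb <- tb[tb$approach == appr & tb$endpoint == rf$endpoint, ]
    got <- b[b$scope == "statewide",
             c("excess_deaths_central", "excess_deaths_low",
               "excess_deaths_high")]
    want <- tb$deaths[match(c("central", "low", "high"), tb$level)]
    expect_true(all(abs(unlist(got) - want) <=
                    1e-9 * pmax(abs(want), 1)))
  }
})

test_that("smoke_hia wraps the pipeline and its methods run", {
  study <- generate_study(small_cfg(seed = 5))
  fit <- smoke_hia(study)
  expect_s3_class(fit, "smoke_hia")
  expect_equal(sort(unique(fit$acute$approach)), c("crf", "or"))
  expect_s3_class(fit$chronic, "burden_estimate")
  expect_output(print(fit), "acute all_cause")
  expect_output(print(summary(fit)), "per-capita")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
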