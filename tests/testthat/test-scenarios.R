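test_that("exposure reduction scales concentrations and reclassifies smoke days", {
  d <- tiny_deltas(delta = c(97, 10), baseline = c(3, 3))  # episode 100, 13
  expect_identical(apply_reduction(d, 0), d)
  r7 <- apply_reduction(d, 0.7)
  expect_equal(unique(r7$episode_pm25[r7$county_id == "A1"]), 30.0)
  expect_true(all(r7$smoke_day[r7$county_id == "A1"]))
  r8 <- apply_reduction(d, 0.8)
  expect_equal(unique(r8$episode_pm25[r8$county_id == "A1"]), 20.0)
  expect_false(any(r8$smoke_day))
  r1 <- apply_reduction(d, 1)
  expect_true(all(r1$episode_pm25 == 0))
  expect_true(all(r1$delta_c < 0))
  expect_false(any(r1$smoke_day))
  # baseline untouched
  expect_identical(r1$baseline_pm25, d$baseline_pm25)
  expect_error(apply_reduction(d, 1.1), "\\[0, 1\\]")
  expect_error(apply_reduction(d, -0.1), "\\[0, 1\\]")
})

test_that("total elimination avoids exactly the unmitigated burden", {
  d <- tiny_deltas(delta = c(97, 10), baseline = c(3, 3))
  demo <- tiny_demo()
  for (rf in list(crf_all_cause(), or_all_cause())) {
    full <- run_acute(d, demo, rf)
    av <- avoided_mortality(d, demo, rf, intervention_scenario(1))
    for (col in c("excess_deaths_central", "excess_deaths_low",
                  "excess_deaths_high"))
      expect_equal(av[[col]], full[[col]])
  }
  # no reduction avoids nothing
  av0 <- avoided_mortality(d, demo, crf_all_cause(),
                           intervention_scenario(0))
  expect_identical(av0$excess_deaths_central, rep(0, 3))
})

test_that("avoided mortality is monotone in the reduction fraction", {
  study <- generate_study(small_cfg(seed = 9))
  fit <- smoke_hia(study)
  fgrid <- seq(0, 1, by = 0.05)
  for (rf in list(crf_all_cause(), or_all_cause())) {
    av <- vapply(fgrid, function(f) {
      a <- avoided_mortality(fit$deltas, study$counties, rf,
                             intervention_scenario(f))
      a$excess_deaths_central[a$scope == "statewide"]
    }, numeric(1))
    expect_true(all(diff(av) >= -1e-12))
  }
})

test_that("OR-approach avoided mortality steps only at threshold crossings", {
  d <- tiny_deltas(delta = c(97, 40), baseline = c(3, 3))  # episode 100, 43
  demo <- tiny_demo()
  thr <- attr(d, "smoke_threshold")
  # crossing fractions: f* = 1 - thr/episode
  stars <- sort(1 - thr / unique(d$episode_pm25))
  av_at <- function(f) {
    a <- avoided_mortality(d, demo, or_all_cause(),
                           intervention_scenario(f))
    a$excess_deaths_central[a$scope == "statewide"]
  }
  # constant on each open interval between crossings
  cuts <- c(0, stars, 1)
  for (j in seq_len(length(cuts) - 1)) {
    f1 <- cuts[j] + 1e-6; f2 <- cuts[j + 1] - 1e-6
    expect_equal(av_at(f1), av_at(f2))
  }
  # strictly increasing across each crossing
  for (s in stars) expect_gt(av_at(s + 1e-6), av_at(s - 1e-6))
  # CRF approach is continuous: small change in f, small change in avoided
  crf_at <- function(f) {
    a <- avoided_mortality(d, demo, crf_all_cause(),
                           intervention_scenario(f))
    a$excess_deaths_central[a$scope == "statewide"]
  }
  expect_lt(abs(crf_at(0.5 + 1e-6) - crf_at(0.5 - 1e-6)), 1e-3)
})

test_that("poverty-targeted avoided mortality never exceeds the total-population value", {
  study <- generate_study(small_cfg(seed = 13))
  fit <- smoke_hia(study)
  for (f in c(0.1, 0.4, 0.8)) {
    tot <- avoided_mortality(fit$deltas, study$counties, crf_all_cause(),
                             intervention_scenario(f, "total_population"))
    pov <- avoided_mortality(fit$deltas, study$counties, crf_all_cause(),
                             intervention_scenario(f, "poverty_population"))
    expect_lte(pov$excess_deaths_central[pov$scope == "statewide"],
               tot$excess_deaths_central[tot$scope == "statewide"])
  }
})

test_that("scenario table covers every reduction and approach", {
  d <- tiny_deltas(delta = c(97, 40), baseline = c(3, 3))
  st <- scenario_table(d, tiny_demo(),
                       list(crf_all_cause(), or_all_cause()),
                       reductions = c(0.4, 1.0))
  expect_equal(nrow(st), 4)
  expect_setequal(unique(st$approach), c("crf", "or"))
  full <- run_acute(d, tiny_demo(), crf_all_cause())
  expect_equal(st$avoided_central[st$reduction == 1 & st$approach == "crf"],
               full$excess_deaths_central[full$scope == "statewide"])
})

test_that("air-cleaner program costing rounds households to the nearest integer", {
  res <- pac_program_cost(785244)
  expect_identical(res$households, 307939)
  expect_identical(res$total_cost_usd, 46190850)
  expect_equal(round(res$total_cost_usd / 1e6, 1), 46.2)
  exact <- pac_program_cost(255)
  expect_identical(exact$households, 100)
  expect_identical(exact$total_cost_usd, 15000)
  zero <- pac_program_cost(0)
  expect_identical(zero$households, 0)
  expect_identical(zero$total_cost_usd, 0)
  custom <- pac_program_cost(1000, cost_model(unit_cost = 200,
                                              household_size = 4))
  expect_identical(custom$households, 250)
  expect_identical(custom$total_cost_usd, 50000)
})
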