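test_that("the generator is deterministic under a fixed seed", {
  cfg <- cohort_config(n_women = 2000, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed gives a different cohort
  cfg2 <- cohort_config(n_women = 2000, seed = 124)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("degenerate configurations behave as required", {
  # no risk factors possible -> everyone low risk
  cfg <- cohort_config(n_women = 500, p_age_under20 = 0, p_hist_anxiety = 0,
                       p_hist_depression = 0, p_life_event = 0,
                       risk_factor_association = 0, seed = 5)
  co <- generate_cohort(cfg)
  expect_false(any(co$high_risk))

  # certain depression in both strata -> everyone depressed
  cfg <- cohort_config(n_women = 500, p_dep_given_highrisk = 1,
                       p_dep_given_lowrisk = 1, seed = 5)
  co <- generate_cohort(cfg)
  expect_true(all(co$depressed))
  expect_true(all(co$severity != "none"))
})

test_that("structural invariants hold on every generated cohort", {
  for (seed in c(1, 77)) {
    co <- generate_cohort(cohort_config(n_women = 3000, seed = seed))
    rf_any <- co$age_under20 | co$hist_anxiety | co$hist_depression | co$life_event
    expect_identical(co$high_risk, rf_any)
    expect_identical(co$severity == "none", !co$depressed)
    expect_true(all(co$phq9_score >= 0 & co$phq9_score <= 27))
    expect_true(all(co$epds_score >= 0 & co$epds_score <= 30))
    expect_true(all(co$eq5d_utility >= 0 & co$eq5d_utility <= 1))
  }
})

test_that("marginals and conditional prevalences are recovered at scale", {
  cfg <- cohort_config(n_women = 100000, seed = 2024)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$age_under20) - 0.028), 0.005)
  expect_lt(abs(mean(co$hist_anxiety) - 0.353), 0.005)
  expect_lt(abs(mean(co$hist_depression) - 0.340), 0.005)
  expect_lt(abs(mean(co$life_event) - 0.182), 0.005)
  expect_lt(abs(mean(co$high_risk) - 0.558), 0.01)
  s <- stratify(co)
  expect_lt(abs(mean(s$high_risk$depressed) - 0.171), 0.01)
  expect_lt(abs(mean(s$low_risk$depressed) - 0.017), 0.01)
  # severity split among the depressed
  expect_lt(abs(mean(s$whole$severity[s$whole$depressed] == "moderate_severe") -
                  0.30), 0.02)
})

test_that("association calibration hits the target union probability", {
  marg <- c(0.028, 0.353, 0.340, 0.182)
  # independence target -> association approximately zero
  indep <- 1 - prod(1 - marg)
  expect_lt(abs(calibrate_association(indep, marg)), 0.02)

  rho <- calibrate_association(0.558, marg)
  expect_gt(rho, 0)
  # re-simulation check
  co <- generate_cohort(cohort_config(n_women = 100000,
                                      risk_factor_association = rho, seed = 31))
  expect_lt(abs(mean(co$high_risk) - 0.558), 0.005)

  # a target below the largest marginal is unattainable
  expect_error(calibrate_association(0.30, marg), "unattainable")
  expect_error(calibrate_association(0.90, marg), "unattainable")
})

test_that("instrument scores separate depressed from non-depressed women", {
  co <- generate_cohort(cohort_config(n_women = 20000, seed = 8))
  for (col in c("phq9_score", "epds_score")) {
    expect_gt(mean(co[[col]][co$depressed]), mean(co[[col]][!co$depressed]))
  }
  expect_gt(mean(co$whooley_positive[co$depressed]),
            mean(co$whooley_positive[!co$depressed]))
})

test_that("cohort CSV round trip is lossless", {
  co <- generate_cohort(cohort_config(n_women = 1000, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2, co, tolerance = 1e-12)

  # an empty cohort writes a header-only file that reads back empty
  write_cohort(co[0, ], path)
  expect_identical(nrow(read_cohort(path)), 0L)

  # a missing column is reported by name
  df <- utils::read.csv(path)
  df$severity <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "severity")
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(p_dep_given_highrisk = 1.4), "p_dep_given_highrisk")
  expect_error(cohort_config(n_women = 0), "n_women")
  expect_error(cohort_config(risk_factor_association = 1), "risk_factor_association")
  expect_error(cohort_config(instrument_loading = 0), "instrument_loading")
})
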