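test_that("scenario application is pure and reversible", {
  base <- model_params()
  snapshot <- base
  scn <- scenario("mix", "utility$fp_decrement" = 0.10,
                  "costs$fp_fraction" = 0.30)
  out <- apply_scenario(base, scn)
  expect_identical(base, snapshot) # base untouched
  expect_equal(out$utility$fp_decrement, 0.10)
  expect_equal(out$costs$fp_fraction, 0.30)

  # empty scenario and revert-by-reapplication
  expect_identical(apply_scenario(base, NULL), base)
  expect_identical(apply_scenario(base, scenario("empty")), base)
  back <- apply_scenario(out, scenario("revert", "utility$fp_decrement" = 0,
                                       "costs$fp_fraction" = 0.20))
  expect_equal(back, base)

  expect_error(apply_scenario(base, scenario("bad", "no$such$thing" = 1)),
               "unknown parameter path")
})

test_that("scalar overrides of uncertain quantities keep their descriptors", {
  out <- apply_scenario(model_params(), scenario("fn", "p_fn_identified" = 0.25))
  expect_s3_class(out$p_fn_identified, "adc_unc")
  expect_equal(out$p_fn_identified$mean, 0.25)
  expect_identical(out$p_fn_identified$dist, "fixed")
})

test_that("administration-time scenarios follow the published totals", {
  # trebled administration and scoring: 5.13 min Whooley, 10.62 min PHQ-9/EPDS
  p3 <- apply_scenario(model_params(), baseline_scenarios()$admin_3x)
  rp <- adcase:::realise_params(p3)
  expect_equal(rp$screen_cost,
               round_half_up(5.13 * 0.92, 2) + round_half_up(10.62 * 0.92, 2))

  # instruments completed online: administration time zero, scoring retained
  p0 <- apply_scenario(model_params(), baseline_scenarios()$admin_online)
  rp0 <- adcase:::realise_params(p0)
  expect_equal(rp0$screen_cost,
               round_half_up(1 * 0.92, 2) + round_half_up(2 * 0.92, 2))
})

test_that("false-positive cost fractions rescale the partial treatment cost", {
  rp10 <- adcase:::realise_params(
    apply_scenario(model_params(), baseline_scenarios()$fp_fraction_10))
  expect_equal(rp10$fp_cost, 27.34)
  rp30 <- adcase:::realise_params(
    apply_scenario(model_params(), baseline_scenarios()$fp_fraction_30))
  expect_equal(rp30$fp_cost, 82.03)
})

test_that("scenario effects point in the expected directions", {
  res <- run_scenarios(scenarios = baseline_scenarios()[c(
    "base", "fp_fraction_30", "admin_3x", "fp_decrement_2"
  )])
  g <- function(scn, strat, col) res[[col]][res$scenario == scn &
                                              res$strategy == strat]
  # raising the FP treatment fraction costs the FP-heavy strategies most
  d_fp <- vapply(c("none", "universal", "targeted"), function(s) {
    g("fp_fraction_30", s, "cost") - g("base", s, "cost")
  }, numeric(1))
  expect_gt(d_fp[["targeted"]], d_fp[["universal"]])
  # longer administration raises screening cost only where screening happens
  d_adm <- vapply(c("none", "universal", "targeted"), function(s) {
    g("admin_3x", s, "cost") - g("base", s, "cost")
  }, numeric(1))
  expect_equal(d_adm[["none"]], 0)
  expect_gt(d_adm[["universal"]], d_adm[["targeted"]])
  # an FP utility decrement harms the FP-heavy strategies most
  d_q <- vapply(c("none", "universal", "targeted"), function(s) {
    g("fp_decrement_2", s, "qaly") - g("base", s, "qaly")
  }, numeric(1))
  expect_lt(d_q[["targeted"]], d_q[["universal"]])
})
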