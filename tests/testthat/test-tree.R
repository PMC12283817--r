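whole_utilities <- function(params = model_params()) {
  stratum_utilities(params, "whole")
}

test_that("QALY integration matches closed forms", {
  # constant utility: u * horizon / 52
  expect_equal(qaly(cbind(c(0, 20), c(0.910, 0.910))), 0.910 * 20 / 52)
  expect_equal(qaly(cbind(c(0, 20), c(0, 0))), 0)
  # 8-week linear improvement then flat
  tr <- cbind(c(0, 8, 20), c(0.643, 0.869, 0.869))
  expect_equal(qaly(tr), (8 * (0.643 + 0.869) / 2 + 12 * 0.869) / 52)

  expect_error(qaly(cbind(c(0, 10), c(1, 1))), "cover the full horizon")
  expect_error(qaly(cbind(c(0, 20), c(1.2, 0.5))), "\\[0, 1\\]")
  expect_error(qaly(cbind(c(5, 0, 20), c(1, 1, 1))), "non-decreasing")
})

test_that("pathway trajectories have the declared shapes", {
  ut <- whole_utilities()
  times <- model_params()$times

  tn <- build_trajectory("tn", ut, times = times)
  expect_equal(unname(tn[, "utility"]), c(0.910, 0.910))

  # missed initially-mild case declines to the moderate/severe utility
  miss <- build_trajectory("fn_unidentified", ut, "mild", times)
  expect_equal(unname(miss[1, ]), c(0, 0.910 * 0.88))
  expect_equal(unname(miss[2, ]), c(20, 0.910 * 0.74))
  expect_equal(round(miss[, "utility"], 3), c(0.801, 0.673),
               ignore_attr = TRUE)

  # treated responder and spontaneous recovery differ only in ramp length
  tp <- build_trajectory("tp_responder", ut, "mild", times)
  sp <- build_trajectory("fn_spontaneous", ut, "mild", times)
  expect_equal(tp[c(1, 3), "utility"], sp[c(1, 3), "utility"],
               ignore_attr = TRUE)
  expect_equal(unname(tp[2, "week"]), 8)
  expect_equal(unname(sp[2, "week"]), 7)

  # late identification: flat to week 10, recovered by week 18
  late <- build_trajectory("fn_identified_responder", ut, "modsev", times)
  expect_equal(unname(late[, "week"]), c(0, 10, 18, 20))
  expect_equal(unname(late[4, "utility"]), 0.910)

  # false positives sit at the (possibly decremented) non-depressed utility
  ut2 <- ut
  ut2$fp_decrement <- 0.02
  fp <- build_trajectory("fp", ut2, times = times)
  expect_equal(unname(fp[1, "utility"]), 0.910 * 0.98)

  expect_error(build_trajectory("nonsense", ut, times = times), "unknown pathway")
  expect_error(build_trajectory("tp_responder", ut, times = times), "severity")
})

test_that("screening-outcome probabilities follow the identification route", {
  pr <- branch_probabilities(0.103, 0.706, 0.895, "case_finding")
  expect_equal(pr[["TP"]], 0.072718)
  expect_equal(pr[["FP"]], 0.094185)
  expect_equal(sum(pr), 1)

  # standard care gates false positives on a GP visit
  pr <- branch_probabilities(0.103, 0.501, 0.813, "standard_care", p_visit = 0.722)
  expect_equal(pr[["FP"]], 0.897 * 0.722 * 0.187)
  expect_equal(sum(pr), 1)

  pr <- branch_probabilities(0, 0.7, 0.9, "case_finding")
  expect_equal(pr[["TP"]], 0)
  expect_equal(pr[["FN"]], 0)

  expect_error(branch_probabilities(0.1, 0.5, 0.8, "standard_care"), "p_visit")
  expect_error(branch_probabilities(1.2, 0.5, 0.8, "case_finding"), "prev")
})

test_that("branch probabilities of every strategy sum to one", {
  scenarios <- baseline_scenarios()
  for (scn in scenarios[c("base", "fp_decrement_10", "admin_3x")]) {
    p <- apply_scenario(model_params(), scn)
    for (s in c("none", "universal", "targeted")) {
      ev <- evaluate_strategy(p, s)
      expect_equal(sum(ev$branches$probability), 1, tolerance = 1e-9)
      expect_true(all(ev$branches$probability >= 0))
      expect_true(all(ev$branches$qalys >= 0 &
                        ev$branches$qalys <= 20 / 52 + 1e-12))
    }
  }
})

test_that("equal utilities make QALYs insensitive to the strategy", {
  p <- model_params()
  p$utility$decrement_mild <- 0
  p$utility$decrement_modsev <- 0
  m <- cf_model(p)
  expect_equal(diff(range(m$results$qaly)), 0, tolerance = 1e-12)
  expect_equal(m$results$qaly[1], 0.910 * 20 / 52)
})

test_that("expected values respond monotonically to parameters", {
  base <- cf_model(model_params())

  # better treatment recovery can only help
  p <- model_params()
  p$recovery$fsh$mean <- 0.75
  up <- cf_model(p)
  expect_true(all(up$results$qaly >= base$results$qaly - 1e-12))

  # costlier assessment can only cost more
  p <- model_params()
  p$costs$assessment <- 80
  up <- cf_model(p)
  expect_true(all(up$results$cost >= base$results$cost - 1e-12))
})

test_that("analytic evaluation agrees with a microsimulation oracle", {
  rp <- adcase:::realise_params(model_params())
  m <- cf_model(model_params())
  for (s in c("none", "universal", "targeted")) {
    sim <- microsim_strategy(rp, s, n = 50000, seed = 101)
    det <- m$results[m$results$strategy == s, ]
    expect_lt(abs(det$cost - sim$cost), 3 * sim$cost_se)
    expect_lt(abs(det$qaly - sim$qaly), 3 * sim$qaly_se)
  }
})
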