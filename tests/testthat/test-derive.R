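make_cohort <- function(n = 200, seed = 42) {
  generate_cohort(cohort_config(n_women = n, seed = seed))
}

test_that("risk stratification is exhaustive, exclusive, and factor-driven", {
  co <- make_cohort(500)
  s <- stratify(co)
  expect_identical(nrow(s$high_risk) + nrow(s$low_risk), nrow(co))
  expect_length(intersect(s$high_risk$id, s$low_risk$id), 0)
  expect_identical(nrow(s$whole), nrow(co))

  # a single life event is enough to be high risk
  one <- co[1, ]
  one$age_under20 <- one$hist_anxiety <- one$hist_depression <- FALSE
  one$life_event <- TRUE
  one$high_risk <- one$life_event
  expect_true(stratify(one)$high_risk$high_risk)

  # all factors false -> low risk; empty cohort -> three empty groups
  none <- one
  none$life_event <- FALSE
  none$high_risk <- FALSE
  expect_identical(nrow(stratify(none)$high_risk), 0L)
  empty <- stratify(co[0, ])
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("proportion estimates use Wilson intervals", {
  co <- make_cohort(391, seed = 9)
  est <- estimate_proportion(co, "high_risk")
  w <- wilson_ci(sum(co$high_risk), nrow(co))
  expect_equal(est$value, w$estimate)
  expect_equal(est$ci95, c(w$lower, w$upper))
  expect_equal(est$se, sqrt(est$value * (1 - est$value) / est$n))
  expect_error(estimate_proportion(co[0, ], "high_risk"), "0 observations")
})

test_that("strategy performance handles chaining and edge cases", {
  co <- make_cohort(2000, seed = 3)

  # perfect instrument: score equals gold standard
  perfect <- co
  perfect$phq9_score <- ifelse(perfect$depressed, 27L, 0L)
  p <- estimate_performance(perfect, list(label = "perfect",
                                          stages = list(list(instrument = "phq9",
                                                             threshold = 10))))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)

  # a never-positive second stage blanks the chain: sensitivity 0, specificity 1
  never <- list(label = "chain", stages = list(
    list(instrument = "whooley"),
    list(instrument = "phq9", threshold = 28)
  ))
  p <- estimate_performance(co, never)
  expect_equal(p$sensitivity, 0)
  expect_equal(p$specificity, 1)

  expect_error(estimate_performance(co[0, ], strategy_menu()[["Whooley"]]),
               "empty")
  expect_error(estimate_performance(co[!co$depressed, ],
                                    strategy_menu()[["Whooley"]]),
               "both depressed and non-depressed")
})

test_that("two-stage strategies obey the chaining inequalities", {
  co <- make_cohort(30000, seed = 12)
  menu <- strategy_menu()
  whooley <- estimate_performance(co, menu[["Whooley"]])
  for (chain_id in c("Whooley->EPDS>=10", "Whooley->EPDS>=13", "Whooley->PHQ-9")) {
    chain <- estimate_performance(co, menu[[chain_id]])
    second_id <- sub("Whooley->", "", chain_id)
    second_id <- if (second_id == "PHQ-9") "PHQ-9>=10" else second_id
    second <- estimate_performance(co, menu[[second_id]])
    expect_lte(chain$sensitivity, whooley$sensitivity)
    expect_lte(chain$sensitivity, second$sensitivity)
    expect_gte(chain$specificity, whooley$specificity)
  }
})

test_that("strategy filtering applies inclusive 70%/60% bounds", {
  mk <- function(id, sens, spec) {
    structure(list(strategy_id = id, stratum = "whole", sensitivity = sens,
                   specificity = spec), class = "adc_performance")
  }
  out <- filter_strategies(list(
    mk("a", 0.706, 0.895), mk("b", 0.69, 0.99), mk("c", 0.70, 0.60),
    mk("d", 0.90, 0.59)
  ))
  expect_identical(out$included, c(TRUE, FALSE, TRUE, FALSE))
  expect_match(out$exclusion_reason[2], "sensitivity")
  expect_match(out$exclusion_reason[4], "specificity")
})

test_that("depressed-state utilities derive from stratum means by decrement", {
  co <- make_cohort(5000, seed = 21)
  ut <- estimate_utilities(co)
  hr <- ut[ut$stratum == "high_risk", ]
  expect_equal(hr$mild, hr$nondep_mean * 0.88)
  expect_equal(hr$modsev, hr$nondep_mean * 0.74)
  # published arithmetic: 0.869 and 0.910 under 12% / 26% decrements
  expect_equal(round(0.869 * 0.88, 3), 0.765)
  expect_equal(round(0.910 * 0.74, 3), 0.673)
  # zero decrement leaves utility unchanged
  ut0 <- estimate_utilities(co, 0, 0)
  expect_equal(ut0$mild, ut0$nondep_mean)
})

test_that("derive_params produces a valid parameter set from a cohort", {
  co <- make_cohort(20000, seed = 14)
  p <- derive_params(co)
  expect_s3_class(p, "adc_params")
  rp <- adcase:::realise_params(p)
  expect_equal(rp$p_highrisk, mean(co$high_risk))
  expect_equal(rp$prev[["whole"]], mean(co$depressed))
  # literature-derived components untouched
  expect_equal(unname(rp$treat_cost[["fsh"]]), 273.44)
  expect_equal(rp$sens_std, 0.501)
})
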