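# Derivation of the model parameter block from individual-level cohort data:
# stratified prevalence, instrument operating characteristics, strategy
# inclusion filtering, utilities and GP-visit proportions.

#' Partition a cohort by risk stratum
#'
#' A woman is high-risk if she carries at least one of the four risk factors
#' (aged under 20, history of anxiety, history of depression, recent
#' threatening life event); the partition into high/low risk is exhaustive
#' and exclusive, and `whole` is their union.
#'
#' @param records an `adc_cohort` data.frame.
#' @return list with elements `whole`, `high_risk`, `low_risk`.
#' @export
stratify <- function(records) {
  hr <- records$high_risk
  list(
    whole = records,
    high_risk = records[hr, , drop = FALSE],
    low_risk = records[!hr, , drop = FALSE]
  )
}

#' Estimate a proportion with a Wilson 95% CI
#'
#' @param records a cohort data.frame.
#' @param predicate a function of the records returning a logical vector, or
#'   the name of a logical column.
#' @param name optional label for the estimate.
#' @return list with `name`, `value`, `se`, `ci95` (Wilson score), `n`.
#' @examples
#' co <- generate_cohort(cohort_config(n_women = 400, seed = 7))
#' estimate_proportion(co, "high_risk")
#' @export
estimate_proportion <- function(records, predicate, name = NULL) {
  x <- if (is.character(predicate)) records[[predicate]] else predicate(records)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("cannot estimate a proportion from 0 observations")
  w <- wilson_ci(sum(x), n)
  list(
    name = name %||% if (is.character(predicate)) predicate else "proportion",
    value = w$estimate, se = w$se, ci95 = c(w$lower, w$upper), n = n
  )
}

#' Case-finding strategy definitions
#'
#' The seven candidate strategies: four one-stage (EPDS at thresholds 10 and
#' 13, the Whooley questions, PHQ-9 at threshold 10) and three two-stage
#' (Whooley followed by EPDS-10, EPDS-13 or PHQ-9; the second stage is
#' applied only to first-stage positives and a final positive requires both).
#'
#' @return named list of strategy definitions (label plus ordered stages).
#' @export
strategy_menu <- function() {
  st <- function(instrument, threshold = NULL) {
    list(instrument = instrument, threshold = threshold)
  }
  list(
    "EPDS>=10" = list(label = "EPDS>=10", stages = list(st("epds", 10))),
    "EPDS>=13" = list(label = "EPDS>=13", stages = list(st("epds", 13))),
    "Whooley" = list(label = "Whooley", stages = list(st("whooley"))),
    "PHQ-9>=10" = list(label = "PHQ-9>=10", stages = list(st("phq9", 10))),
    "Whooley->EPDS>=10" = list(label = "Whooley->EPDS>=10",
                               stages = list(st("whooley"), st("epds", 10))),
    "Whooley->EPDS>=13" = list(label = "Whooley->EPDS>=13",
                               stages = list(st("whooley"), st("epds", 13))),
    "Whooley->PHQ-9" = list(label = "Whooley->PHQ-9",
                            stages = list(st("whooley"), st("phq9", 10)))
  )
}

stage_positive <- function(records, stage) {
  switch(stage$instrument,
    whooley = records$whooley_positive,
    epds = records$epds_score >= stage$threshold,
    phq9 = records$phq9_score >= stage$threshold,
    stop(sprintf("unknown instrument '%s'", stage$instrument))
  )
}

#' Operating characteristics of a case-finding strategy
#'
#' Sensitivity and specificity of a one- or two-stage strategy against
#' gold-standard depression status in a stratum, with Wilson 95% CIs. In a
#' two-stage strategy the final result is positive only if every stage is
#' positive.
#'
#' @param records an `adc_cohort` data.frame.
#' @param strategy_definition an entry of [strategy_menu()] (or a list with
#'   `label` and `stages`).
#' @param stratum label recorded on the result.
#' @return list of class `adc_performance`: `strategy_id`, `stratum`,
#'   `sensitivity`/`specificity` with `se` and `ci95`, `n_cases`,
#'   `n_noncases`.
#' @export
estimate_performance <- function(records, strategy_definition, stratum = "whole") {
  if (!nrow(records)) stop("stratum is empty")
  pos <- Reduce(`&`, lapply(strategy_definition$stages, stage_positive,
                            records = records))
  dep <- records$depressed
  n_cases <- sum(dep)
  n_noncases <- sum(!dep)
  if (n_cases == 0 || n_noncases == 0) {
    stop("stratum must contain both depressed and non-depressed records")
  }
  se_w <- wilson_ci(sum(pos & dep), n_cases)
  sp_w <- wilson_ci(sum(!pos & !dep), n_noncases)
  structure(list(
    strategy_id = strategy_definition$label,
    stratum = stratum,
    sensitivity = se_w$estimate, sens_se = se_w$se,
    sens_ci95 = c(se_w$lower, se_w$upper),
    specificity = sp_w$estimate, spec_se = sp_w$se,
    spec_ci95 = c(sp_w$lower, sp_w$upper),
    n_cases = n_cases, n_noncases = n_noncases
  ), class = "adc_performance")
}

#' Filter strategies on minimum acceptable performance
#'
#' Strategies with sensitivity below 70% are considered unacceptable at
#' identifying cases; strategies with specificity below 60% generate too
#' many false positives. Both bounds are inclusive.
#'
#' @param performances list of `adc_performance` objects.
#' @param min_sens,min_spec inclusion thresholds.
#' @return data.frame with `strategy_id`, `sensitivity`, `specificity`,
#'   `included`, `exclusion_reason`.
#' @export
filter_strategies <- function(performances, min_sens = 0.70, min_spec = 0.60) {
  if (!length(performances)) stop("no performances supplied")
  rows <- lapply(performances, function(p) {
    reason <- NA_character_
    if (p$sensitivity < min_sens) {
      reason <- sprintf("sensitivity %.3f below %.2f", p$sensitivity, min_sens)
    } else if (p$specificity < min_spec) {
      reason <- sprintf("specificity %.3f below %.2f", p$specificity, min_spec)
    }
    data.frame(strategy_id = p$strategy_id, stratum = p$stratum,
               sensitivity = p$sensitivity, specificity = p$specificity,
               included = is.na(reason), exclusion_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Utility table by stratum and depression state
#'
#' Non-depressed mean utility and its standard error per stratum, with
#' depressed-state utilities formed by applying the proportional decrements
#' to the stratum's non-depressed mean (mirroring how the model parameters
#' are constructed, rather than estimating depressed means directly).
#'
#' @param records an `adc_cohort` data.frame.
#' @param decrement_mild,decrement_modsev proportional decrements.
#' @return data.frame with one row per stratum: `nondep_mean`, `nondep_se`,
#'   `n_nondep`, `mild`, `modsev`.
#' @export
estimate_utilities <- function(records, decrement_mild = 0.12,
                               decrement_modsev = 0.26) {
  strata <- stratify(records)
  rows <- lapply(names(strata), function(nm) {
    nd <- strata[[nm]][!strata[[nm]]$depressed, , drop = FALSE]
    if (!nrow(nd)) stop(sprintf("stratum '%s' has no non-depressed records", nm))
    m <- mean(nd$eq5d_utility)
    data.frame(
      stratum = nm, nondep_mean = m,
      nondep_se = stats::sd(nd$eq5d_utility) / sqrt(nrow(nd)),
      n_nondep = nrow(nd),
      mild = m * (1 - decrement_mild),
      modsev = m * (1 - decrement_modsev),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Derive a model parameter set from a cohort
#'
#' Replaces the cohort-derived components of a base parameter set (high-risk
#' proportion, stratified prevalence, two-stage case-finding operating
#' characteristics, non-depressed utilities, GP-visit probabilities, severity
#' split) with estimates from the supplied cohort. Literature-derived
#' components (treatment effects and mix, standard-care accuracy, unit
#' costs) are retained from `base`.
#'
#' @param cohort an `adc_cohort` data.frame.
#' @param base parameter set supplying the non-cohort components.
#' @param chain two-stage strategy to derive operating characteristics for.
#' @return an `adc_params` object.
#' @export
derive_params <- function(cohort, base = model_params(),
                          chain = strategy_menu()[["Whooley->PHQ-9"]]) {
  s <- stratify(cohort)
  p_hr <- estimate_proportion(cohort, "high_risk")
  prev_w <- estimate_proportion(cohort, "depressed")
  prev_h <- estimate_proportion(s$high_risk, "depressed")
  prev_l <- estimate_proportion(s$low_risk, "depressed")
  perf_w <- estimate_performance(cohort, chain, "whole")
  perf_h <- estimate_performance(s$high_risk, chain, "high_risk")
  ut <- estimate_utilities(cohort, base$utility$decrement_mild,
                           base$utility$decrement_modsev)
  visit_h <- estimate_proportion(s$high_risk, "gp_visit")
  visit_l <- estimate_proportion(s$low_risk, "gp_visit")
  visit_w <- estimate_proportion(cohort, "gp_visit")
  dep <- cohort[cohort$depressed, , drop = FALSE]
  p_ms <- estimate_proportion(dep, function(d) d$severity == "moderate_severe")

  p <- base
  p$p_highrisk <- unc(p_hr$value, se = p_hr$se)
  p$prevalence <- list(
    whole = unc(prev_w$value, se = prev_w$se),
    high = unc(prev_h$value, se = prev_h$se),
    low = unc(prev_l$value, se = prev_l$se)
  )
  p$p_modsev <- unc(p_ms$value, se = p_ms$se)
  p$case_finding <- list(
    whole = list(sens = unc(perf_w$sensitivity, se = perf_w$sens_se),
                 spec = unc(perf_w$specificity, se = perf_w$spec_se)),
    high = list(sens = unc(perf_h$sensitivity, se = perf_h$sens_se),
                spec = unc(perf_h$specificity, se = perf_h$spec_se))
  )
  u <- function(st) ut[ut$stratum == st, ]
  p$utility$nondep <- list(
    whole = unc(u("whole")$nondep_mean, se = u("whole")$nondep_se),
    high = unc(u("high_risk")$nondep_mean, se = u("high_risk")$nondep_se),
    low = unc(u("low_risk")$nondep_mean, se = u("low_risk")$nondep_se)
  )
  p$p_gp_visit <- list(
    whole = unc(visit_w$value, se = visit_w$se),
    high = unc(visit_h$value, se = visit_h$se),
    low = unc(visit_l$value, se = visit_l$se)
  )
  validate_params(p)
  p
}
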