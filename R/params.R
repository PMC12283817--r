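#' Model parameter set for the antenatal case-finding decision model
#'
#' Constructs the complete parameter block of the decision model: stratified
#' prevalence and risk-group size, depression severity split, treatment mix and
#' treatment-effect probabilities (derived from baselines and relative risks),
#' GP-visit probabilities, operating characteristics of standard care and of
#' the included two-stage case-finding strategy (Whooley questions followed by
#' PHQ-9), unit costs, utilities, and the time structure of the 20-week
#' antenatal horizon. Probabilities and utilities carry uncertainty
#' descriptors (standard errors or 95% CIs) used by the probabilistic
#' sensitivity analysis; unit costs are fixed.
#'
#' Any component can be overridden by name; overrides are validated. Scalar
#' overrides of uncertain quantities replace the mean and keep the
#' uncertainty descriptor.
#'
#' @param ... named overrides of top-level components (advanced use; the
#'   scenario engine in [apply_scenario()] is the supported way to vary
#'   parameters).
#' @return an object of class `adc_params`.
#' @examples
#' p <- model_params()
#' p$costs$treatments$fsh
#' @export
model_params <- function(...) {
  p <- list(
    p_highrisk = unc(0.558, ci = c(0.507, 0.607)),
    prevalence = list(
      whole = unc(0.103, ci = c(0.074, 0.137)),
      high  = unc(0.171, ci = c(0.122, 0.227)),
      low   = unc(0.017, ci = c(0.004, 0.050))
    ),
    p_modsev = unc(0.30, se = 0.030),
    # moderate/severe treatment mix (shares renormalised after PSA draws)
    treatment_mix = list(
      ipt    = unc(0.128, ci = c(0.092, 0.171)),
      pharma = unc(0.523, ci = c(0.465, 0.581)),
      both   = unc(0.349, ci = c(0.295, 0.406))
    ),
    p_no_spontaneous_recovery = unc(0.65, se = 0.065),
    # probability of recovery by treatment, derived unrounded from
    # baseline x RR; CIs are the published CIs on the derived probability
    recovery = list(
      fsh    = unc(1 - derive_recovery(0.38, 1.59, "recovery"), ci = c(0.51, 0.72)),
      ipt    = unc(1 - derive_recovery(0.64, 0.69, "no_recovery"), ci = c(0.45, 0.64)),
      pharma = unc(1 - derive_recovery(0.43, 1.27, "recovery"), ci = c(0.41, 0.71)),
      both   = unc(1 - derive_recovery(0.43, 1.47, "recovery"), ci = c(0.51, 0.75))
    ),
    p_gp_visit = list(
      whole = unc(0.722, ci = c(0.675, 0.765)),
      high  = unc(0.780, ci = c(0.721, 0.830)),
      low   = unc(0.642, ci = c(0.565, 0.712))
    ),
    # chance a false negative who does not spontaneously recover is picked up
    # by their GP halfway through the horizon (expert opinion; fixed in PSA)
    p_fn_identified = unc(0.10, dist = "fixed"),
    standard_care = list(
      sens = unc(0.501, ci = c(0.413, 0.590)),
      spec = unc(0.813, ci = c(0.745, 0.873))
    ),
    # two-stage Whooley -> PHQ-9 operating characteristics; SEs are binomial
    # at the source-cohort group sizes (whole: 40 cases / 351 non-cases;
    # high-risk: 37 / 181)
    case_finding = list(
      whole = list(
        sens = unc(0.706, se = sqrt(0.706 * 0.294 / 40)),
        spec = unc(0.895, se = sqrt(0.895 * 0.105 / 351))
      ),
      high = list(
        sens = unc(0.742, se = sqrt(0.742 * 0.258 / 37)),
        spec = unc(0.850, se = sqrt(0.850 * 0.150 / 181))
      )
    ),
    utility = list(
      nondep = list(
        whole = unc(0.910, se = 0.01),
        high  = unc(0.869, se = 0.01),
        low   = unc(0.910, se = 0.01)
      ),
      decrement_mild = 0.12,
      decrement_modsev = 0.26,
      fp_decrement = 0
    ),
    costs = list(
      instruments = list(
        whooley = list(admin = 0.71, scoring = 1, rate = 0.92),
        epds    = list(admin = 1.54, scoring = 2, rate = 0.92),
        phq9    = list(admin = 1.54, scoring = 2, rate = 0.92)
      ),
      admin_multiplier = 1,
      scoring_multiplier = 1,
      assessment = 55,
      gp_consultation = 39.23,
      gp_minutes = 9.22,
      gp_base_minutes = 9.22,
      treatments = list(
        fsh    = list(staff_minutes = 175, rate = 0.85, materials = 7,
                      gp_consultations = 3, drug = 0),
        ipt    = list(staff_minutes = 440, rate = 1.80, materials = 0,
                      gp_consultations = 3, drug = 0),
        pharma = list(staff_minutes = 0, rate = 0, materials = 0,
                      gp_consultations = 7, drug = 25.65),
        both   = list(staff_minutes = 440, rate = 1.80, materials = 0,
                      gp_consultations = 3, drug = 25.65)
      ),
      fp_fraction = 0.20
    ),
    chain = c("whooley", "phq9"),
    times = list(
      horizon_weeks = 20,
      treatment_weeks = 8,
      spontaneous_recovery_weeks = 7,
      fn_identification_week = 10,
      weeks_per_year = 52
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop(sprintf("unknown parameter component '%s'", nm))
    p[[nm]] <- dots[[nm]]
  }
  class(p) <- "adc_params"
  validate_params(p)
  p
}

#' Validate a model parameter set
#'
#' Checks structural invariants: all proportions in `[0, 1]`, the
#' moderate/severe treatment mix summing to one, non-negative costs, and a
#' horizon at least as long as the treatment course.
#'
#' @param params an `adc_params` object.
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_params <- function(params) {
  prop_fields <- list(
    p_highrisk = params$p_highrisk,
    "prevalence$whole" = params$prevalence$whole,
    "prevalence$high" = params$prevalence$high,
    "prevalence$low" = params$prevalence$low,
    p_modsev = params$p_modsev,
    p_no_spontaneous_recovery = params$p_no_spontaneous_recovery,
    p_fn_identified = params$p_fn_identified,
    "standard_care$sens" = params$standard_care$sens,
    "standard_care$spec" = params$standard_care$spec,
    "recovery$fsh" = params$recovery$fsh,
    "recovery$ipt" = params$recovery$ipt,
    "recovery$pharma" = params$recovery$pharma,
    "recovery$both" = params$recovery$both,
    "p_gp_visit$whole" = params$p_gp_visit$whole,
    "p_gp_visit$high" = params$p_gp_visit$high,
    "p_gp_visit$low" = params$p_gp_visit$low,
    "case_finding$whole$sens" = params$case_finding$whole$sens,
    "case_finding$whole$spec" = params$case_finding$whole$spec,
    "case_finding$high$sens" = params$case_finding$high$sens,
    "case_finding$high$spec" = params$case_finding$high$spec,
    "utility$nondep$whole" = params$utility$nondep$whole,
    "utility$nondep$high" = params$utility$nondep$high,
    "utility$nondep$low" = params$utility$nondep$low,
    "utility$decrement_mild" = params$utility$decrement_mild,
    "utility$decrement_modsev" = params$utility$decrement_modsev,
    "utility$fp_decrement" = params$utility$fp_decrement,
    "costs$fp_fraction" = params$costs$fp_fraction
  )
  for (nm in names(prop_fields)) {
    stopifnot_proportion(unc_mean(prop_fields[[nm]]), nm)
  }
  mix <- sum(vapply(params$treatment_mix, unc_mean, numeric(1)))
  if (abs(mix - 1) > 1e-9) {
    stop(sprintf("treatment_mix shares must sum to 1 (got %.10f)", mix))
  }
  costs <- c(
    unlist(lapply(params$costs$instruments, unlist)),
    params$costs$assessment, params$costs$gp_consultation,
    unlist(lapply(params$costs$treatments, unlist))
  )
  if (any(costs < 0)) stop("all unit costs and cost components must be non-negative")
  if (params$times$horizon_weeks < params$times$treatment_weeks) {
    stop("horizon_weeks must be at least treatment_weeks")
  }
  invisible(params)
}

# ---- realisation: collapse uncertain quantities to a scalar parameter list ----

# Collapse an adc_params object to plain numbers, substituting `draw` values
# (named list from the PSA) where provided, and compute all derived
# quantities the tree evaluation needs.
realise_params <- function(params, draw = list()) {
  gv <- function(x, nm) if (!is.null(draw[[nm]])) draw[[nm]] else unc_mean(x)
  p_hr <- gv(params$p_highrisk, "p_highrisk")
  prev_h <- gv(params$prevalence$high, "prev_high")
  prev_l <- gv(params$prevalence$low, "prev_low")
  # the whole-sample prevalence is the stratum mixture plus the (tiny)
  # rounding offset between the published whole-sample figure and the
  # mixture of the published stratum figures; this keeps PSA draws coherent
  # (no negative derived low-risk prevalence) while reproducing the
  # published whole-sample value at the base case
  offset <- unc_mean(params$prevalence$whole) -
    (unc_mean(params$p_highrisk) * unc_mean(params$prevalence$high) +
       (1 - unc_mean(params$p_highrisk)) * unc_mean(params$prevalence$low))
  prev_w <- min(1, max(0, p_hr * prev_h + (1 - p_hr) * prev_l + offset))
  mix <- c(
    ipt = gv(params$treatment_mix$ipt, "mix_ipt"),
    pharma = gv(params$treatment_mix$pharma, "mix_pharma"),
    both = gv(params$treatment_mix$both, "mix_both")
  )
  mix <- mix / sum(mix)
  cst <- params$costs
  screen_cost <- sum(vapply(params$chain, function(ins) {
    i <- cst$instruments[[ins]]
    instrument_cost(i$admin * cst$admin_multiplier,
                    i$scoring * cst$scoring_multiplier, i$rate)
  }, numeric(1)))
  tc <- function(t) treatment_cost(t$staff_minutes, t$rate, t$materials,
                                   t$gp_consultations, t$drug)
  treat_costs <- vapply(cst$treatments, tc, numeric(1))
  u_nd <- c(
    whole = gv(params$utility$nondep$whole, "u_whole"),
    high = gv(params$utility$nondep$high, "u_high"),
    low = gv(params$utility$nondep$low, "u_low")
  )
  list(
    p_highrisk = p_hr,
    prev = c(whole = prev_w, high = prev_h, low = prev_l),
    # low-risk arm of the targeted strategy: share of depression left after
    # removing the high-risk stratum, preserving the whole-sample prevalence
    prev_low_targeted = (prev_w - p_hr * prev_h) / (1 - p_hr),
    p_modsev = gv(params$p_modsev, "p_modsev"),
    mix = mix,
    p_no_spont = gv(params$p_no_spontaneous_recovery, "p_no_spont"),
    recovery = c(
      fsh = gv(params$recovery$fsh, "rec_fsh"),
      ipt = gv(params$recovery$ipt, "rec_ipt"),
      pharma = gv(params$recovery$pharma, "rec_pharma"),
      both = gv(params$recovery$both, "rec_both")
    ),
    p_visit = c(
      whole = gv(params$p_gp_visit$whole, "visit_whole"),
      high = gv(params$p_gp_visit$high, "visit_high"),
      low = gv(params$p_gp_visit$low, "visit_low")
    ),
    p_fn_identified = gv(params$p_fn_identified, "p_fn_identified"),
    sens_std = gv(params$standard_care$sens, "sens_std"),
    spec_std = gv(params$standard_care$spec, "spec_std"),
    sens_cf = c(
      whole = gv(params$case_finding$whole$sens, "sens_cf_whole"),
      high = gv(params$case_finding$high$sens, "sens_cf_high")
    ),
    spec_cf = c(
      whole = gv(params$case_finding$whole$spec, "spec_cf_whole"),
      high = gv(params$case_finding$high$spec, "spec_cf_high")
    ),
    u_nondep = u_nd,
    dec_mild = params$utility$decrement_mild,
    dec_modsev = params$utility$decrement_modsev,
    fp_decrement = params$utility$fp_decrement,
    screen_cost = screen_cost,
    assess_cost = cst$assessment,
    gp_cost = round_half_up(cst$gp_consultation * cst$gp_minutes / cst$gp_base_minutes, 2),
    fp_cost = false_positive_cost(treat_costs[["fsh"]], cst$fp_fraction),
    treat_cost = treat_costs,
    times = params$times
  )
}

# names of the uncertain quantities the PSA draws, with their descriptors
uncertain_params <- function(params) {
  list(
    p_highrisk = params$p_highrisk,
    prev_high = params$prevalence$high,
    prev_low = params$prevalence$low,
    p_modsev = params$p_modsev,
    mix_ipt = params$treatment_mix$ipt,
    mix_pharma = params$treatment_mix$pharma,
    mix_both = params$treatment_mix$both,
    p_no_spont = params$p_no_spontaneous_recovery,
    rec_fsh = params$recovery$fsh,
    rec_ipt = params$recovery$ipt,
    rec_pharma = params$recovery$pharma,
    rec_both = params$recovery$both,
    visit_whole = params$p_gp_visit$whole,
    visit_high = params$p_gp_visit$high,
    visit_low = params$p_gp_visit$low,
    p_fn_identified = params$p_fn_identified,
    sens_std = params$standard_care$sens,
    spec_std = params$standard_care$spec,
    sens_cf_whole = params$case_finding$whole$sens,
    spec_cf_whole = params$case_finding$whole$spec,
    sens_cf_high = params$case_finding$high$sens,
    spec_cf_high = params$case_finding$high$spec,
    u_whole = params$utility$nondep$whole,
    u_high = params$utility$nondep$high,
    u_low = params$utility$nondep$low
  )
}

# ---- serialisation ----

serialise_node <- function(x) {
  if (inherits(x, "adc_unc")) {
    out <- list(`_unc` = TRUE, mean = x$mean, se = x$se, dist = x$dist)
    if (!is.null(x$ci)) out$ci <- x$ci
    out
  } else if (is.list(x)) {
    lapply(x, serialise_node)
  } else {
    x
  }
}

deserialise_node <- function(x) {
  if (is.list(x) && isTRUE(x$`_unc`)) {
    unc(x$mean, se = x$se, ci = if (!is.null(x$ci)) unlist(x$ci), dist = x$dist)
  } else if (is.list(x)) {
    lapply(x, deserialise_node)
  } else if (is.character(x) || length(x) > 1) {
    unlist(x)
  } else {
    x
  }
}

#' Write / read a model parameter set
#'
#' Parameters are stored as JSON with a schema version; the round trip is
#' lossless (uncertainty descriptors included).
#'
#' @param params an `adc_params` object.
#' @param path file path.
#' @return `read_params()` returns an `adc_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  obj <- list(schema = "adcase-params/1", params = serialise_node(unclass(params)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, "adcase-params/1")) {
    stop(sprintf("unrecognised parameter file schema: %s", obj$schema))
  }
  p <- deserialise_node(obj$params)
  p$chain <- unlist(p$chain)
  class(p) <- "adc_params"
  validate_params(p)
  p
}

#' @export
print.adc_params <- function(x, ...) {
  rp <- realise_params(x)
  cat("Antenatal depression case-finding model parameters\n")
  cat(sprintf("  high-risk proportion: %.3f; prevalence (whole/high/low): %.3f / %.3f / %.3f\n",
              rp$p_highrisk, rp$prev["whole"], rp$prev["high"], rp$prev["low"]))
  cat(sprintf("  case finding (Whooley->PHQ-9) sens/spec: whole %.3f/%.3f, high-risk %.3f/%.3f\n",
              rp$sens_cf["whole"], rp$spec_cf["whole"], rp$sens_cf["high"], rp$spec_cf["high"]))
  cat(sprintf("  standard care sens/spec: %.3f/%.3f; GP visit (whole/high/low): %.3f/%.3f/%.3f\n",
              rp$sens_std, rp$spec_std, rp$p_visit["whole"], rp$p_visit["high"], rp$p_visit["low"]))
  cat(sprintf("  screening cost per woman: £%.2f; treatments (FSH/IPT/pharma/both): £%.2f/%.2f/%.2f/%.2f\n",
              rp$screen_cost, rp$treat_cost["fsh"], rp$treat_cost["ipt"],
              rp$treat_cost["pharma"], rp$treat_cost["both"]))
  cat(sprintf("  horizon: %d weeks; utilities (non-depressed, whole): %.3f\n",
              x$times$horizon_weeks, rp$u_nondep["whole"]))
  invisible(x)
}
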