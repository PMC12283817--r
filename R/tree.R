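#' QALYs from a piecewise-linear utility trajectory
#'
#' Integrates a utility trajectory over the model horizon by the trapezoidal
#' rule (exact for piecewise-linear trajectories) and converts utility-weeks
#' to quality-adjusted life years. No discounting is applied (the horizon is
#' under one year).
#'
#' @param trajectory a two-column matrix or data.frame of `(week, utility)`
#'   knots with non-decreasing weeks covering `[0, horizon]`.
#' @param horizon_weeks length of the model horizon in weeks.
#' @param weeks_per_year weeks per year, default 52.
#' @return QALYs (years).
#' @examples
#' qaly(cbind(c(0, 20), c(0.910, 0.910))) # 0.910 * 20/52 = 0.35
#' @export
qaly <- function(trajectory, horizon_weeks = 20, weeks_per_year = 52) {
  tr <- as.matrix(trajectory)
  if (ncol(tr) != 2) stop("trajectory must have two columns: week, utility")
  w <- tr[, 1]; u <- tr[, 2]
  if (is.unsorted(w)) stop("trajectory weeks must be non-decreasing")
  if (w[1] > 0 || w[length(w)] < horizon_weeks) {
    stop(sprintf("trajectory must cover the full horizon [0, %g]", horizon_weeks))
  }
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]")
  area <- sum(diff(w) * (head2(u) + u[-1]) / 2)
  area / weeks_per_year
}

head2 <- function(x) x[-length(x)]

#' Utility trajectory for a pathway through the decision tree
#'
#' Builds the piecewise-linear utility trajectory over the 20-week horizon for
#' a given pathway. Shapes:
#' * `tn` — flat at the non-depressed utility;
#' * `fp` — flat at the non-depressed utility reduced by the false-positive
#'   decrement (zero in the base case);
#' * `tp_responder` — linear improvement from the severity-specific depressed
#'   utility to the non-depressed utility over the 8-week treatment course,
#'   flat thereafter;
#' * `tp_nonresponder` — flat at the depressed utility;
#' * `fn_spontaneous` — linear improvement over the 7 weeks after screening,
#'   flat thereafter;
#' * `fn_identified_responder` — flat depressed until GP identification at
#'   week 10, then the treatment ramp (completing at week 18), flat to the end;
#' * `fn_identified_nonresponder` — flat at the depressed utility;
#' * `fn_unidentified` — for initially mild depression, linear decline from
#'   the mild to the moderate/severe utility across the whole horizon; for
#'   moderate/severe depression, flat.
#'
#' @param path pathway label (see Details).
#' @param utilities list with `nondep`, `mild`, `modsev` utilities and
#'   optionally `fp_decrement`; see [stratum_utilities()].
#' @param severity `"mild"` or `"modsev"` (required for depressed pathways).
#' @param times list of model times as in `model_params()$times`.
#' @return a two-column matrix of `(week, utility)` knots.
#' @export
build_trajectory <- function(path, utilities, severity = NULL,
                             times = model_params()$times) {
  H <- times$horizon_weeks
  Tt <- times$treatment_weeks
  Sp <- times$spontaneous_recovery_weeks
  Id <- times$fn_identification_week
  u_n <- utilities$nondep
  u_dep <- function() {
    if (is.null(severity)) stop("severity required for depressed pathways")
    switch(severity, mild = utilities$mild, modsev = utilities$modsev,
           stop(sprintf("unknown severity '%s'", severity)))
  }
  kn <- switch(path,
    tn = cbind(c(0, H), c(u_n, u_n)),
    fp = {
      u <- u_n * (1 - (utilities$fp_decrement %||% 0))
      cbind(c(0, H), c(u, u))
    },
    tp_responder = cbind(c(0, Tt, H), c(u_dep(), u_n, u_n)),
    tp_nonresponder = cbind(c(0, H), rep(u_dep(), 2)),
    fn_spontaneous = cbind(c(0, Sp, H), c(u_dep(), u_n, u_n)),
    fn_identified_responder =
      cbind(c(0, Id, Id + Tt, H), c(u_dep(), u_dep(), u_n, u_n)),
    fn_identified_nonresponder = cbind(c(0, H), rep(u_dep(), 2)),
    fn_unidentified = {
      if (is.null(severity)) stop("severity required for depressed pathways")
      if (severity == "mild") {
        cbind(c(0, H), c(utilities$mild, utilities$modsev))
      } else {
        cbind(c(0, H), rep(utilities$modsev, 2))
      }
    },
    stop(sprintf("unknown pathway label '%s'", path))
  )
  colnames(kn) <- c("week", "utility")
  kn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Utility set for a stratum
#'
#' Non-depressed mean utility for the stratum with depressed-state utilities
#' formed by proportional decrements (12% mild, 26% moderate/severe in the
#' base case).
#'
#' @param params an `adc_params` object (or realised parameter list).
#' @param stratum `"whole"`, `"high"` or `"low"`.
#' @return list with `nondep`, `mild`, `modsev`, `fp_decrement`.
#' @export
stratum_utilities <- function(params, stratum = "whole") {
  rp <- if (inherits(params, "adc_params")) realise_params(params) else params
  u_n <- rp$u_nondep[[stratum]]
  list(
    nondep = u_n,
    mild = u_n * (1 - rp$dec_mild),
    modsev = u_n * (1 - rp$dec_modsev),
    fp_decrement = rp$fp_decrement
  )
}

#' Screening-outcome probabilities for one arm of the tree
#'
#' Under case finding every woman is screened: `P(TP) = prev * sens`,
#' `P(FN) = prev * (1 - sens)`, `P(FP) = (1 - prev) * (1 - spec)` and
#' `P(TN)` the remainder. Under standard care (no case finding, and the
#' low-risk arm of the targeted strategy) identification of non-depressed
#' women as false positives requires a GP visit:
#' `P(FP) = (1 - prev) * p_visit * (1 - spec)`, while identification of
#' depressed women uses the standard-care sensitivity directly.
#'
#' @param prev depression prevalence in the arm.
#' @param sens,spec operating characteristics of the identification route.
#' @param mode `"case_finding"` or `"standard_care"`.
#' @param p_visit probability of visiting a GP (standard care only).
#' @return named vector with `TP`, `FN`, `TN`, `FP`, summing to one.
#' @export
branch_probabilities <- function(prev, sens, spec,
                                 mode = c("case_finding", "standard_care"),
                                 p_visit = NULL) {
  mode <- match.arg(mode)
  for (v in c("prev", "sens", "spec")) stopifnot_proportion(get(v), v)
  tp <- prev * sens
  fn <- prev * (1 - sens)
  fp <- if (mode == "case_finding") {
    (1 - prev) * (1 - spec)
  } else {
    if (is.null(p_visit)) stop("p_visit required for standard care")
    (1 - prev) * p_visit * (1 - spec)
  }
  tn <- 1 - tp - fn - fp
  if (tn < -1e-12) stop("branch probabilities outside [0, 1]")
  c(TP = tp, FN = fn, TN = tn, FP = fp)
}

# ---- branch enumeration for one arm -----------------------------------------
#
# Enumerates every terminal branch of the case-finding-and-treatment tree for
# one arm (a stratum under one identification route) and returns parallel
# vectors of probability, cost and QALYs. Cost composition:
#   case finding: both chained instruments for every screened woman; every
#     screen positive (TP and FP) gets a one-hour midwife assessment plus a
#     GP consultation to initiate treatment; TP pay the severity-specific
#     treatment package; FP pay the partial (20% FSH) cost; FN who fail to
#     recover spontaneously and are later identified by the GP (week 10)
#     incur one GP consultation plus the full treatment package.
#   standard care: every woman who visits a GP incurs one consultation;
#     identified positives (true and false) incur an identification
#     consultation, plus treatment (TP) or the partial cost (FP); later
#     identification of FN as above.
arm_branches <- function(rp, mode, prev, sens, spec, p_visit, utilities,
                         label_prefix = "") {
  times <- rp$times
  pr <- branch_probabilities(prev, sens, spec, mode, p_visit)
  screen <- if (mode == "case_finding") rp$screen_cost else 0
  base_cost <- screen + if (mode == "standard_care") p_visit * rp$gp_cost else 0
  pos_cost <- if (mode == "case_finding") rp$assess_cost + rp$gp_cost else rp$gp_cost

  # severity-conditional treatment menus: mild -> FSH only; moderate/severe ->
  # observed mix of IPT, pharmacotherapy and combined treatment
  menus <- list(
    mild = list(shares = c(fsh = 1),
                costs = rp$treat_cost["fsh"],
                rec = rp$recovery["fsh"]),
    modsev = list(shares = rp$mix,
                  costs = rp$treat_cost[c("ipt", "pharma", "both")],
                  rec = rp$recovery[c("ipt", "pharma", "both")])
  )
  p_sev <- c(mild = 1 - rp$p_modsev, modsev = rp$p_modsev)

  lab <- character(0); prob <- numeric(0); cost <- numeric(0); q <- numeric(0)
  add <- function(l, p, cst, traj) {
    lab <<- c(lab, paste0(label_prefix, l))
    prob <<- c(prob, p)
    cost <<- c(cost, cst)
    q <<- c(q, qaly(traj, times$horizon_weeks, times$weeks_per_year))
  }
  tr <- function(path, sev = NULL) build_trajectory(path, utilities, sev, times)

  add("TN", pr[["TN"]], base_cost, tr("tn"))
  add("FP", pr[["FP"]], base_cost + pos_cost + rp$fp_cost, tr("fp"))

  for (sev in c("mild", "modsev")) {
    m <- menus[[sev]]
    for (t in names(m$shares)) {
      p_t <- pr[["TP"]] * p_sev[[sev]] * m$shares[[t]]
      c_t <- base_cost + pos_cost + m$costs[[t]]
      add(paste("TP", sev, t, "responder", sep = "."),
          p_t * m$rec[[t]], c_t, tr("tp_responder", sev))
      add(paste("TP", sev, t, "nonresponder", sep = "."),
          p_t * (1 - m$rec[[t]]), c_t, tr("tp_nonresponder", sev))
    }
    p_fn_sev <- pr[["FN"]] * p_sev[[sev]]
    add(paste("FN", sev, "spontaneous", sep = "."),
        p_fn_sev * (1 - rp$p_no_spont), base_cost, tr("fn_spontaneous", sev))
    p_persist <- p_fn_sev * rp$p_no_spont
    for (t in names(m$shares)) {
      p_t <- p_persist * rp$p_fn_identified * m$shares[[t]]
      c_t <- base_cost + rp$gp_cost + m$costs[[t]]
      add(paste("FN", sev, "identified", t, "responder", sep = "."),
          p_t * m$rec[[t]], c_t, tr("fn_identified_responder", sev))
      add(paste("FN", sev, "identified", t, "nonresponder", sep = "."),
          p_t * (1 - m$rec[[t]]), c_t, tr("fn_identified_nonresponder", sev))
    }
    add(paste("FN", sev, "unidentified", sep = "."),
        p_persist * (1 - rp$p_fn_identified), base_cost, tr("fn_unidentified", sev))
  }
  list(label = lab, prob = prob, cost = cost, qaly = q)
}

# ---- strategy evaluation ----------------------------------------------------

# Arms making up a strategy: list of (weight, mode, prev, sens, spec, p_visit).
# In the three-way population comparison all strategies are evaluated on the
# whole-sample utility set so that QALYs are comparable across strategies.
strategy_arms <- function(rp, strategy) {
  switch(strategy,
    none = list(list(
      weight = 1, mode = "standard_care", prev = rp$prev[["whole"]],
      sens = rp$sens_std, spec = rp$spec_std,
      p_visit = rp$p_visit[["whole"]], prefix = ""
    )),
    universal = list(list(
      weight = 1, mode = "case_finding", prev = rp$prev[["whole"]],
      sens = rp$sens_cf[["whole"]], spec = rp$spec_cf[["whole"]],
      p_visit = NULL, prefix = ""
    )),
    targeted = list(
      list(
        weight = rp$p_highrisk, mode = "case_finding",
        prev = rp$prev[["high"]],
        sens = rp$sens_cf[["high"]], spec = rp$spec_cf[["high"]],
        p_visit = NULL, prefix = "high."
      ),
      list(
        weight = 1 - rp$p_highrisk, mode = "standard_care",
        prev = rp$prev_low_targeted,
        sens = rp$sens_std, spec = rp$spec_std,
        p_visit = rp$p_visit[["low"]], prefix = "low."
      )
    ),
    stop(sprintf("unknown strategy '%s'", strategy))
  )
}

#' Evaluate one strategy deterministically
#'
#' Expected cost (GBP) and QALYs per person for a strategy, with the full
#' branch table for audit. The targeted strategy is the population-weighted
#' combination of case finding in the high-risk stratum and standard care in
#' the low-risk stratum.
#'
#' @param params an `adc_params` object.
#' @param strategy `"none"`, `"universal"` or `"targeted"`.
#' @param utilities utility set to evaluate on; defaults to the whole-sample
#'   set so that the three strategies are comparable.
#' @return list with `strategy`, `cost`, `qaly` and a `branches` data.frame
#'   (label, probability, cost, QALYs per branch; probabilities sum to 1).
#' @export
evaluate_strategy <- function(params, strategy = c("none", "universal", "targeted"),
                              utilities = NULL) {
  strategy <- match.arg(strategy)
  rp <- if (inherits(params, "adc_params")) realise_params(params) else params
  if (is.null(utilities)) utilities <- stratum_utilities(rp, "whole")
  arms <- strategy_arms(rp, strategy)
  lab <- character(0); prob <- numeric(0); cost <- numeric(0); q <- numeric(0)
  for (a in arms) {
    br <- arm_branches(rp, a$mode, a$prev, a$sens, a$spec, a$p_visit,
                       utilities, a$prefix)
    lab <- c(lab, br$label)
    prob <- c(prob, a$weight * br$prob)
    cost <- c(cost, br$cost)
    q <- c(q, br$qaly)
  }
  list(
    strategy = strategy,
    cost = sum(prob * cost),
    qaly = sum(prob * q),
    branches = data.frame(label = lab, probability = prob,
                          cost = cost, qalys = q)
  )
}

# fast path used by the PSA: expected cost and QALYs only
strategy_values <- function(rp, strategy, utilities) {
  out <- c(cost = 0, qaly = 0)
  for (a in strategy_arms(rp, strategy)) {
    br <- arm_branches(rp, a$mode, a$prev, a$sens, a$spec, a$p_visit, utilities)
    out <- out + a$weight * c(sum(br$prob * br$cost), sum(br$prob * br$qaly))
  }
  out
}
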