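#' Fit the antenatal case-finding decision model
#'
#' Evaluates the three-stage decision tree (risk stratification, case
#' finding, treatment) deterministically for a set of strategies, returning a
#' model object with expected cost and QALYs per person for each strategy and
#' the full branch audit tables.
#'
#' Methods: [print.cf_model()], [summary.cf_model()] (incremental
#' cost-effectiveness analysis), [coef.cf_model()], [predict.cf_model()]
#' (population projection), [simulate.cf_model()] (probabilistic sensitivity
#' analysis).
#'
#' @param params an `adc_params` object, default [model_params()].
#' @param strategies character vector among `"none"`, `"universal"`,
#'   `"targeted"`.
#' @return an object of class `cf_model`.
#' @examples
#' m <- cf_model()
#' m
#' summary(m)
#' @export
cf_model <- function(params = model_params(),
                     strategies = c("none", "universal", "targeted")) {
  validate_params(params)
  strategies <- match.arg(strategies, several.ok = TRUE)
  ev <- lapply(strategies, function(s) evaluate_strategy(params, s))
  names(ev) <- strategies
  res <- data.frame(
    strategy = strategies,
    cost = vapply(ev, `[[`, numeric(1), "cost"),
    qaly = vapply(ev, `[[`, numeric(1), "qaly"),
    row.names = NULL
  )
  structure(
    list(params = params, results = res,
         branches = lapply(ev, `[[`, "branches")),
    class = "cf_model"
  )
}

#' @export
print.cf_model <- function(x, ...) {
  cat("Antenatal depression case-finding decision model (20-week horizon)\n")
  cat("Deterministic expected values per person:\n")
  df <- x$results
  df$cost <- sprintf("£%.2f", df$cost)
  df$qaly <- sprintf("%.4f", df$qaly)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Incremental cost-effectiveness summary of a fitted model
#'
#' Orders strategies by cost and performs a frontier analysis: strictly
#' dominated strategies (at least as costly and no more effective than
#' another) are flagged, extendedly dominated strategies (bypassed by a
#' steeper-then-flatter ICER sequence) are flagged, and ICERs are computed
#' along the efficient frontier from unrounded values.
#'
#' @param object a `cf_model`.
#' @param ... unused.
#' @return an object of class `cf_icers`: the results table augmented with
#'   `status` and `icer` columns.
#' @export
summary.cf_model <- function(object, ...) {
  ia <- incremental_analysis(object$results)
  class(ia) <- c("cf_icers", class(ia))
  ia
}

#' @export
print.cf_icers <- function(x, ...) {
  cat("Incremental cost-effectiveness analysis\n")
  df <- as.data.frame(x)
  df$cost <- sprintf("£%.2f", df$cost)
  df$qaly <- sprintf("%.4f", df$qaly)
  df$icer <- ifelse(is.na(df$icer), "-", sprintf("£%.0f/QALY", df$icer))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Incremental analysis with dominance and extended dominance
#'
#' @param results data.frame with columns `strategy`, `cost`, `qaly`.
#' @return the input ordered by ascending cost with `status`
#'   (`"reference"`, `"icer"`, `"dominated"`, `"extendedly_dominated"`) and
#'   `icer` (GBP/QALY vs the previous frontier strategy; `NA` off the
#'   frontier and for the reference).
#' @examples
#' incremental_analysis(data.frame(strategy = c("A", "B"),
#'                                 cost = c(100, 50), qaly = c(1, 2)))
#' @export
incremental_analysis <- function(results) {
  if (nrow(results) < 1) stop("no strategies to compare")
  df <- results[order(results$cost, results$strategy), , drop = FALSE]
  n <- nrow(df)
  status <- rep("icer", n)
  # strict dominance: another strategy costs no more and yields at least as
  # many QALYs, with at least one strict inequality
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance on the remaining candidates: ICERs along the frontier
  # must be increasing; drop any strategy whose ICER vs the previous frontier
  # point exceeds that of a later candidate
  repeat {
    idx <- which(status != "dominated" & status != "extendedly_dominated")
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qaly[idx])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    status[idx[bad[1] + 1]] <- "extendedly_dominated"
  }
  frontier <- which(status %in% "icer")
  df$status <- status
  df$icer <- NA_real_
  if (length(frontier)) {
    df$status[frontier[1]] <- "reference"
    if (length(frontier) > 1) {
      df$icer[frontier[-1]] <- diff(df$cost[frontier]) / diff(df$qaly[frontier])
    }
  }
  row.names(df) <- NULL
  df
}

#' @export
coef.cf_model <- function(object, ...) {
  rp <- realise_params(object$params)
  c(
    p_highrisk = rp$p_highrisk,
    prev_whole = rp$prev[["whole"]], prev_high = rp$prev[["high"]],
    prev_low_targeted = rp$prev_low_targeted,
    sens_cf_whole = rp$sens_cf[["whole"]], spec_cf_whole = rp$spec_cf[["whole"]],
    sens_cf_high = rp$sens_cf[["high"]], spec_cf_high = rp$spec_cf[["high"]],
    sens_std = rp$sens_std, spec_std = rp$spec_std,
    screen_cost = rp$screen_cost, gp_cost = rp$gp_cost,
    u_nondep_whole = rp$u_nondep[["whole"]]
  )
}

#' Project the model onto a fixed birth cohort
#'
#' Scales screening-outcome probabilities and per-person expected values to a
#' hypothetical cohort (600,000 women by default, the approximate annual
#' number of births in England and Wales). Counts are reported per stratum
#' block (the targeted strategy has separate high-risk and low-risk blocks),
#' with TP/FN derived from the unrounded number of depressed women, all
#' counts rounded half-up, and TN as the remainder so blocks sum exactly.
#'
#' @param object a `cf_model`.
#' @param cohort_size number of women, default 600,000.
#' @param ... unused.
#' @return an object of class `cf_projection`: a data.frame with one row per
#'   strategy-stratum block (`n`, `n_depressed`, `TP`, `TN`, `FN`, `FP`,
#'   `total_cost`, `total_qalys`).
#' @examples
#' predict(cf_model(), cohort_size = 600000)
#' @export
predict.cf_model <- function(object, cohort_size = 600000, ...) {
  if (cohort_size < 0) stop("cohort_size must be non-negative")
  rp <- realise_params(object$params)
  rows <- list()
  for (s in object$results$strategy) {
    arms <- strategy_arms(rp, s)
    for (a in arms) {
      n_arm <- cohort_size * a$weight
      pr <- branch_probabilities(a$prev, a$sens, a$spec, a$mode, a$p_visit)
      n_dep <- n_arm * a$prev
      tp <- round_half_up(n_arm * pr[["TP"]])
      fn <- round_half_up(n_arm * pr[["FN"]])
      fp <- round_half_up(n_arm * pr[["FP"]])
      tn <- round_half_up(n_arm) - tp - fn - fp
      rows[[length(rows) + 1]] <- data.frame(
        strategy = s,
        stratum = if (a$prefix == "") "whole" else sub("\\.$", "", a$prefix),
        n = round_half_up(n_arm),
        n_depressed = round_half_up(n_dep),
        TP = tp, TN = tn, FN = fn, FP = fp,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  # totals are per-person means scaled to the full cohort, attached to the
  # first block of each strategy
  out$total_cost <- NA_real_
  out$total_qalys <- NA_real_
  first <- !duplicated(out$strategy)
  out$total_cost[first] <- object$results$cost[match(out$strategy[first],
                                                     object$results$strategy)] * cohort_size
  out$total_qalys[first] <- object$results$qaly[match(out$strategy[first],
                                                      object$results$strategy)] * cohort_size
  attr(out, "cohort_size") <- cohort_size
  class(out) <- c("cf_projection", class(out))
  out
}

#' @export
print.cf_projection <- function(x, ...) {
  cat(sprintf("Projection onto a cohort of %s women\n",
              format(attr(x, "cohort_size"), big.mark = ",", scientific = FALSE)))
  df <- as.data.frame(x)
  df$total_cost <- ifelse(is.na(df$total_cost), "",
                          sprintf("£%.0f", df$total_cost))
  df$total_qalys <- ifelse(is.na(df$total_qalys), "",
                           sprintf("%.0f", df$total_qalys))
  print(df, row.names = FALSE)
  invisible(x)
}
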