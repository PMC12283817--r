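# Declarative one-way sensitivity-scenario engine. A scenario is a named set
# of parameter overrides addressed by `$`-separated paths into the parameter
# structure; applying a scenario returns a new parameter set and leaves the
# base set untouched.

#' Define a sensitivity scenario
#'
#' @param name scenario label.
#' @param ... overrides as `path = value` pairs, where `path` is a
#'   `$`-separated path into the parameter structure (e.g.
#'   `"utility$fp_decrement" = 0.02`, `"costs$gp_minutes" = 13.83`). A scalar
#'   assigned to an uncertain quantity replaces its mean and keeps its
#'   uncertainty descriptor.
#' @return an object of class `adc_scenario`.
#' @export
scenario <- function(name, ...) {
  structure(list(name = name, overrides = list(...)), class = "adc_scenario")
}

param_paths <- function(x, prefix = character(0)) {
  if (inherits(x, "adc_unc") || !is.list(x)) {
    return(paste(prefix, collapse = "$"))
  }
  unlist(lapply(names(x), function(nm) param_paths(x[[nm]], c(prefix, nm))))
}

set_path <- function(params, path, value) {
  parts <- strsplit(path, "$", fixed = TRUE)[[1]]
  node <- params
  for (p in parts) {
    if (is.null(node[[p]])) {
      stop(sprintf("unknown parameter path '%s'; valid paths include: %s",
                   path, paste(utils::head(param_paths(unclass(params)), 12),
                               collapse = ", ")))
    }
    node <- node[[p]]
  }
  target <- if (inherits(node, "adc_unc") && is.numeric(value) &&
                length(value) == 1) {
    node$mean <- value
    node
  } else {
    value
  }
  set_nested <- function(x, parts, value) {
    if (length(parts) == 1) {
      x[[parts]] <- value
      return(x)
    }
    x[[parts[1]]] <- set_nested(x[[parts[1]]], parts[-1], value)
    x
  }
  set_nested(params, parts, target)
}

#' Apply a scenario to a parameter set
#'
#' @param params an `adc_params` object (left unmodified).
#' @param scn an `adc_scenario`, or `NULL` / an empty scenario for the base
#'   case.
#' @return a new validated `adc_params` object.
#' @examples
#' p <- apply_scenario(model_params(), scenario("fp2", "utility$fp_decrement" = 0.02))
#' p$utility$fp_decrement
#' @export
apply_scenario <- function(params, scn = NULL) {
  if (is.null(scn)) return(params)
  if (!inherits(scn, "adc_scenario")) stop("'scn' must be created by scenario()")
  out <- params
  for (path in names(scn$overrides)) {
    out <- set_path(out, path, scn$overrides[[path]])
  }
  validate_params(out)
  out
}

#' The pre-specified sensitivity scenarios
#'
#' The one-way scenarios of the analysis plan: a utility decrement for
#' false-positive outcomes (2% and 10%); instrument administration time set
#' to zero (completed online before the visit; scoring time retained) or
#' trebled (administration and scoring, matching the published totals of
#' 5.13 min for the Whooley questions and 10.62 min for PHQ-9/EPDS); the
#' false-positive partial treatment fraction at 10% and 30%; the probability
#' that a missed case is later identified by the GP at 5% and 25%; and a
#' longer GP consultation to assess depression (13.83 min, 1.5 times the
#' 9.22-min average).
#'
#' @return named list of `adc_scenario` objects (including the base case).
#' @export
baseline_scenarios <- function() {
  list(
    base = scenario("base"),
    fp_decrement_2 = scenario("fp_decrement_2", "utility$fp_decrement" = 0.02),
    fp_decrement_10 = scenario("fp_decrement_10", "utility$fp_decrement" = 0.10),
    admin_online = scenario("admin_online", "costs$admin_multiplier" = 0),
    admin_3x = scenario("admin_3x", "costs$admin_multiplier" = 3,
                        "costs$scoring_multiplier" = 3),
    fp_fraction_10 = scenario("fp_fraction_10", "costs$fp_fraction" = 0.10),
    fp_fraction_30 = scenario("fp_fraction_30", "costs$fp_fraction" = 0.30),
    fn_identified_5 = scenario("fn_identified_5", "p_fn_identified" = 0.05),
    fn_identified_25 = scenario("fn_identified_25", "p_fn_identified" = 0.25),
    gp_consultation_long = scenario("gp_consultation_long",
                                    "costs$gp_minutes" = 13.83)
  )
}

#' Run a set of scenarios
#'
#' Deterministic evaluation plus incremental analysis for each scenario.
#'
#' @param params base parameter set.
#' @param scenarios list of `adc_scenario` objects, default
#'   [baseline_scenarios()].
#' @param strategies strategies to compare.
#' @return data.frame with one row per scenario-strategy combination:
#'   `scenario`, `strategy`, `cost`, `qaly`, `status`, `icer`.
#' @export
run_scenarios <- function(params = model_params(),
                          scenarios = baseline_scenarios(),
                          strategies = c("none", "universal", "targeted")) {
  rows <- lapply(scenarios, function(scn) {
    p <- apply_scenario(params, scn)
    m <- cf_model(p, strategies)
    ia <- incremental_analysis(m$results)
    ia$scenario <- scn$name
    ia
  })
  out <- do.call(rbind, rows)
  out <- out[, c("scenario", "strategy", "cost", "qaly", "status", "icer")]
  row.names(out) <- NULL
  out
}
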