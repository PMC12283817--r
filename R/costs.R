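#' Cost of administering and scoring a case-finding instrument
#'
#' Midwife time (administration plus scoring, in minutes) multiplied by the
#' per-minute staff rate, reported to the penny (half up). A Band 6 midwife at
#' GBP 55/h corresponds to GBP 0.92/min.
#'
#' @param admin_minutes minutes to administer the instrument.
#' @param scoring_minutes minutes to score the instrument.
#' @param rate_per_minute staff cost per minute (GBP).
#' @return cost in GBP, rounded half-up to 2 decimal places.
#' @examples
#' instrument_cost(0.71, 1, 0.92) # Whooley questions, 1.57
#' instrument_cost(1.54, 2, 0.92) # EPDS / PHQ-9, 3.26
#' @export
instrument_cost <- function(admin_minutes, scoring_minutes, rate_per_minute) {
  if (admin_minutes < 0 || scoring_minutes < 0 || rate_per_minute < 0) {
    stop("instrument cost components must be non-negative")
  }
  round_half_up((admin_minutes + scoring_minutes) * rate_per_minute, 2)
}

#' Cost of a treatment package
#'
#' Staff contact time at a per-minute rate, plus materials, plus GP
#' consultations at the GP consultation unit cost, plus drug costs.
#'
#' @param staff_minutes total staff contact minutes.
#' @param rate_per_minute staff cost per face-to-face minute (GBP).
#' @param materials materials cost (GBP), e.g. a self-help manual.
#' @param gp_consultations number of GP consultations bundled with treatment.
#' @param drug_cost drug acquisition cost (GBP).
#' @param gp_consultation_cost unit cost of one GP consultation (GBP).
#' @return cost in GBP, rounded half-up to 2 decimal places.
#' @examples
#' treatment_cost(175, 0.85, materials = 7, gp_consultations = 3)  # FSH, 273.44
#' treatment_cost(440, 1.80, gp_consultations = 3)                 # IPT, 909.69
#' treatment_cost(0, 0, gp_consultations = 7, drug_cost = 25.65)   # sertraline, 300.26
#' @export
treatment_cost <- function(staff_minutes, rate_per_minute, materials = 0,
                           gp_consultations = 0, drug_cost = 0,
                           gp_consultation_cost = 39.23) {
  args <- c(staff_minutes, rate_per_minute, materials, gp_consultations, drug_cost)
  if (any(args < 0)) stop("treatment cost components must be non-negative")
  round_half_up(
    staff_minutes * rate_per_minute + materials +
      gp_consultations * gp_consultation_cost + drug_cost,
    2
  )
}

#' Partial treatment cost attributed to a false-positive case
#'
#' Women incorrectly identified as depressed are assumed to start, but not
#' complete, facilitated self-help; a fraction of the full FSH package cost is
#' attributed to them.
#'
#' @param full_cost full treatment/monitoring package cost (GBP).
#' @param fraction fraction of the full cost incurred, in `[0, 1]`.
#' @return cost in GBP, rounded half-up to 2 decimal places.
#' @examples
#' false_positive_cost(273.44, 0.20) # 54.69
#' @export
false_positive_cost <- function(full_cost, fraction) {
  stopifnot_proportion(fraction, "fraction")
  if (full_cost < 0) stop("full_cost must be non-negative")
  round_half_up(full_cost * fraction, 2)
}

#' Derive a no-recovery probability from a baseline and a relative risk
#'
#' Treatment effects are reported as relative risks against a baseline
#' (placebo or treatment-as-usual) probability. Depending on whether the RR
#' acts on recovery or on no-recovery, the probability of *no* recovery is
#' `1 - baseline * RR` or `baseline * RR` respectively. The unrounded value is
#' returned and carried through the model; published tables round to 2 dp.
#'
#' @param baseline baseline probability the relative risk acts on.
#' @param rr relative risk.
#' @param direction whether `baseline * rr` is a probability of `"recovery"`
#'   or of `"no_recovery"`.
#' @return probability of no recovery (unrounded).
#' @examples
#' derive_recovery(0.38, 1.59, "recovery")    # FSH: 0.3958 (recovery 0.6042)
#' derive_recovery(0.64, 0.69, "no_recovery") # IPT: 0.4416
#' derive_recovery(0.43, 1.27, "recovery")    # sertraline: 0.4539
#' @export
derive_recovery <- function(baseline, rr, direction = c("recovery", "no_recovery")) {
  direction <- match.arg(direction)
  p <- baseline * rr
  if (is.na(p) || p < 0 || p > 1) {
    stop(sprintf("baseline * RR = %g lies outside [0, 1]", p))
  }
  if (direction == "recovery") 1 - p else p
}
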