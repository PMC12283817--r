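# Independent Monte-Carlo microsimulation of the decision tree: individual
# women are walked through risk stratification, identification, treatment and
# recovery, with costs and QALYs accumulated from closed-form per-path
# formulas written out directly (not via the package's trajectory/QALY code).
# Serves as the oracle for the analytic tree evaluation.

microsim_strategy <- function(rp, strategy, n, seed) {
  set.seed(seed)
  u_n <- rp$u_nondep[["whole"]]
  u_mild <- u_n * (1 - rp$dec_mild)
  u_ms <- u_n * (1 - rp$dec_modsev)
  u_fp <- u_n * (1 - rp$fp_decrement)

  # closed-form utility-week areas over the 20-week horizon
  q_flat <- function(u) 20 * u / 52
  q_treated <- function(u0) (8 * (u0 + u_n) / 2 + 12 * u_n) / 52
  q_spont <- function(u0) (7 * (u0 + u_n) / 2 + 13 * u_n) / 52
  q_late <- function(u0) (10 * u0 + 8 * (u0 + u_n) / 2 + 2 * u_n) / 52
  q_decline <- 20 * (u_mild + u_ms) / 2 / 52

  if (strategy == "targeted") {
    hr <- stats::runif(n) < rp$p_highrisk
    prev <- ifelse(hr, rp$prev[["high"]], rp$prev_low_targeted)
    cf <- hr
    sens <- ifelse(hr, rp$sens_cf[["high"]], rp$sens_std)
    spec <- ifelse(hr, rp$spec_cf[["high"]], rp$spec_std)
    p_visit <- ifelse(hr, 0, rp$p_visit[["low"]])
  } else if (strategy == "universal") {
    cf <- rep(TRUE, n)
    prev <- rep(rp$prev[["whole"]], n)
    sens <- rep(rp$sens_cf[["whole"]], n)
    spec <- rep(rp$spec_cf[["whole"]], n)
    p_visit <- rep(0, n)
  } else {
    cf <- rep(FALSE, n)
    prev <- rep(rp$prev[["whole"]], n)
    sens <- rep(rp$sens_std, n)
    spec <- rep(rp$spec_std, n)
    p_visit <- rep(rp$p_visit[["whole"]], n)
  }

  dep <- stats::runif(n) < prev
  modsev <- dep & (stats::runif(n) < rp$p_modsev)
  visit <- !cf & (stats::runif(n) < p_visit)

  identified <- dep & (stats::runif(n) < sens)
  fp <- !dep & (stats::runif(n) < (1 - spec)) & (cf | visit)

  # treatment: mild -> FSH; moderate/severe -> sampled mix
  tx <- rep(NA_character_, n)
  tx[dep & !modsev] <- "fsh"
  i_ms <- which(dep & modsev)
  tx[i_ms] <- sample(c("ipt", "pharma", "both"), length(i_ms), replace = TRUE,
                     prob = rp$mix)
  recovers <- !is.na(tx) & (stats::runif(n) < rp$recovery[tx])

  fn <- dep & !identified
  spont <- fn & (stats::runif(n) < (1 - rp$p_no_spont))
  late <- fn & !spont & (stats::runif(n) < rp$p_fn_identified)

  cost <- numeric(n)
  cost[cf] <- cost[cf] + rp$screen_cost
  cost[visit] <- cost[visit] + rp$gp_cost
  pos <- identified | fp
  cost[pos & cf] <- cost[pos & cf] + rp$assess_cost + rp$gp_cost
  cost[pos & !cf] <- cost[pos & !cf] + rp$gp_cost
  cost[identified] <- cost[identified] + rp$treat_cost[tx[identified]]
  cost[fp] <- cost[fp] + rp$fp_cost
  cost[late] <- cost[late] + rp$gp_cost + rp$treat_cost[tx[late]]

  u0 <- ifelse(modsev, u_ms, u_mild)
  q <- numeric(n)
  q[!dep & !fp] <- q_flat(u_n)
  q[fp] <- q_flat(u_fp)
  q[identified & recovers] <- q_treated(u0[identified & recovers])
  q[identified & !recovers] <- q_flat(u0[identified & !recovers])
  q[spont] <- q_spont(u0[spont])
  q[late & recovers] <- q_late(u0[late & recovers])
  q[late & !recovers] <- q_flat(u0[late & !recovers])
  missed <- fn & !spont & !late
  q[missed & !modsev] <- q_decline
  q[missed & modsev] <- q_flat(u_ms)

  list(
    cost = mean(cost), cost_se = stats::sd(cost) / sqrt(n),
    qaly = mean(q), qaly_se = stats::sd(q) / sqrt(n)
  )
}

# set all uncertainty descriptors in a parameter set to zero (degenerate PSA)
zero_uncertainty <- function(params) {
  strip <- function(x) {
    if (inherits(x, "adc_unc")) {
      x$se <- 0
      x$ci <- NULL
      x
    } else if (is.list(x)) {
      structure(lapply(x, strip), class = class(x))
    } else {
      x
    }
  }
  strip(params)
}
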