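#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain probability and utility from a beta distribution
#' matched to its mean and standard error (method of moments; SEs recovered
#' from 95% CIs as width/3.92 where only a CI is published), holds unit costs
#' fixed, and re-evaluates the strategies on independent draws within each
#' iteration (each strategy carries the full parameter uncertainty, so
#' decision uncertainty is not artificially suppressed for strategies whose
#' structural parameters coincide). The moderate/severe treatment-mix shares
#' are drawn individually and renormalised; the whole-sample prevalence is
#' derived per draw from the stratum primitives so that all probabilities
#' remain coherent.
#'
#' `simulate()` on a fitted [cf_model()] is the idiomatic entry point.
#'
#' @param object a `cf_model`.
#' @param nsim number of PSA iterations (10,000 in the primary analysis).
#' @param seed integer seed; the full PSA is deterministic given the seed.
#' @param thresholds willingness-to-pay thresholds (GBP/QALY) at which the
#'   cost-effectiveness acceptability curve is evaluated.
#' @param ... unused.
#' @return an object of class `cf_psa`: per-iteration costs and QALYs per
#'   strategy, percentile summaries, and the CEAC. Methods:
#'   [print.cf_psa()], [summary.cf_psa()], [plot.cf_psa()].
#' @examples
#' m <- cf_model()
#' psa <- simulate(m, nsim = 100, seed = 1)
#' summary(psa)
#' @export
simulate.cf_model <- function(object, nsim = 10000, seed = 1,
                              thresholds = c(0, 20000, 30000), ...) {
  run_psa(object$params, strategies = object$results$strategy,
          n_iter = nsim, seed = seed, thresholds = thresholds)
}

#' @rdname simulate.cf_model
#' @param params an `adc_params` object.
#' @param strategies strategies to compare.
#' @param n_iter number of iterations.
#' @export
run_psa <- function(params = model_params(),
                    strategies = c("none", "universal", "targeted"),
                    n_iter = 10000, seed = 1,
                    thresholds = c(0, 20000, 30000)) {
  validate_params(params)
  if (n_iter < 1) stop("n_iter must be at least 1")
  up <- uncertain_params(params)
  ns <- length(strategies)
  # independent draws per strategy within an iteration: each strategy is
  # evaluated on its own parameter vector, so decision uncertainty reflects
  # the full parameter uncertainty of every strategy
  draws <- with_seed(seed, lapply(up, unc_draw, n = n_iter * ns))
  cost <- matrix(NA_real_, n_iter, ns, dimnames = list(NULL, strategies))
  qal <- cost
  for (i in seq_len(n_iter)) {
    for (k in seq_len(ns)) {
      d <- lapply(draws, `[[`, (i - 1L) * ns + k)
      rp <- realise_params(params, d)
      ut <- stratum_utilities(rp, "whole")
      v <- strategy_values(rp, strategies[k], ut)
      cost[i, k] <- v[["cost"]]
      qal[i, k] <- v[["qaly"]]
    }
  }
  summ <- data.frame(
    strategy = strategies,
    mean_cost = colMeans(cost),
    cost_lo = apply(cost, 2, stats::quantile, 0.025),
    cost_hi = apply(cost, 2, stats::quantile, 0.975),
    mean_qaly = colMeans(qal),
    qaly_lo = apply(qal, 2, stats::quantile, 0.025),
    qaly_hi = apply(qal, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  structure(
    list(cost = cost, qaly = qal, summary = summ,
         ceac = ceac(cost, qal, thresholds),
         n_iter = n_iter, seed = seed, thresholds = thresholds),
    class = "cf_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Probability each strategy has the maximal net monetary benefit
#' (`lambda * QALYs - cost`) across PSA iterations, per willingness-to-pay
#' threshold; ties are split equally, so probabilities sum to one at every
#' threshold.
#'
#' @param cost,qaly iteration-by-strategy matrices.
#' @param thresholds willingness-to-pay values (GBP/QALY).
#' @return data.frame with `threshold` and one probability column per
#'   strategy.
#' @export
ceac <- function(cost, qaly, thresholds = c(0, 20000, 30000)) {
  out <- lapply(thresholds, function(l) {
    nmb <- l * qaly - cost
    best <- nmb >= apply(nmb, 1, max) - 1e-12
    wins <- best / rowSums(best)
    colMeans(wins)
  })
  df <- data.frame(threshold = thresholds, do.call(rbind, out))
  names(df)[-1] <- colnames(cost)
  row.names(df) <- NULL
  df
}

#' @export
print.cf_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  print(summary(x))
  invisible(x)
}

#' @export
summary.cf_psa <- function(object, ...) {
  df <- object$summary
  out <- data.frame(
    strategy = df$strategy,
    cost = sprintf("%.2f (%.2f, %.2f)", df$mean_cost, df$cost_lo, df$cost_hi),
    qalys = sprintf("%.4f (%.4f, %.4f)", df$mean_qaly, df$qaly_lo, df$qaly_hi)
  )
  for (i in seq_len(nrow(object$ceac))) {
    out[[sprintf("p_ce_at_%g", object$ceac$threshold[i])]] <-
      sprintf("%.3f", unlist(object$ceac[i, -1]))
  }
  out
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x a `cf_psa` object.
#' @param lambda_grid optional dense threshold grid for smooth curves;
#'   defaults to 0 to 50,000 in steps of 1,000.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cf_psa <- function(x, lambda_grid = seq(0, 50000, by = 1000), ...) {
  cc <- ceac(x$cost, x$qaly, lambda_grid)
  graphics::matplot(cc$threshold, as.matrix(cc[, -1]), type = "l", lty = 1,
                    lwd = 2, col = seq_len(ncol(cc) - 1),
                    xlab = "Willingness to pay (GBP/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = names(cc)[-1], lty = 1, lwd = 2,
                   col = seq_len(ncol(cc) - 1), bty = "n")
  invisible(cc)
}
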