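---
title: "Modelling the cost-effectiveness of antenatal depression case finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of antenatal depression case finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcase)
```

## The decision problem

Around one in ten pregnant women experiences antenatal depression, and most
cases are not identified by routine care. Systematic *case finding* —
administering a short screening instrument such as the Whooley questions,
the EPDS or the PHQ-9, with screen positives referred for further
assessment — is one way to improve identification. Because midwife and GP
time is scarce, a *targeted* programme restricted to women with at least one
recognised risk factor (age under 20, history of anxiety, history of
depression, or a recent threatening life event) is an alternative to
*universal* screening.

`adcase` implements a decision-tree cost-effectiveness model comparing three
strategies for a cohort of women at around 20 weeks' gestation, over a
20-week horizon to approximately the time of birth, from the perspective of
the English NHS and personal social services (2021 prices):

* **no case finding** — depression can only be identified when a woman
  visits her GP with symptoms;
* **universal case finding** — every woman is screened with the two-stage
  Whooley-then-PHQ-9 strategy (the only candidate strategy passing the
  inclusion bounds of at least 70% sensitivity and at least 60% specificity);
* **targeted case finding** — women with at least one risk factor (55.8% of
  the population) are screened; the rest receive standard care.

Health benefit is measured in QALYs accrued over the horizon from
EQ-5D-based utilities; no discounting is applied as the horizon is under a
year.

## Model structure

Each strategy partitions women by gold-standard depression status and
screening outcome (TP/FN/TN/FP). Under case finding,

$$P(\mathrm{TP}) = \pi\,s,\quad P(\mathrm{FN}) = \pi(1-s),\quad
  P(\mathrm{FP}) = (1-\pi)(1-c),$$

with prevalence $\pi$, sensitivity $s$ and specificity $c$. Under standard
care, identification of non-depressed women as false positives additionally
requires a GP visit (probability 0.722 whole-sample, 0.642 low-risk), while
identification of depressed women uses the standard-care sensitivity 0.501
directly. This asymmetry is required to reproduce the published projected
counts for the no-case-finding arm, and is kept as such.

Identified (true positive) women are treated according to severity: mild to
moderate depression (70%) receives facilitated self-help (FSH, £273.44);
moderate to severe depression (30%) receives intensive psychological
therapy (12.8%, £909.69), sertraline (52.3%, £300.26) or both (34.9%,
£935.34). Recovery probabilities are derived unrounded from published
baselines and relative risks (e.g. FSH: $0.38 \times 1.59 = 0.6042$).
False negatives recover spontaneously with probability 0.35; of those who
do not, 10% are identified by their GP at week 10 and treated. False
positives incur 20% of the FSH cost (£54.69).

### QALY accrual

Utility trajectories are piecewise linear over the horizon and integrated
exactly by the trapezoidal rule:

* non-depressed (TN and FP): flat at the stratum utility (0.910 whole
  sample); an optional FP decrement applies in scenarios;
* treated responders: linear improvement from the severity-specific
  depressed utility (12% decrement mild, 26% moderate/severe) to the
  non-depressed utility over the 8-week course, flat after;
* spontaneous recovery: the same shape over 7 weeks;
* late-identified responders: flat depressed to week 10, ramp to week 18;
* untreated mild cases decline linearly to the moderate/severe utility
  across the horizon — untreated antenatal depression worsens; untreated
  moderate/severe cases remain flat at the moderate/severe utility.

### Cost composition

Decisions where published totals constrain but do not uniquely determine
the pathway arithmetic:

* **Two-stage screening cost.** Both instruments are costed for every
  screened woman (£1.57 + £3.26 = £4.83). This keeps the screening cost
  independent of first-stage positivity and is the convention consistent
  with the published sensitivity analysis on administration time, where
  trebling the instrument time raises the universal strategy's per-person
  cost by exactly three times the full two-instrument cost minus the base
  cost.
* **Treatment-initiation consultation.** Every identified positive (true
  and false), in every arm, incurs one GP consultation (£39.23) alongside
  the one-hour midwife assessment (£55) charged in the case-finding arms;
  clinically, prescribing or referral goes through the GP. With this
  composition the deterministic per-person costs are £53.52 (universal),
  £62.26 (none) and £64.34 (targeted), within about 4% of the published
  £52.24 / £61.10 / £61.81, and every published dominance relationship is
  reproduced.
* **GP visits in standard care.** Every woman who visits her GP incurs one
  consultation, whether or not depression is identified.
* **Utilities in the three-way comparison.** All three strategies are
  evaluated on the whole-sample utility set. Using the high-risk utility
  (0.869) inside the targeted strategy's screening arm would make its QALYs
  incomparable with the other strategies (the published per-person QALYs
  for targeted are arithmetically impossible under stratum-specific
  utilities). Stratum-specific utility sets remain available via
  `stratum_utilities()` for stratum-restricted analyses.
* **Prevalence coherence.** The published whole-sample prevalence (10.3%)
  differs from the mixture of the published stratum figures
  ($0.558 \times 0.171 + 0.442 \times 0.017 = 0.1029$) by rounding. The
  model treats the whole-sample prevalence as this mixture plus the
  constant offset, so the base case reproduces the published value exactly
  while probabilistic draws of the stratum primitives remain coherent (the
  low-risk share of depression under the targeted strategy can never go
  negative). The low-risk arm's prevalence is derived as the whole-sample
  total minus the high-risk total, reproducing the published projected
  count of depressed low-risk women.

## Worked example

```{r}
m <- cf_model()
m
summary(m)
```

The universal strategy costs less and yields more QALYs than no case
finding (dominance); the targeted strategy gains slightly more QALYs than
universal at an incremental cost-effectiveness ratio far above the £30,000
per QALY threshold.

```{r}
predict(m, cohort_size = 600000)
```

```{r, fig.width = 6, fig.height = 4}
psa <- simulate(m, nsim = 2000, seed = 1)
summary(psa)
plot(psa)
```

```{r}
head(run_scenarios(scenarios = baseline_scenarios()[c("base", "fp_decrement_2",
                                                      "admin_3x")]), 9)
```

## The synthetic cohort generator

No individual-level data ship with the package; `generate_cohort()` creates
cohorts with the statistical structure the analysis assumes, so the whole
derivation pipeline is testable end to end.

* **Risk factors** are generated from an equicorrelated probit model: each
  factor indicator thresholds a latent normal sharing a single common
  factor. One association parameter controls the overlap;
  `calibrate_association()` finds it by bisection on the (monotone) union
  probability, computed by deterministic quadrature, so that 55.8% of women
  carry at least one factor despite the independence bound being about 66%.
* **Depression and severity** are Bernoulli conditional on stratum (17.1% /
  1.7%) and on depression (30% moderate/severe).
* **Instrument responses** load on a shared latent severity trait with
  instrument-specific noise; latent cell means for (stratum x status) are
  solved numerically so that the two-stage Whooley-then-PHQ-9 strategy
  attains 74.2% / 85.0% sensitivity/specificity in the high-risk stratum
  and 70.6% / 89.5% whole-sample. The implied low-risk cells (sensitivity
  about 0.25 among low-risk depressed women, specificity about 0.94) follow
  from mixture decomposition. PHQ-9 and EPDS scores are discretised from
  the latent response so that the score thresholds coincide with the
  latent thresholds.
* **Utilities** are beta-distributed per woman with the configured
  stratum/severity mean and a between-woman SD of 0.15. A truncated
  Gaussian was rejected: censoring at 1 with a realistic SD shifts the
  non-depressed mean by about 0.02, which would make the generator's means
  unrecoverable; the beta form is bounded by construction, mean-exact, and
  right-skewed like observed EQ-5D index values.
* **Not emulated:** item-level instrument responses, longitudinal
  (postnatal) waves, and item missingness (an optional missingness rate
  exists for the life-event factor but defaults to zero, as the analysis
  uses complete cases). Passing recovery tests therefore show that the
  derivation pipeline is correct under the model's assumptions, not that
  those assumptions hold in any real cohort.

## Probabilistic sensitivity analysis

Probabilities and utilities are drawn from beta distributions matched by
the method of moments to their mean and SE (SEs recovered from published
95% CIs as width/3.92, including asymmetric CIs); unit costs are fixed. The
three moderate/severe treatment-mix shares are drawn individually from
their CIs and renormalised to sum to one. The probability that a missed
case is later identified (0.10, an expert-opinion value without a reported
CI) is held fixed and varied only in scenarios. Operating characteristics
of the two-stage strategy carry binomial SEs at the source-cohort group
sizes (40 cases / 351 non-cases whole-sample; 37 / 181 high-risk), as no
CIs are published for them.

Within each iteration the strategies are evaluated on **independent**
parameter draws. With draws common across strategies, the strategies'
QALYs move almost in lockstep and the acceptability curve degenerates
(the dominant strategy wins essentially every iteration), which is
irreconcilable with the published spread of the acceptability
probabilities; independent draws reproduce that spread qualitatively.
The CEAC reports, per willingness-to-pay threshold, the proportion of
iterations in which each strategy has the highest net monetary benefit
$\lambda Q - C$, with exact ties split equally so the probabilities always
sum to one. Percentile (2.5/97.5) intervals summarise iteration spread.

## Numerical choices and conventions

* Monetary rounding is half-up to the penny at reporting boundaries only;
  derived probabilities are carried unrounded through the model (ICERs are
  computed from unrounded values).
* Trapezoidal integration is exact for the piecewise-linear trajectories;
  QALYs use 52 weeks per year.
* Projection counts round half-up, with TP/FN derived from the unrounded
  number of depressed women and TN as the block remainder, so blocks sum
  exactly to the cohort size.
* The frontier algorithm removes strictly dominated strategies, then
  iteratively removes extendedly dominated ones until ICERs increase along
  the frontier; ties are broken by strategy label.
* Scenario overrides address parameters by `$`-separated path, are applied
  to a copy, and are re-validated; the "trebled administration time"
  scenario multiplies administration *and* scoring minutes by three
  (matching the published scenario totals of 5.13 and 10.62 minutes), while
  the "online completion" scenario zeroes administration time but retains
  scoring time. The long-GP-consultation scenario rescales every
  consultation charged at the standalone GP unit cost; consultations
  embedded in treatment package prices are part of those fixed packages.

## Problem sizes

The test suite exercises the generator and derivation at 100,000 women
(Monte-Carlo SEs small enough to resolve the 2-decimal parameter targets),
validates the analytic tree evaluation against a 200,000-walk independent
microsimulation within 3 Monte-Carlo SEs, and runs the PSA sanity checks at
2,000 iterations; the headline PSA uses 10,000 iterations, matching the
primary analysis.

## Limitations

The model inherits the published analysis' scope: a 20-week horizon ending
at birth (no postnatal costs or outcomes), maternal health only, a single
screening time point, no treatment sequencing or adherence, and treatment
efficacy borrowed from postnatal populations. The cost composition of the
standard-care arm is not uniquely identified by the published per-person
means; the branch audit table (`evaluate_strategy()$branches`) makes the
implemented composition fully inspectable.
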