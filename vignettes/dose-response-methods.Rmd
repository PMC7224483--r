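---
title: "Methods: an agent-based dose-response model for surgical cash transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based dose-response model for surgical cash transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cashdose)
```

## The question and the model

Conditional cash transfers offset the cost of seeking care, but the
relationship between the *size* of the transfer and compliance with
scheduled surgery is rarely measured. `cashdose` models that dose-response
for a coastal-Guinea setting: a synthetic population of agents on a
60 km x 60 km plane centred on a Conakry-like density cluster, nine
surveyed hospitals, and a single care-seeking decision per agent.

Each agent needs one of four index operations and chooses among the
hospitals offering it, or staying home, by McFadden random utility: the
deterministic part of the utility of hospital $j$ for agent $i$ is

$$V_{ij} = \gamma_i Q_j - \delta_i D_{ij} + \lambda_i\,
  c(Y_i - P_j + t),$$

and the stay-home alternative has $V_{i0} = \alpha_{\mathrm{home},i} +
\lambda_i$ (home sets $Q = D = P = 0$, so its money term is identically 1).
Any utility component that is constant across alternatives for one agent —
the intercept and all demographic main effects — cancels in the logit ratio
and is therefore not computed; the home offset $\alpha_{\mathrm{home}}$
absorbs their net effect on the care/home margin and is one of the two
calibrated parameters. The additive Gumbel error is never drawn explicitly:
choices are sampled from the multinomial-logit probabilities it implies.

Assumptions worth keeping in sight:

* **one decision, no interaction** — agents decide once, do not learn, and
  do not interact with each other; hospitals have no capacity limit;
* **independent attributes** — only the marginal distributions of gender,
  education, wealth, age and income are published, so attributes are drawn
  independently except income-given-wealth and procedure eligibility
  (cesarean requires a woman aged 15–49); wealth–location correlation,
  known to exist, is deliberately not invented;
* **planar distance** — road networks are not modelled; $D_{ij}$ is
  Euclidean km on the plane.

## The money term and why the curve must flatten

The cost function the utility uses is the capped net-income share

$$c(Y - P + t) = \min(Y - P + t,\ Y)/Y,$$

unitless, equal to 1 whenever the transfer covers the price, strictly
increasing in $t$ below that, and negative when the out-of-pocket
remainder exceeds a month's income. The cap is the mechanism behind the
headline result: once $t$ reaches the most expensive surveyed operation
(600,000 GNF), every alternative's money term is 1, utilities stop
depending on $t$, and the dose-response curve is exactly flat. A
`log_consumption` variant (`log` of the capped share, floored at 1% of
income) is available via the `money_form` configuration switch for
sensitivity analyses. No mechanism in this utility can make the no-show
rate *rise* again at very large transfers; a slow post-plateau uptick is
sometimes described for models of this kind, but it is not reproducible
from these equations and is intentionally not engineered in.

## Tunable parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `g_mean`, `g_sd` | quality weight $\gamma$ | unitless | 1, 0.2 | fixed; makes the quality spread (Q from 0.05 to 0.89) shift market shares by design |
| `d_mean`, `d_sd` | distance weight $\delta$ | per km | 0.05, 0.01 | fixed; ~3 utility units across the plane, so distance deters but does not dominate |
| `l_mean`, `l_sd` | money weight $\lambda$ | unitless | calibrated (~2.7), 0.5 | free parameter #1 |
| `a_home_mean`, `a_home_sd` | home offset | unitless | calibrated (~-0.44), 0.5 | free parameter #2 |
| `batch_size` | agents per run | agents | 20,000 | matches the batched design the model emulates |
| `n_runs` | runs per dose | runs | 50 | percentile UIs stable to well under a percentage point |
| dose grid | transfer sweep | GNF | 0–1,000,000 by 10,000 | the published experimental grid |

The preference-weight standard deviations are not published for this model
family; they are set once to plausible fractions of their means (they
create agent-level heterogeneity but barely move batch means, which the
calibration controls).

## Calibration

Two anchors identify the two free means: a 56.6% no-show rate with no
transfer and 30.0% at t = 280,000 GNF. The objective — the sum of squared
anchor errors in rate units — is evaluated on a fixed block of common
random numbers (10 runs x 5,000 agents per dose by default), making it a
deterministic, nearly smooth function of the parameters, and is minimized
by Nelder–Mead from the packaged starting values. With a single anchor the
money weight stays fixed and the home offset is found by bisection, since
the no-show rate is monotone in it. Convergence requires every anchor to
be reproduced within 1.5 percentage points; failure signals a condition
object carrying the best-found parameters. Because the small-budget
objective and the full-budget evaluation differ only by Monte Carlo error,
the calibrated model lands comfortably inside both published 95%
uncertainty bands at full scale (50 runs x 20,000 agents) for every master
seed we have tried.

## What the synthetic-data generator emulates — and what it does not

The population module stands in for the DHS- and WorldPop-derived inputs
of the original analysis.

* **Demographics** reproduce the published marginals exactly in
  expectation, including the idiosyncratic age structure (40.9% aged 50+);
  they are validated against the generator's own targets, not against
  national pyramids.
* **Income** is "quantized": a log-normal is fitted to the published
  median (554,986 GNF/month) and IQR (341,936–842,990), then partitioned
  at its own quintiles into five bands; each agent draws from their wealth
  quintile's band by inverse CDF. The median is matched exactly by
  construction; a two-parameter family cannot also match both quartiles,
  and the fit splits the residual evenly (both off by ~3.4%, within the
  5% the analysis tolerates). Incomes are treated as monthly, consistent
  with the World Bank monthly household-expenditure figure the survey
  write-up cites (457,785 GNF).
* **Space** is a two-component mixture: with probability 0.7 an agent
  falls in an isotropic Gaussian cluster (centre (12, 12) km, sd 6 km,
  truncated to the square axis-wise so the marginals stay analytic),
  otherwise uniform background. This emulates the qualitative
  Conakry-peninsula density gradient — all that matters for the distance
  term — not the real raster. Hospital coordinates are likewise synthetic
  (packaged fixed defaults, majority near the cluster); the real GPS
  positions were collected but never published.
* **Procedure need** is uniform over the four surveyed operations with
  ineligible cesarean draws reassigned. No case-mix data exist; uniform
  keeps the 600,000-GNF laparotomy price binding for a substantial share
  of agents, which is what places the plateau at the maximum price.

Consequently, passing tests show the *mechanism* is right under these
study conditions; they do not show the model predicts real Guinean
utilization — the original analysis itself validates only against
published aggregate no-show rates.

## Numerical choices

* **Softmax** is max-shifted per agent; probabilities match a brute-force
  $e^V/\sum e^V$ oracle to 1e-10 and normalize to 1 within 1e-12.
* **Uncertainty intervals** are empirical 2.5th–97.5th percentiles across
  runs with the linear-interpolation (R type 7) quantile definition,
  pinned explicitly because percentile definitions differ at these run
  counts.
* **Imputation** of unknown survey cells is the arithmetic mean of the
  column's known values; a reported 0 (hospital D's operating rooms) is a
  value, not a missing cell; "not offered" prices are never imputed.
  Printed summary statistics reproduce the survey write-up's per-statistic
  rounding (cesarean mean truncated, non-cesarean mean rounded).
* **Common random numbers**: the dose sweep reuses one per-run seed block
  at every dose, so adjacent-dose contrasts are nearly noise-free, the
  curve is monotone to machine precision below the cap, and every dose at
  or above 600,000 GNF is bit-identical. Plateau detection therefore
  defaults to an exact-flatness threshold (`epsilon = 1e-9`) on adjacent
  changes; for curves from independent streams, pass an epsilon of the
  order of the Monte Carlo noise instead.
* **Monotonicity** is assessed against the antitonic least-squares fit
  (`isoreg`), with a default tolerance of one standard error of a
  per-dose mean.
* **Seeds**: every pipeline entry point spawns per-run seeds from one
  master seed by a fixed scheme, so any result is reproducible from a
  single integer.

## Subgroup analysis

Per-run no-show rates are stratified by gender, education, age band (and
optionally wealth quintile); each stratum gets an across-run mean and 95%
UI, and a pairwise comparison against the first stratum of its variable.
Consistent with the model's interval-based reporting, the default
significance flag is non-overlap of the two strata's 95% UIs. The
across-run distribution of per-run differences is also summarized
(`diff_low`, `diff_high`), and `rule = "difference_ui"` flags on that
interval excluding zero instead — a considerably more sensitive rule that
detects even the sub-percentage-point structural gaps the cesarean
eligibility rule creates (eligible women face mostly free cesareans, so
female and 15–49 strata sit slightly lower at every dose). At the
calibrated defaults the default rule flags no gender, education or age
stratum, while an engineered stratum with 10-fold lower income is flagged
under either rule.

## Problem sizes

Desk-scale defaults keep a full pipeline (calibration, two full batches,
a 101-dose sweep) in the low minutes on one core: calibration evaluates
10 runs x 5,000 agents per dose per candidate, headline batches use
50 runs x 20,000 agents, and the sweep uses 10 runs x 5,000 agents per
dose. The original analysis ran 10,000 batches; `n_runs` scales there via
the configuration when that precision is needed.

## Known limitations

Beyond the scope cuts above: the choice set ignores informal and NGO care
outside the nine hospitals; prices are point values without non-medical
costs broken out (the transfer implicitly offsets the bundle); the
binary show/no-show outcome ignores delay; and the calibration anchors are
themselves model-derived published estimates, so the calibrated level
inherits their uncertainty even though the dose-response *shape* is driven
by the surveyed price structure.
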