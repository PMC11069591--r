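---
title: "Dynamic Bayesian networks for spatio-temporal search-frequency panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian networks for spatio-temporal search-frequency panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnpanel)
library(dplyr)
```

## The model

`dbnpanel` analyses weekly panels of nonnegative frequencies — one column
per health condition, one row per (state, county, week) — with a two-slice
Gaussian dynamic Bayesian network (DBN). Each condition appears twice, at a
generic week `t0` and the following week `t1`, and arcs may only point
forward in time; instantaneous (same-week) arcs are disallowed. Every `t1`
node is modelled by a linear regression on its parents at `t0`:

    X[i, t1] = mu[i] + sum_j beta[ij] * X[j, t0] + eps[i],   eps[i] ~ N(0, sigma2[i])

which makes the DBN a structured vector autoregression of order 1. The
model assumes the panel is stationary (so two generic consecutive slices
suffice) and that each week depends on the previous week only. Because the
two slices are disjoint node sets, the graph is acyclic by construction,
yet *folding* the two copies of each condition into one node yields a cyclic
graph in which arc pairs `X -> Y` and `Y -> X` across slices become feedback
loops and self-arcs become autoloops — the representation a clinician reads.

Structure is learned by maximizing the penalized log-likelihood

    PL(D, w) = log L(D) - w * u(n) * p

over forward-only arc sets, where `p` counts parameters (per node: one
coefficient per parent, an intercept, a residual variance) and the penalty
unit is `u(n) = log(n) / 2`, so `w = 1` is exactly the Bayesian Information
Criterion. A `penalty_unit = "literal"` switch uses `u(n) = log(n)` instead,
matching the convention in which the penalty is written `w log(n) p`; the
BIC convention is the default because `w = 1` is described as the BIC
throughout, and only the scale of `w` differs between the two readings.
The score is decomposable — each node contributes an independent term — so
greedy hill climbing over single-arc additions and deletions (reversals
would point backward in time and are not moves) can be run per target
node; the result is identical to accepting the single best global move per
step, and ties are broken lexicographically by (target, source) so the
search is fully deterministic. For small systems `exhaustive_dag()`
enumerates every parent subset per node and provides the exact optimum as a
cross-check.

## Tunable parameters

* **`w` (sparsity penalty, dimensionless, default grid `1, 2, ..., 128`).**
  `tune_penalty()` learns a DBN per `w` on the weeks before `split_week`
  (default 52, one year of weekly data) and evaluates the average
  R-squared on the held-out weeks. The chosen `w` is the largest whose
  validation accuracy ratio against the `w = 1` model exceeds
  `ratio_floor` (default 0.999): the sparsest model that predicts
  essentially as well as the densest. The ratio rule is an explicit,
  reproducible stand-in for choosing the elbow of the accuracy-vs-penalty
  curve by eye.
* **Bootstrap averaging (`B = 500`, `fraction = 0.75`).** Structures are
  re-learned on `B` resamples drawn with replacement at 75% of the original
  row count, with the condition order randomised per resample so
  tie-breaking cannot systematically favour any arc. An arc's *strength* is
  its inclusion frequency across resamples. Resampling with replacement at
  reduced size is one of two defensible readings of an m-out-of-n
  bootstrap; `replace = FALSE` is available.
* **Significance threshold.** `estimate_threshold()` compares the empirical
  CDF of the strengths with the ideal configuration (noise arcs at 0,
  significant arcs at 1, CDF flat at the noise fraction `t`) and picks the
  `t` minimizing the L1 distance — the length-weighted median of the ECDF
  over [0, 1]. The threshold is then the strength order statistic at `t`.
  Because any cut inside a gap of the strength distribution selects the
  same arcs, the reported threshold is the midpoint between that order
  statistic and the next distinct strength; arcs strictly above it enter
  the consensus graph in decreasing strength order, discarding arcs that
  would close a directed cycle (impossible across slices, but the same
  routine serves the static-network comparison, where it does fire).
* **Imputation (`k = 4`, `min_observed = 5`).** Missing cells are filled by
  a two-sided exponentially weighted moving average: up to `k` observed
  neighbours per side, weight `2^(-distance)`, renormalized over available
  neighbours — so imputed values are convex combinations of observed ones
  and observed cells are never altered. Conditions with more than 30%
  missing data overall are dropped before imputation (strict inequality:
  exactly 30% is retained), and (county, condition) series with fewer than
  `min_observed = 5` observed points are declared unimputable and removed;
  the 5-point floor is a package choice, exposed as a parameter, since no
  canonical value exists.

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` draws a known two-slice structure: every condition
keeps a self-arc with coefficient in (0.4, 0.55), the requested number of
feedback pairs and one-way arcs get cross coefficients of magnitude 0.2-0.4
with random sign, and the whole coefficient matrix is rescaled (preserving
sparsity) until its spectral radius is below 0.92, so the implied VAR(1) is
comfortably stable. `simulate_panel()` adds time-constant state and county
random intercepts and discards a burn-in so series are approximately
stationary. The spatial standard deviations are calibrated from the
stationary within-county variance so that states contribute about 12% and
counties about 49% of total variance on average — the dependence profile
of weekly county-level health-search panels — and the self-coefficient
range is set so counties *plus* lag-1 autocorrelation land near 64%. The
baseline draws are rescaled to their exact target variance because ten
state-level draws are otherwise far too noisy to emulate a stated variance
fraction. Conditions get a positive mean level (`mean_level`, default six
total standard deviations above zero): normalized search frequencies of
retained conditions are bounded away from zero — rare conditions are
filtered out before analysis — and series hovering at zero would dominate
relative-error metrics through near-zero denominators. As a guard for
truths specified with low or zero levels, the simulator additionally
shifts the panel so at least 99.9% of values are nonnegative and clips the
rest at zero (the clipped fraction is recorded and stays below 0.1%),
which keeps the linear-Gaussian model exactly correct before clipping
rather than distorting it with a transform. Every analysis stage is
location-invariant, so the level affects only nonnegativity and
relative-error metrics.

The generator does **not** emulate: normalization artifacts of real search
data, pandemic-era shocks or other non-stationarity, heavy-tailed or
zero-inflated marginals, spatial adjacency (only membership matters), or
missingness that is informative about the values. Passing tests on this
generator therefore demonstrate that the estimation machinery recovers the
model class it assumes at realistic dependence levels — not that real
search panels satisfy those assumptions.

Default problem sizes are a desk-scale analogue of a national panel:
10 states x 20 counties x 100 weeks x 12 conditions (19,800 lagged rows),
with `B = 100` bootstrap resamples in the examples and tests; these sizes
were chosen so a full pipeline run completes in well under a minute while
leaving effect sizes detectable with wide margins.

## County baselines and structure learning

With county intercepts at roughly half the total variance, regressing a
condition on the previous week's slice does *not* fully absorb the
baseline through the self-arc: the baseline both attenuates cross-condition
coefficients (by roughly the within-county variance fraction) and leaks
genuine partial dependence onto non-parent arcs, because other conditions'
lagged values help separate a county's baseline from its transient state.
Those leaked arcs are real properties of the raw-data distribution — they
survive bootstrap averaging — but they are not part of the generating
structure. `center_counties()` removes each county's mean per condition
(the two-slice analogue of subtracting the mixed-model random intercepts),
after which structure recovery on the default generator is essentially
exact. The pipeline therefore centres by default
(`run_pipeline(center = TRUE)`); learning from raw values remains available
both for sensitivity analysis and because the static-network audit
deliberately works on raw data.

## Variance decomposition

`variance_decomposition()` fits, per condition, nested random intercepts
(state, county-within-state) by REML and reports each component's share of
total variance. The serial component is quantified as the *additional*
share explained when within-county residuals are regressed on their lag —
`phi^2` times the residual share — and reported as `county_ar1_prop =
county share + increment`, matching the convention of quoting counties
"together with autocorrelation". This sequential attribution was chosen
over a jointly refit AR(1) model because the combined figure is the
quantity of interest and the increment reading makes the three shares
directly comparable; boundary (zero-variance) REML fits are flagged rather
than truncated, since the constrained optimizer cannot go negative.

## Variance shares, generative inference, stratification

`parent_variance_shares()` attributes a node's explained variance to its
parents ANOVA-style. The self-parent enters first; the remaining parents'
contributions are incremental explained-variance gains averaged over all
orderings of the non-self parents (computed by subset enumeration), which
makes the attribution exactly order-invariant — a fixed-order sequential
decomposition would depend on an arbitrary parent order. Shares are
normalized over non-self parents because autocorrelation dominates every
local model numerically.

`simulate_from_dbn()` uses the fitted model generatively (t0 resampled from
the observed rows by default, or drawn from fitted marginal Gaussians), and
`stratified_share()` asks whether a same-week association between a focal
condition and a target is carried by a stratifying condition: it augments
the target's regression with the focal condition at `t1` — the only way to
operationalize a same-week association in a model class without
instantaneous arcs — and compares the focal share overall against shares
within the stratifier's simulated quartile strata (low = bottom quartile,
average = middle two, high = top). The stratifier itself is excluded from
the regressor set: stratification *is* the control for it, and in a
linear-Gaussian model additionally conditioning on it linearly would force
the focal share to essentially zero both overall and within every stratum,
leaving the stratified comparison nothing to detect. Quartiles come from
the simulated distribution by default, keeping the procedure fully
model-based (`quartile_source = "empirical"` is available).

## The static-network audit

To show what ignoring space-time structure does, `learn_static()` fits a
classical one-slice Gaussian network (hill climbing with additions,
deletions and reversals under an acyclicity check) on raw county-week rows
and on rows de-structured by `remove_spatiotemporal()` (random intercepts
subtracted; optional AR(1) pre-whitening, off by default since only the
intercept removal is unambiguous). `compare_coefficients()` reports how
many coefficients shrink by at least half and how many change sign after
de-structuring — over the intersection of the two arc sets by default,
with a union mode (absent coefficients treated as zero and excluded from
the sign comparison) reported separately. `classify_arcs()` grades every
static arc against the folded dynamic truth: `correct`,
`feedback_collapsed` (the truth is a feedback loop, which an acyclic graph
cannot hold), `reversed`, or `spurious`.

## Numerical choices and degenerate inputs

* Local scores are computed from one Gram matrix via Cholesky solves, so a
  hill climb costs almost nothing beyond a single `crossprod` of the data;
  a singular local design raises an error naming the offending node.
* Residual sums of squares are floored at `n * 1e-300` so noiseless data
  score finitely.
* The threshold estimator falls back to 0.5 with a warning when all
  strengths are identical (no separation exists).
* Injection at rate `r` removes exactly `round(r * N)` cells in single mode;
  in batch mode, runs of four consecutive weeks are placed non-adjacent so
  every injected maximal run has length exactly four, and placement stops
  when the target count is reached.
* Relative imputation error excludes cells whose true value is zero (the
  ratio is undefined) and reports their count separately.
* Zero-variance targets make R-squared undefined; they are reported as `NA`
  and excluded from averages.

## Known limitations

* Only order-1 dynamics: higher-order lags would multiply the node count
  and break the folded-graph reading.
* Linear-Gaussian local models: no discrete or hybrid nodes, no
  heteroscedasticity.
* Inference is forward simulation plus stratification; no do-calculus or
  counterfactual machinery.
* The causal reading of arcs inherits the usual assumptions — faithfulness,
  no latent confounders, representative sampling — none of which the
  package can verify from data.
* Kalman-filter imputation is supported only through the function-valued
  `method` interface of `impute_panel()`; the built-in imputers are EWMA
  and linear interpolation.

## A minimal run

```{r pipeline, eval = FALSE}
res <- run_pipeline(
  out_dir = "dbn-run",
  p = 12, n_feedback = 8, n_unidirectional = 10,
  n_states = 10, counties_per_state = 20, n_weeks = 100,
  seed = 1, B = 100
)
res$tuning$chosen_w
fold(res$consensus)
autoplot(res$folded)
```
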