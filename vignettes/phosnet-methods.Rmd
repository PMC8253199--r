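---
title: "Inferring phosphorus-regulation networks from short balanced panels: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data model

Mineral metabolism is governed by a web of mutually regulating factors —
serum phosphate, corrected calcium, PTH, FGF23, soluble α-Klotho,
1,25-dihydroxyvitamin D, bone alkaline phosphatase, and urinary phosphate
excretion. Under a dietary phosphate intervention these analytes can be
sampled repeatedly over a day in a small cohort, giving a *balanced panel*:
`N` subjects × `T` ordinal time points × `V` variables per diet condition,
with the typical scale being `N = 6`, `T = 9`, `V = 8` and three conditions
(regular, low, high phosphate load). phosnet infers, per condition, a
directed graph whose edge `x -> y` means "the history of `x` improves the
prediction of `y` beyond `y`'s own history" — Granger causality, a
statistical-predictive notion, never a claim of mechanism.

Design choices at the data layer:

* **Ordinal time.** Sampling clocks are uneven (e.g. 00:00, 04:00, 08:00,
  10:00, ...), but all lag-based panel estimators below assume integer
  lags. The container therefore maps declared times to `0..T-1` by sort
  order within condition and keeps the original labels as metadata only.
* **No imputation, ever.** At `N = 6`, `T = 9` an imputed cell is
  statistically invisible but can flip edges; the loader rejects
  unbalanced or missing data with the offending subject/time named.
* **Conditions are analyzed separately** — one network per diet arm,
  never pooled.
* **Baseline samples** (taken before the intervention day) are not part of
  the nine-point series and are excluded from the causal analysis.
* `T >= 4` and `N >= 2` are enforced at construction: below that no
  downstream test is defined.

## Stationarity screening

Granger regressions on nonstationary series produce spurious edges, so
every variable is first screened with a pooled panel unit-root test of the
Levin–Lin–Chu family. For subject `i`, the first difference and the lagged
level are each partialled on the ADF augmentation terms (lagged
differences) and the deterministic terms, and both residual series are
normalized by the subject's ADF residual standard error. The normalized
pairs are pooled into one no-intercept regression `e ~ v`, giving the
common autoregressive deviation `delta` (zero under the unit-root null)
and its t-statistic `t_delta`. Because the within-panel operations bias
`t_delta` to the left, the statistic is recentred and rescaled,

    t* = (t_delta - N * T_tilde * S_N * SE(delta) / sigma2_e * mu_star) / sigma_star,

where `S_N` is the mean over subjects of the ratio of the Bartlett
long-run standard deviation of the differences (truncation
`ceiling(3.21 * T^(1/3))`, capped at `T - 3`) to the ADF residual SD, and
`T_tilde` the effective per-subject length. Small (very negative) `t*`
rejects the unit root against the left tail of the standard normal.

**Where the adjustment moments come from.** Published moment tables for
this statistic start at effective lengths around 25; a nine-point panel is
far outside them, and interpolating a transcribed table invites errors. The
default (`moments = "simulated"`) therefore calibrates `mu_star` and
`sigma_star` at run time: at least 2000 null panels of exactly the same
`(N, T, lags, deterministic)` are simulated, the pair `(t_delta, a)` (with
`a` the replicate's adjustment factor) recorded, and the moments chosen so
that `t*` has mean 0 and SD 1 under the null — a location–scale match under
the identical formula used for the real data. Calibrations are cached per
dimension within a session and are deterministic given a seed. The
`moments = "tabulated"` mode uses the same calibration precomputed at high
replication (8000 replicates, `N = 50`) over a grid of effective lengths,
linearly interpolated; its very short trend-specification cells are
intrinsically unstable (almost no residual degrees of freedom) and are
retained for honesty, not recommended for use.

**Lag defaults and the power trade-off.** With `T < 15` there is no room
for augmentation and the default is `lags = 0` (the studied case). For
longer panels the default `floor(T^(1/3))` is conservative against serial
correlation in the differences, but superfluous augmentation lags cost
real power in pooled short panels; when the differenced process is known
to be serially uncorrelated, `lags = 0` is the correctly specified and
sharper choice. The test-suite power experiments are run at the lag order
matching their generating process for exactly this reason.

`ensure_stationary()` wraps the test in the decision the analysis needs:
test, difference within subject once if not rejected, retest, up to
`max_diff` rounds; all variables are finally truncated to a common grid so
the panel stays balanced, and the per-variable differencing orders are
returned as a log rather than silently applied. A variable that still
fails is flagged (warning by default, hard error on request). Whether any
real analyte requires differencing is an empirical question the log
answers per dataset; nothing is assumed.

## Pairwise panel Granger causality

For an ordered pair (cause `x`, effect `y`) the model is the pooled
fixed-effects Granger regression

    y_{i,t} = alpha_i + sum_{l=1..p} rho_l y_{i,t-l} + sum_{l=1..p} beta_l x_{i,t-l} + eps_{i,t},

estimated after the *within transformation* (subtracting subject means
over the estimation window), which absorbs the intercepts `alpha_i`. The
null of Granger non-causality is `beta_1 = ... = beta_p = 0`.

* **Lag order.** Default `p = 1`: with `T = 9` each subject contributes 8
  usable transitions and the half-windows only 4; `p >= 2` would leave the
  halves nearly degenerate. The order is configurable for longer panels.
* **Nickell bias and the half-panel jackknife.** The within estimator of
  dynamic-panel coefficients is biased at small `T` (the demeaning couples
  regressors and errors). The half-panel jackknife combines the full-window
  estimate with estimates from the first and last halves of the window,
  `theta_hpj = 2*theta_full - (theta_first + theta_second)/2`, removing the
  leading `O(1/T)` bias term. Each half re-estimates its own within
  transformation; with an odd effective length the middle period is
  dropped so the halves are balanced and disjoint.
* **Variance.** The default is a delete-one-subject jackknife (CR3-type
  cluster-robust) variance of the bias-corrected estimator itself: because
  demeaning is per subject, deleting a subject is an exact rank-downdate
  of the normal equations of all three window regressions, and the spread
  of the deleted-subject estimates (factor `(N-1)/N`) estimates the
  variance of the combination. A conventional one-window sandwich
  evaluated at the same point understates the combination's dispersion
  when `T` is as short as nine and makes the test over-reject; the
  cluster jackknife holds the nominal size in the package's Monte-Carlo
  suite at the study dimensions. The Wald statistic on the cross-lag
  block is referred to chi-square with `p` degrees of freedom.
* **Bootstrap mode.** With very few subjects the chi-square reference is
  itself questionable, so a percentile-t alternative is provided: subjects
  are resampled with replacement, the recentred bootstrap Wald statistics
  are compared with the observed one, and the p-value is the tail
  fraction. Deterministic given a seed.
* **Bivariate conditioning.** Each test conditions only on the effect's
  own lags — the *pairwise* design. A consequence worth stating plainly:
  the test detects indirect influence (x -> m -> y) as readily as direct
  influence, because the mediator is never conditioned on. Inferred edges
  are therefore "direct or mediated predictive influence", and the
  edge-recovery experiments in the test suite use ground truths without
  directed two-step paths so that they measure direct-edge detection
  rather than this intrinsic conflation. Multivariate conditioning is out
  of scope by design.

All statistics are invariant to rescaling any variable by a positive
constant, so measurement units never matter.

## From tests to a network

The `V*(V-1)` ordered-pair results (56 for the eight analytes) are
thresholded at `alpha` (default 0.05 per pair, matching the conventional
reporting rule; Benjamini–Hochberg correction is available behind a flag
and recorded in the output metadata — with 56 simultaneous tests the
reader should know which convention produced a graph). Each significant
pair contributes a nonnegative weight:

* `"wald"` (default): the Wald statistic — "the larger, the stronger";
* `"one_minus_p"`: `1 - p`;
* `"coef"`: the absolute bias-corrected first cross-lag coefficient.

Graph metrics are computed on the binary (thresholded) digraph:

* **degree centralities** divide in/out edge counts by `n - 1` (the
  possible counterpart nodes), so an 8-node network reports multiples of
  `1/7`;
* **betweenness** is directed unweighted shortest-path betweenness,
  normalized by `(n-1)(n-2)`; pairs with no connecting path contribute
  nothing. The normalization convention cannot be cross-checked against
  published per-study values without the underlying edge lists, so an
  unnormalized option is provided;
* **density** is the realized fraction of the `n(n-1)` possible directed
  edges, and equals the mean of either degree centrality — a useful
  internal consistency check that the report layer asserts.

Report tables round half away from zero to 2 decimals; everything
internal and serialized is full precision. `realize_degree_sequence()`
reconstructs a simple digraph from prescribed in/out degree sequences via
the standard maximum-flow bipartite construction, which is what lets the
package verify that published degree tables, edge counts and densities are
mutually consistent without access to raw data.

## The synthetic generator

Raw measurements behind the motivating study design are not public, so the
generator stands in for them. It draws balanced panels from a panel VAR
with subject fixed effects:

    y_t = alpha_i + sum_l t(A[,,l]) %*% y_{t-l} + eps_t,

with `alpha_i ~ N(0, diag(fixed_effect_sd^2))`, Gaussian innovations with
arbitrary SPD covariance, a burn-in (default 100 steps, enough to erase
transients at spectral radius up to 0.9), optional post-hoc integration of
flagged variables (cumulative sum), and optional affine marginal dressing.
The ground truth is defined by the coefficient support: edge `j -> k`
exists iff some lag's `|A[j,k,l]| > 0`, with strength `max_l |A[j,k,l]|`.
The constructor refuses non-stationary (companion spectral radius >= 1)
coefficient tensors.

It emulates: the study dimensions, subject-level heterogeneity (intercepts
only, matching the homogeneous-slope assumption of the pooled estimator),
Gaussian noise, known causal structure. It does **not** emulate circadian
forcing, non-Gaussian or heteroskedastic noise, heterogeneous dynamics
across subjects, or missing data — so a green validation suite says the
*estimators* behave as designed under the study geometry, not that real
hormone data satisfy the model.

The per-condition presets build their ground-truth graphs by realizing the
in/out degree sequences of the three diet conditions' reference centrality
profiles (degree centralities × 7), so the synthetic truth has the same
topology class as the reported networks (26, 27 and 13 edges). Cross
coefficients have magnitude 0.5 with deterministic alternating signs; if a
dense condition pushed the companion radius to 0.95 or beyond, the cross
block would be rescaled to radius 0.9 (the regular-diet graph sits at
~0.88, so in practice no rescaling occurs). Marginal scales are arbitrary
dressing — the analysis is scale-equivariant — and are documented as such.

Two Monte-Carlo design choices deserve their rationale:

* **Bias experiment.** The cross-lag coefficient of the within estimator
  is only biased when the demeaning couples the cause's lags with the
  effect's errors, i.e. when the effect feeds back into the cause. The
  experiment that demonstrates the jackknife's bias reduction therefore
  uses `beta(x -> y) = 0` with a strong reverse edge `y -> x`
  (coefficient 2.0) and own-lag 0.5 at `N = 20`, `T = 10`: strong enough
  feedback that the transmitted bias stands clearly above the Monte-Carlo
  noise of 500 replicates.
* **Edge-recovery truths.** Recovery is scored as edge-set F1 against
  direct edges. Because the pairwise test also fires on two-step paths
  (see above), the sparse ground truths are drawn chain-free (all edges
  from a source block to a sink block, 8 edges of magnitude 0.6 on 8
  variables); with unconstrained sparse truths the measured "false
  positives" are substantially detected mediation, which is a property of
  the pairwise design, not an estimation failure.

## Validation suite and problem sizes

The test suite recomputes, at full size, the operating characteristics the
package claims (sizes chosen as a balance between Monte-Carlo resolution
and a test run that stays pleasant on one core):

* Granger test size on null VARs, `N = 50`, `T = 9`, 500 replicates,
  acceptance band 0.03–0.08 at nominal 0.05;
* power > 0.9 against a single `beta = 0.8` edge, 200 replicates;
* mean absolute error of the jackknife-corrected cross-lag coefficient
  below the uncorrected one, 500 replicates;
* unit-root test size on random-walk panels, `N = 20`, `T = 50`,
  500 replicates, band 0.03–0.08, plus tabulated/simulated decision
  agreement;
* betweenness equal to an exhaustive shortest-path-counting oracle on 100
  random 8-node digraphs;
* repeated-measures correlation equal to an independent ANCOVA solve to
  10 significant digits on 200 random datasets;
* end-to-end edge recovery F1 >= 0.8 over 50 seeds (`N = 30`, `T = 9`).

The degree-sequence layer is verified exactly: realizing each diet
condition's published degree profile reproduces its reported density
(0.46 / 0.48 / 0.23 at 2 dp) and extreme centralities (0.71, 0.86, 0.57).

## Companion statistics

`rmcorr()` estimates the common within-subject linear association by the
ANCOVA model `y ~ subject + common slope * x`; after within-subject
centering it reduces to the Pearson correlation of the centered pairs with
`df = n_obs - N - 1`. It is invariant to per-subject shifts of either
variable and flips sign with either variable. Confidence intervals (an
optional Fisher-z form) are labelled approximate. `kruskal_wallis_bonferroni()`
wraps the standard tie-corrected Kruskal–Wallis test and follows it with
pairwise two-group rank tests whose p-values are multiplied by an
**explicit** family size: which family (per table? per analyte?) a
multiplicity correction should span is an analysis decision, so the
function defaults to the number of comparisons it actually makes and
echoes the value used rather than guessing silently.

## Numerical notes and degenerate inputs

Singular designs (a variable constant after demeaning, collinear lags) are
reported as errors naming the offending variable, and the pairwise sweep
collects per-pair failures instead of aborting. Constant series fail the
unit-root screen with the subject named. The Bartlett long-run variance is
floored at a tiny positive value. Ranking ties are reported as ties (the
hub report joins exactly tied top nodes). All file outputs serialize at
full double precision (`%.17g`), so write/read round trips are exact;
2-decimal rounding (half away from zero) exists only in report rendering.

## Limitations

Six subjects is very little information: at the study's own `N = 6` the
pairwise test has modest power, and the demonstration workflow on
synthetic data shows sparse recovered networks relative to their ground
truths at that scale (see `analysis/03_granger_networks.R` output). Edges
are predictive, possibly mediated, and conditioned on nothing beyond the
effect's own history; betweenness normalization and the per-pair
significance convention are reconstructions of standard practice where the
underlying reporting left them open; and the generator's Gaussian,
circadian-free world is a deliberately modest stand-in for hormone
physiology.
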