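---
title: "Cherry-picking vulnerability in meta-analyses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cherry-picking vulnerability in meta-analyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherrymeta)
```

## The problem

Evidence-based medicine leans heavily on meta-analyses: K independent
trials each report an effect estimate $y_i$ (here always on a pooling
scale such as the log odds ratio) and a within-study variance
$\sigma_i^2$, and these are combined into a single pooled estimate and
p-value. The selection of which studies enter the pool is governed by
inclusion/exclusion criteria — and in practice those criteria are often
not pre-registered. An analyst who chooses criteria *after* seeing the
study results can retain a subset $D_S$ of $S$ of the $K$ available
studies that delivers a desired conclusion. `cherrymeta` quantifies how
easy that is: it implements the standard pooling model, the adversarial
selection rule, closed-form conditions under which selection succeeds with
stated probability, and a Monte Carlo framework measuring how often
conclusions actually flip.

## Pooling model

Fixed-effect model: $y_i \sim N(\theta, \sigma_i^2)$ with known
$\sigma_i^2$ and weights $w_i = 1/\sigma_i^2$. The maximum-likelihood
pooled estimate is the weighted mean
$\hat\theta = \sum w_i y_i / \sum w_i$ with standard error
$(\sum w_i)^{-1/2}$ and CI
$\hat\theta \mp z_\alpha (\sum w_i)^{-1/2}$, $z_\alpha =
\Phi^{-1}(1-\alpha/2)$. Decisions use the one-sided right-tailed
$p_{meta} = \Phi(-\hat\theta \sqrt{\sum w_i})$ for $H_0: \theta = 0$
versus $H_1: \theta > 0$ (a beneficial treatment); left- and two-tailed
variants are exposed through the `sided` argument. Note the deliberate
asymmetry — the CI uses the two-sided quantile while the decision p-value
is one-sided; both are reported.

Random-effects model: $y_i \sim N(\theta, \sigma_i^2 + \tau^2)$ with
between-study variance $\tau^2$ estimated by the DerSimonian–Laird moment
estimator
$$\hat\tau^2 = \max\left\{0,\ \frac{Q - (S-1)}
 {\sum w_i^0 - \sum (w_i^0)^2 / \sum w_i^0}\right\},\qquad
 w_i^0 = 1/\sigma_i^2,$$
where $Q$ is Cochran's statistic around the fixed-effect mean. For a
single study the denominator is degenerate and $\hat\tau^2$ is defined as
0 with a warning: one study carries no between-study information. All
within-study variances are treated as known constants throughout — the
standard assumption, and the one that keeps the null distribution of
$p_{meta}$ exactly uniform.

Heterogeneity is summarised as $I^2 = \tau^2/(\tau^2 + s^2)$ with $s^2$ a
*typical* within-study variance (by default the mean of the
$\sigma_i^2$). This typical-variance form is what makes the simulation
grid interpretable: with $s^2 = 0.17$, the grid's $\tau^2 = 0.70$
corresponds to $I^2 \approx 80\%$ (considerable heterogeneity). The
Q-based sample estimate of $I^2$ is intentionally not implemented; the
two do not coincide and mixing them invites confusion.

## The selection rule

`cherry_pick()` ranks studies by their per-study one-sided p-value
$p_i = \Phi(-\sqrt{w_i}\, y_i)$ — not by $w_i y_i$, which would be scale
ambiguous — and keeps the top-$S$ smallest (`direction = "overstate"`,
forcing $p_{meta}(D_S) \le \alpha$) or largest
(`direction = "understate"`, forcing $p_{meta}(D_S) \ge \alpha$). Ties are
broken by input row order, which makes results invariant to row
permutation up to that documented rule.

For equal weights the greedy rule is provably optimal (the pooled z is
monotone in the selected sum of standardized effects at fixed $S$); for
unequal weights it need not be, so an exhaustive enumeration oracle
(`method = "exhaustive"`, refusing more than `budget` subsets, with
lexicographic label tie-break) is provided. The package reports both
rather than claiming greedy optimality in general; the test suite asserts
exact agreement under equal weights and exhaustive dominance otherwise.

One property worth spelling out because intuition fails: whether growing
the selection from $S$ to $S{+}1$ *helps* the overstater depends on the
picked fraction. With equal weights, adding the next-best standardized
effect $z_{new}$ to the selected sum $T_S$ lowers the pooled p iff
$z_{new} \ge T_S(\sqrt{(S+1)/S} - 1)$. At small $S/K$ the added study is
well above that threshold and larger selections are stronger; near
$S \approx K$ the added study often has $z_{new} < 0$ and dilutes the
selection. The tests assert this exact one-step law rather than a blanket
monotonicity.

### Between-study variance under selection

Under the random-effects model, $\hat\tau^2$ itself depends on which
studies are in hand, which is what `tau2_policy` controls:

* `"full_set"` (default): $\hat\tau^2$ is estimated once from all $K$
  studies and then held fixed while subsets are ranked and pooled. This
  keeps the weights — and hence the closed-form bounds below — valid for
  every subset, and mirrors an analyst who froze the heterogeneity
  estimate before trimming the study list.
* `"subset"`: $\hat\tau^2$ is re-estimated on each candidate subset
  (sensitivity mode). Greedy ranking, which happens before any subset
  exists, still uses the full-set estimate — the only one available at
  ranking time; the selected subset's pooled p then uses its own
  re-estimate. In exhaustive mode every enumerated subset re-estimates
  $\tau^2$, which is the expensive path.

A joint treatment in which the selection rule itself anticipates the
subset-dependence of $\hat\tau^2$ is out of scope.

## Vulnerability bounds

Write $\eta = w_{max}/w_{min}$ for the weight ratio of the studies in
play, $\delta$ for the failure-probability budget and $\epsilon$ for the
picking-fraction parameter. The package evaluates two closed-form
sufficient conditions (`pickable()`):

* **Overstatement** ($\theta = 0$, $\alpha \in (0,\tfrac12)$,
  $\epsilon \in (0,\tfrac13)$): if $S/K \le \epsilon$ and
  $$S \ \ge\ \max\left\{
    \frac{\eta\,\Phi^{-1}(\alpha)}{\Phi^{-1}(1/2 - \epsilon^2/2)},\
    \frac{\epsilon \log(1/\delta)}{2}
      \Big(\frac12 - \frac{3\epsilon^2}{2}\Big)^{-2}\right\},$$
  top-$S$ selection achieves $p_{meta}(D_S) \le \alpha$ with probability
  at least $1-\delta$. The first term grows with $\eta$ and diverges as
  $\epsilon \to 0^+$; the second is a concentration requirement on the
  number of favourable studies among $K \ge S/\epsilon$.
* **Understatement** ($\theta > 0$, $\epsilon \in (0,1)$): if
  $1-\epsilon \le S/K \le 1$ and
  $$\frac{\eta\,\Phi^{-1}(\alpha)}{\Phi^{-1}(1 - \epsilon^2/2)}
    \ \le\ S\ <\ \frac{(1-\epsilon)\log(1/\delta)}{2(1-\epsilon/2)^2} - 2,$$
  selection achieves $p_{meta}(D_S) \ge \alpha$ with probability at least
  $\delta$ — note the asymmetry: a chance of at least $\delta$, not
  $1-\delta$, which the report surfaces in its notes. The window may be
  empty (as $\delta \to 1^-$ the upper expression tends to $-2$); an
  empty window is reported, never raised as an error.

Two implementation decisions deserve comment. First, $\eta$ is formally a
property of the *selected* subset, which does not exist before selection;
the package computes it over all supplied studies by default — a
conservative upper bound on any subset's ratio — and `weight_ratio()` can
be re-applied to the selection post hoc. Second, the bounds are
real-valued while $S$ is an integer; the gates use
$S \ge \lceil s_{min} \rceil$ and
$\lceil s_{low} \rceil \le S < s_{high}$.

These are *sufficient* conditions with generous constants, so the
meaningful correctness check is behavioural: `guarantee_frequency()`
simulates ensembles at the stated $(S, K)$, applies the exact public
selection rule and measures the achieved frequency. The test suite runs
it at 300–1000 replicates for configurations flagged satisfied (for
example $\alpha = 0.05$, $\delta = 0.1$, $\epsilon = 0.1$, $\eta \in
\{1, 2\}$, giving $S = 132$ resp. $263$, $K = 10S$) and requires the
guaranteed frequency up to binomial slack
$2\sqrt{\delta(1-\delta)/\text{reps}}$. This locks the implemented
expressions to their probabilistic meaning.

## The simulation design

`simulate_studies()` emulates a realistic ensemble of trials:
$\sigma_i^2 \sim 0.25\,\chi^2_1$ truncated to $(0.009, 0.600)$ — giving a
mean within-study variance of about 0.17 — and
$y_i \mid \sigma_i \sim N(\theta, \sigma_i^2 + \tau^2)$. Truncation is by
exact rejection sampling (acceptance rate
$P(0.036 < \chi^2_1 < 2.4) \approx 0.728$), never by clamping, which
would pile probability mass on the interval ends and shift the mean. Each
simulated study reports $\sigma_i^2$, not $\sigma_i^2 + \tau^2$: a real
trial does not know the between-study variance.

A `scenario()` is one grid cell: $S$ picked from
$K = \mathrm{round}(S/\text{ratio})$ (nearest integer, ties up — the
design never states how fractional $K$ resolves, so the choice is fixed
and documented here), true effect $\theta$ (0 = overstatement case,
$>0$ = understatement case), true $\tau^2$, $\alpha = 0.05$, analysis
model defaulting to fixed when $\tau^2 = 0$ and random otherwise with the
full-set $\tau^2$ policy. A *false conclusion* is
$p_{meta}(D_S) \le \alpha$ when $\theta = 0$ and
$p_{meta}(D_S) > \alpha$ when $\theta > 0$; the understatement count is
unconditional by default (a `conditional` flag restricts counting to
replicates where the full set was itself significant — the two differ
only when the full-set test lacks power). The default grid is
$S = 2{:}30$, ratio $\in \{1/3, 1/5, 1/10\}$,
$\theta \in \{0, 0.5, 1\}$, $\tau^2 \in \{0, 0.01, 0.1, 0.5, 0.7\}$.

Reproducibility: `run_grid()` derives each scenario's seed by hashing the
scenario parameters together with the master seed, so per-scenario results
are independent substreams, unchanged under permutation or subsetting of
the grid. `run_scenario()` and `guarantee_frequency()` save and restore
the caller's RNG state.

What the generator does *not* emulate: estimated (rather than known)
within-study variances and the resulting non-normal null, publication
bias, correlated studies, and effect scales where the normal model is
poor for small trials. Passing tests therefore demonstrate vulnerability
of the idealized pooling model, not a measurement of any particular
literature.

## Problem sizes and numerical choices

The routine test suite uses 10,000 replicates for distributional checks
(uniformity of the null p, CI coverage, type-I calibration without
selection, tolerance ±0.005 around 0.05), 200 replicates per cell for the
trend checks across $S$, $S/K$ and $\tau^2$ (binomial CI about ±0.07,
ample for trends that move by 0.3–1.0), 200 random instances for
greedy-vs-exhaustive agreement at $K \le 12$, and one million draws for
the truncated-variance mean (±0.005 band). Floating-point equality in
tests is exact or at $10^{-9}$ relative unless a worked example states a
looser printed tolerance. The exhaustive oracle's default budget is
$2 \times 10^5$ subsets.

## Data interfaces

Study CSVs carry `label`, `effect` and exactly one of `se`/`variance`
(comma separator, `.` decimal, mandatory header); ambiguous headers and
nonpositive variances are rejected with line numbers. 2×2 tables convert
to log odds-ratio studies with the 0.5-to-all-cells continuity correction
applied only to tables containing a zero cell. The
`benefit_positive` orientation negates the log OR so that protective
treatments (fewer deaths under treatment) satisfy $\theta > 0$, matching
the right-tailed testing convention; published clinical tables often
report the reciprocal convention, which is exactly why the flag exists.
`forest_table()` exports the tidy data behind a forest plot;
`plot()` on a fitted object draws a base-graphics version.

## Known limitations

* The bounds are conservative sufficient conditions; they certify the
  *possibility* of cherry-picking under the stated probability, and say
  nothing about whether a given published meta-analysis was manipulated.
* Greedy selection is the modelled mechanism; for strongly unequal
  weights the globally optimal subset can be better than greedy, so
  vulnerability is if anything understated.
* No REML or Paule–Mandel $\tau^2$, no Hartung–Knapp adjustment, no
  meta-regression, no publication-bias modelling; augmentation scenarios
  ($K < S$) are excluded.
* Within-study variances are treated as known; with estimated variances
  the null of the pooled test is no longer exactly normal and both the
  calibration and the bounds would need asymptotic corrections.
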