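---
title: "Methods: the prediction-based global test for multiple endpoints"
author: "predtest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prediction-based global test for multiple endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predtest)
```

## The testing problem

Early-stage biomedical studies often measure many endpoints with no single
primary outcome, small samples, and substantial correlation among the
measures (the motivating case: arterial spin labeling, a cerebral blood
flow proxy, in six brain regions of 11 adults before and after an exercise
intervention). Per-endpoint testing with multiplicity correction wastes
power; classical global tests (Hotelling's $T^2$, O'Brien's OLS/GLS) either
need $n > m$ or presume a common effect direction.

The test implemented here instead treats the researcher's *a priori*
directional predictions as the object of inference. Let $\phi$ be the
probability that the researcher correctly predicts the direction of an
endpoint's observed effect. The hypotheses are

$$H_0: \phi \le \phi_0 \quad \text{vs.} \quad H_1: \phi > \phi_0,$$

so a rejection says the researcher's theory predicts the system better
than the reference ability $\phi_0$ (usually 0.5, chance). Predictions may
point in different directions on different endpoints, which is what lets
the test accumulate evidence across, say, measures expected to increase
and measures expected to decrease.

## Statistic, weights, and the null distribution

With $m$ endpoints, prediction outcomes $p_i \in \{0, 1\}$ (1 = the
observed sample effect fell on the predicted side) and the sample
correlation matrix $\hat{C} = (r_{ij})$ of the endpoints, each endpoint
receives the weight

$$w_i = \Big(\sum_{j=1}^{m} r_{ij}^2\Big)^{-1}, \qquad
  \tfrac{1}{m} \le w_i \le 1,$$

the diagonal term $r_{ii}^2 = 1$ included (that inclusion is what pins the
limits: $w_i = 1$ for an endpoint uncorrelated with all others, $1/m$
under perfect association). The sum $W = \sum_i w_i \in [1, m]$ acts as
the effective number of quasi-independent endpoints. The statistic

$$T_m = \sum_{i=1}^{m} p_i\, w_i \in [0, W]$$

is the number of effective endpoints correctly predicted; correctly
predicting near-duplicates of other endpoints earns little.

Under $H_0$ (taking the weights as fixed and outcomes independent
Bernoulli($\phi_0$)), every outcome vector $p$ has probability
$\phi_0^{\sum p_i}(1-\phi_0)^{m-\sum p_i}$, so the null distribution of
$T_m$ is exactly enumerable; its mean and variance are $\phi_0 W$ and
$\phi_0(1-\phi_0)\sum_i w_i^2$. `exact_null_distribution()` builds the
full pmf by iterative convolution over endpoints — mathematically the same
$2^m$ enumeration, but values that coincide are merged as it goes. The
p-value is the inclusive upper tail $P(T \ge t_{\mathrm{obs}})$. Two
special cases are useful anchors: with $\hat{C} = I$ the statistic is
Binomial($m, \phi_0$); with all correlations $\pm 1$ it is a
Binomial($m,\phi_0$) count scaled by $1/m$.

### Numerical choices

* **Tie tolerance.** Sums of floating-point weights that differ by less
  than $10^{-9}$ (absolute) are treated as the same statistic value, both
  when merging the support and when counting "as or more extreme". Weights
  are $O(1)$, so this is far above rounding noise and far below any
  genuine gap.
* **Enumeration cap.** The full pmf is refused beyond $m = 25$
  ($2^{25} \approx 3.4\times10^7$ atoms). Simulation loops never build the
  pmf at all: a meet-in-the-middle split evaluates a single tail
  probability in $O(2^{m/2})$, and the test suite asserts exact agreement
  between the two routes.
* **Method switch.** `method = "auto"` uses the exact tail for
  $m \le 20$ and the normal approximation above; the threshold is exposed
  (`exact_limit`) because the literature uses both $m < 20$ and
  $m \le 20$ conventions.
* **Zero effects.** An exactly zero observed effect estimate scores the
  prediction as incorrect — the conservative resolution of a tie the
  theory leaves open.

### Normal approximation

For large $m$, $T_m \approx N(\phi_0 W,\ \phi_0(1-\phi_0)\sum w_i^2)$. No
continuity correction is applied: the support is an irregular set of
weight sums, so no half-width is well defined. The approximation is
poorest when $\phi_0$ nears 0 or 1 at small $m$; `gmae_study()` quantifies
the error (below).

### Decision rule

Rejection requires $p \le \alpha$ **and**, by default, $T_m \ge 1$: at
least one effective endpoint must be correctly predicted. Under perfect
dependence ($W = 1$) the gate forces every single prediction to be
correct, so predicting monotone copies of one measure cannot win by
volume. The gate is a flag (`require_t_ge_1`). Because the null
distribution is discrete, some $(\phi_0, \alpha)$ pairs are infeasible
below a minimum $m$: `minimum_required_m()` returns the smallest $m$ with
$\phi_0^m \le \alpha$ (at that $m$ only a perfect record rejects) — 5, 6,
9, 14, 29 for $\phi_0 = 0.5, \ldots, 0.9$ at $\alpha = 0.05$. We recommend
$\phi_0 \ge 0.5$: lower values claim evidence from sub-chance prediction.

### Estimating the correlation matrix

Pearson correlation is the default (Spearman/Kendall are available via
`cor_method` for heavy-tailed or ordinal endpoints). For paired designs
the correlation of the within-subject differences is used, as in the
worked example. For two-group designs each group is de-meaned before
pooling, so a between-group mean shift cannot masquerade as endpoint
correlation and deflate the weights.

## O'Brien's OLS comparator

`ols_test()` implements the standard OLS global statistic
$T_{\mathrm{OLS}} = \sum_k t_k / \sqrt{\mathbf{1}^\top \hat{R}\,
\mathbf{1}}$, with $t_k$ the per-endpoint pooled-variance two-sample (or
paired one-sample) t statistics and $\hat{R}$ the same correlation matrix
used for the weights. The literature offers no single finite-sample
reference; we use a one-sided $t$ reference with $N - 2$ (two-group) or
$n - 1$ (paired) degrees of freedom and expose `df`, since all published
small-sample approximations are imperfect. Pooled-variance t statistics
match the equal-variance multivariate normal simulation design. The test
is scale- and shift-invariant per endpoint, powerful for equidirectional
common-size effects, and near-level against balanced bidirectional ones —
the behaviour the power study exhibits.

## Random correlation matrices and synthetic data

`random_correlation()` draws from the C-vine construction: layer-$k$
partial correlations are sampled from a symmetric Beta distribution
rescaled to $(-1,1)$ whose shape parameter decreases by $1/2$ per layer,
then composed recursively into full correlations. With `alphad = 1` the
resulting matrix is uniform over the space of positive-definite
correlation matrices — the regime all simulation defaults use. In
dimension 2 this makes the single correlation uniform on $(-1,1)$, which
the suite verifies by a Kolmogorov–Smirnov test; positive definiteness is
guaranteed by construction.

`make_dataset()` draws multivariate normal samples with unit variances,
so effect vectors $\delta$ are in SD units. Stock scenarios: constant
$\delta$, balanced bidirectional $\pm\delta$, a linear "stagger"
($0.5k/m$ for endpoint $k$, with the bidirectional variant negating the
smaller half), and a "spike" (one endpoint at 1 SD, the rest at 0.1).

What the generator deliberately does **not** emulate: non-normal
marginals, unequal variances (harmless for this test and for OLS, both
scale-invariant), structured correlation families (block, AR), missing
data, and endpoint-specific predictive ability. Passing simulation checks
therefore demonstrates correctness of the method under its own stated
sampling model, not robustness to real-data pathologies.

## The simulation studies

**Power and type-I error.** Each cell draws `n_matrices` random
correlation matrices and `n_reps` datasets per matrix. The simulated
researcher predicts each endpoint's true direction correctly with
probability $\phi$, independently per endpoint. Under the default
`scoring = "confirmed"`, an outcome scores 1 only when the prediction is
right about the truth *and* the observed sample mean difference falls on
that side. This was a genuinely open design point, and we chose
"confirmed" on a null-invariance argument: the alternative
(`scoring = "observed"`, crediting any agreement between predicted and
observed signs) makes the null outcome probability exactly $\phi_0$
regardless of effect size — a wrong prediction gets credited precisely
when sampling error flips the observed sign — so the type-I error would
sit at the nominal level in every cell and could never show the
conservativeness that small effects actually induce: with small
$\delta\sqrt{n/2}$ a correct prediction is frequently spoiled by a
wrong-side sample mean, pushing the rejection rate toward zero. The
"observed" variant remains available for studying the test's behaviour
when the researcher's ability is defined against observed rather than
true directions.

Weights always come from the *sample* correlation matrix of the simulated
data, as they would in practice. Monte-Carlo standard errors are reported
with the binomial formula over total replicates; because matrices are the
sampling unit, comparisons in the test suite combine this with the
cluster-level (between-matrix) standard error.

**Sensitivity.** Following the published protocol, each replicate draws a
true matrix, an $n$-observation MVN sample for the sample correlation,
and a Bernoulli($\phi$) outcome vector, then asks whether true-weight and
sample-weight decisions agree. At $n = 20$, $\phi_0 = 0.5$, over
$\phi \in \{0.3,\ldots,0.9\}$ and $m \in \{10,\ldots,40\}$, agreement
averages about 98%.

**GMAE.** For each $(m, \phi_0)$, each correlation matrix contributes the
mean absolute difference between a reference CDF and the normal CDF over
1000 sampled statistics; the grand mean averages over matrices. The
default reference is the empirical CDF of those same sampled statistics —
the construction that scales to $m = 70$ — which carries an irreducible
Monte-Carlo floor of roughly $0.25/\sqrt{1000} \approx 0.008$; this floor
is part of why the reported error settles near 0.01 at $\phi_0 = 0.5$
while still falling visibly with $m$ near the boundary
($\phi_0 = 0.9$). `reference = "exact"` swaps in the enumerated CDF for
$m \le 25$ and shows the true approximation error at $\phi_0 = 0.5$ is
closer to 0.005 by $m = 20$.

**Scale.** Defaults are sized for interactive use and continuous testing:
20 matrices × 100 replicates per power/type-I cell (the published studies
used 50 × 100), 100–500 replicates per sensitivity cell (published: not
stated per cell), 20–30 matrices × 1000 prediction sets per GMAE cell
(published: 100 × 1000). All entry points take explicit counts and a
seed, so full-scale reruns are one argument away; the acceptance script
spreads its ~2000 replicates per cell over 200 matrices to keep the
between-matrix error component small.

## Worked example

```{r asl}
ex <- asl_example()
res <- prediction_test(weights = ex$weights, outcomes = ex$outcomes,
                       phi0 = 0.5, alpha = 0.05)
res
```

Four of six regional increases were correctly predicted, but the two
misses include the highest-weight region (hippocampus, $w = 0.68$), and
$T_m = 1.74$ effective endpoints out of $W$ falls well inside the null
range. Note the published summary rounds its weights; enumerating the
null over these rounded weights gives $p = 19/64 \approx 0.297$, slightly
different from the published $0.3125$ computed from unrounded weights.
The raw subject-level data are not deposited, so the statistic — not the
p-value — is the reproducible anchor.

## Known limitations

* Weights are treated as fixed although they are estimated; at very small
  $n$ the pairwise correlations (hence weights) are unstable. The
  sensitivity study bounds the practical consequence (~2% of decisions
  flip at $n = 20$), but a formal account of weight uncertainty is absent.
* Predictions are strictly one-sided per endpoint; "change / no-change"
  predictions and endpoint-specific $\phi_i$ (a weighted Poisson-binomial
  null) are out of scope.
* The exact method is capped at $m = 25$; beyond that the normal
  approximation (or a Monte-Carlo tail) must serve, and its quality
  degrades as $\phi_0$ approaches 0 or 1.
* The O'Brien comparator's finite-sample reference is an approximation;
  it is known to be anti-conservative for very small $n$, which the
  simulations reproduce rather than correct.
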