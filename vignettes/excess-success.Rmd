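---
title: "Detecting excess success in sets of experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting excess success in sets of experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tes)
```

## The idea

An article that reports several experiments, every one of which "worked",
is making an implicit statistical claim: that a set of studies with these
effect sizes and these sample sizes can plausibly succeed every time.
That claim can be checked. Treating each experiment's observed effect as
the true population value, the probability that an exact replication
would reproduce the reported pattern of significant and non-significant
outcomes can be estimated from the reported summary statistics alone.
If the experiments are independent, the probability that *all* of them
succeed is the product of the per-experiment probabilities,

$$P_{TES} \;=\; \prod_{i=1}^{k} P_i ,$$

where $P_i$ is experiment $i$'s joint success probability. Typical
psychology experiments have estimated power in the 0.5–0.8 range, so a
handful of uniformly successful experiments often yields a product below
0.1 — the conventional criterion below which the set is flagged as "too
good to be true". A small $P_{TES}$ does not show that any single result
is wrong; it shows that *something* — unreported null results,
data-dependent analysis, optional stopping — has biased the set as a
whole.

"Success" is defined by the original authors' own theoretical claims:
some tests must be significant, others (e.g. a predicted null between two
experimental conditions) must be non-significant, sometimes at a relaxed
criterion. The success criterion of an experiment is therefore a
*conjunction* of required outcomes, and the probability of satisfying all
of them simultaneously is usually well below the power of any single
test.

## Estimation routes

Each experiment declares one of three estimation methods.

**Analytic.** For a single-test criterion the success probability is a
closed-form power: noncentral *t* for two-sample comparisons, noncentral
*F* for the one-way omnibus ANOVA and for contrasts, and the Fisher
*z*-transform normal approximation for tests of zero correlation
(`power_correlation()`, the standard implementation in power software).
A required-nonsignificant outcome contributes the complement of power.

**Monte Carlo.** When the criterion couples several tests computed on
the same data (an omnibus ANOVA plus contrasts, two correlated dependent
measures, an interaction plus simple effects), the joint probability has
no closed form. `estimate_joint_success()` draws replications from the
experiment's population model — independent multivariate-normal
participants with the reported means, SDs, and within-participant
correlations — evaluates the full test battery on each replication, and
reports the proportion in which every required outcome held, with its
binomial standard error. The default is 100,000 replications, giving a
standard error of about 0.0016 on probabilities near one half.

**Minimum upper bound.** When required outcomes are correlated but the
correlation structure is not recoverable from the reported summaries
(e.g. three correlations of different predictors with the same dependent
variable), the joint probability cannot be estimated — but it cannot
exceed any single component, so the smallest component power is used as
an upper bound (`joint_upper_bound()`). This is deliberately
conservative: it always favors the article under scrutiny.

## Statistical conventions

Three conventions matter, and each is a deliberate design choice.

**Contrasts within multi-group designs use the omnibus error term.**
A follow-up comparison of two cells inside a $k$-group or 2×2 design is
tested against the mean squared error pooled across *all* cells, with
$N - k$ error degrees of freedom (`cell_contrast` family,
`power_cell_contrast()`). This is the textbook ANOVA follow-up
procedure; the alternative (pooling only the two cells involved) gives
powers a few thousandths lower. A standalone two-sample experiment uses
the ordinary pooled two-sample *t* (`two_sample_t` family).

**Standardized effects taken from summary statistics are
bias-corrected.** The observed standardized mean difference
$d = (\bar x_1 - \bar x_2)/s$ overestimates the population value in
small samples; before a $d$ — whether computed from reported means and
SDs or recovered from a reported $F$ value via
$d = \sqrt{F(n_1+n_2)/(n_1 n_2)}$ — is treated as the true replication
effect, it is shrunk by Hedges' factor $J = 1 - 3/(4\,\mathrm{df} - 1)$
(`effect_scale = "hedges"`, the default for `from_f` derivations).
Experiments simulated directly from reported group means and SDs use
those values as-is: no standardization step occurs, so no correction
applies.

**Interpreting observed statistics as population parameters.** The whole
procedure is a post hoc power argument: the reported sample statistics
are taken as the generating truth for hypothetical replications. Post
hoc power is a poor estimate of the probability of an outcome *already
observed*, but here it is used prospectively, as the estimated success
probability of a fresh replication — the purpose for which it is valid.

## The five-experiment demonstration set

`table1_fixture()` ships a set of five experiments (from five unrelated
articles, brought together purely for illustration) that exercises every
route: three correlated correlation tests combined by the minimum bound;
a three-group ANOVA with two required significant contrasts and one
required null; a single *t*-test judged at the original authors' relaxed
0.1 criterion; two correlated dependent measures whose effects are
recoverable only from $F$ values; and a 2×2 interaction with simple
effects, whose common SD is recovered from the reported interaction $F$
(`sd_from_F()`) because the reported SDs were inconsistent with it.

```{r, eval = FALSE}
res <- run_analysis(table1_fixture(), seed = 1)
res$p_tes    # about 0.018
res$flagged  # TRUE
```

Each experiment alone has a joint success probability between about 0.32
and 0.52 — unremarkable — yet the probability that all five succeed is
about 0.018. Had these experiments appeared in one article supporting
one theory, the uniform success would itself be evidence of bias.
`table2_fixture()` ships the published set-level probabilities for
eighteen articles analyzed this way; fifteen fall below the 0.1
criterion.

One number in the demonstration set deserves a note: the single-*t*
experiment's published success probability (0.517) is not exactly
recoverable from its printed means and SD — it corresponds to the source
article's reported *t* statistic, which is rounded inconsistently with
the printed means. From the printed statistics this package obtains
0.524 with the bias-correction convention above (0.540 without), leaving
the set-level product unchanged to two decimals.

## Effect-size intervals

`effect_estimate()` reports Hedges' $g$ with a confidence interval built
by inverting the noncentral *t* distribution: the noncentrality
parameters whose tail probabilities at the observed *t* each equal
$(1-\text{level})/2$ are found by bisection (tolerance $10^{-8}$, with a
geometrically expanded bracket) and mapped back to the effect scale. The
interval endpoints are scaled by $J$ to match the $g$ point estimate; it
degenerates to the normal-theory interval as the degrees of freedom grow.
For typical sample sizes in this literature ($n \approx 20$ per group)
the 95% interval spans roughly $\pm 0.65$ around the estimate — wide
enough that theories tuned to the point estimates largely fit noise,
which is the other face of the excess-success problem.

## Operating characteristics

The meta-simulation layer measures the behavior of the excess-success
test itself on synthetic literatures. All scenarios use two-sample
designs with unit SD — the simplest design that reproduces every
qualitative property of interest — and compute within-replicate success
probabilities analytically from the observed (bias-corrected) effects,
which is exact for single-test criteria and avoids nested Monte Carlo.

**Unbiased reporting** (`simulate_unbiased_tes()`): sets of $k$ proper
experiments are simulated, and the test is applied only to sets that are
uniformly significant (the condition under which it would be applied in
practice). Conditioning on all-significant outcomes selects sets with
large observed effects, hence large estimated powers and large products:
the realized rate of false bias accusations stays well below the nominal
0.1 criterion — typically near 0.01 across the default grid (tested at
$k \in \{2, 4\}$, $d \in \{0.5, 0.8\}$, $n = 50$, defaults chosen as
ordinary values for a moderately powered literature).

**File-drawer censoring** (`simulate_file_drawer()`): each set runs
several proper experiments but publishes only the significant ones.
Selection inflates the published effect sizes, which inflates the
estimated success probabilities, so the censored sets largely evade the
flag. This is the test's documented blind spot: a high flag rate in a
real literature therefore suggests more than a file drawer.

**Optional stopping** (`simulate_optional_stopping()`): experiments
re-test after every increment of data (default: first look at $n = 20$
per group, steps of 10, ceiling 100, the conventional depiction of
"adding participants until it works") and stop at the first $p \le
\alpha$. At $d = 0$ the realized Type I error is roughly triple the
nominal rate under the defaults, and the stopped p-values pile up just
below the criterion — the signature that motivates scrutiny of articles
whose p-values cluster just under 0.05.

## Numerical choices and degenerate inputs

* Seeding: every stochastic routine takes an explicit seed and restores
  the caller's RNG state. `run_analysis()` derives an independent
  sub-seed per experiment from (master seed, experiment label), so
  results are invariant to experiment order; estimates are bit-for-bit
  reproducible given (config, seed).
* The Monte Carlo engine simulates per-group sufficient statistics
  (means and within-group sums of squares) in vectorized chunks of
  20,000 replications; every supported test family depends on the data
  only through those statistics, and the single-dataset path
  (`evaluate_tests()`) is checked against `t.test()`/`aov()` to 1e-10.
* Zero effects give rejection probability exactly $\alpha$ (noncentral
  distributions at zero noncentrality); powers are monotone in effect
  magnitude, sample size, and $\alpha$.
* `sd_from_F()` raises an error for a zero contrast (no SD can reproduce
  a positive $F$); `validate_experiment_set()` rejects $\alpha \notin
  (0,1)$, dangling group references, empty success criteria, and
  non-positive-semidefinite correlation matrices. Sets with fewer than
  four experiments are accepted with a warning: below four experiments
  the product rarely drops below 0.1, so the test has little power, but
  the arithmetic is well defined.
* `method = "analytic"` is refused for multi-test criteria, which would
  require an independence assumption the data rarely justify; such
  experiments must declare `monte_carlo` or `min_bound`.

## What the simulations do and do not show

The population model behind both the per-experiment simulations and the
meta-simulations is normal, homoscedastic, and independent across
participants — the same assumptions as the original test statistics.
Passing tests therefore validate the probability machinery, not the
robustness of any substantive conclusion to non-normality, unequal
variances, clustered sampling, or dependence between experiments (the
product rule treats experiments as independent, exactly as the original
procedure does). Success probabilities are estimates built on observed
effects, which are themselves noisy; the minimum-bound and
bias-correction conventions push the estimate in the conservative
direction, but a set-level probability is an upper-bound-flavored
estimate, not an exact p-value.

## Problem sizes used in the test suite

Published-value reproductions run at the same 100,000 replications as
the original analyses. Property checks (analytic-vs-simulation
agreement, conservativeness grids, stopping simulations, interval
coverage at 2,000 simulated datasets) use 1,000–50,000 replications per
point — enough that the Monte Carlo error bands in the assertions are a
few thousandths wide — and fixed seeds throughout.
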