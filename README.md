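# tes — Test for Excess Success in sets of experiments

When an article reports four, five, six experiments and every single one
"worked", the uniformity of that success is itself a checkable claim.
`tes` estimates, from the reported summary statistics alone, the
probability that exact replications would reproduce each experiment's
pattern of significant and non-significant outcomes, multiplies the
per-experiment probabilities into a set-level joint probability

P_TES = Π<sub>i</sub> P<sub>i</sub>,

and flags the set when P_TES falls below a conventional criterion
(default 0.1): success this uniform is improbable for unbiased,
fully-reported experiments, suggesting suppressed null results,
data-dependent analysis, or theory fitted to noise. The package is aimed
at methodologists, meta-analysts, editors, and reviewers who want to
audit a body of experiments rather than a single p-value.

Per-experiment probabilities are estimated three ways, declared per
experiment:

* **analytic** — closed-form post hoc power: noncentral *t* for
  two-sample tests and cell contrasts, noncentral *F* for the one-way
  omnibus ANOVA, Fisher-*z* normal approximation for correlations;
  required-nonsignificant outcomes contribute `1 - power`;
* **monte_carlo** — for compound criteria (ANOVA + contrasts + a
  required null; correlated dependent measures; interaction + simple
  effects): 100,000 simulated replications from the reported means, SDs
  and correlations, scoring the proportion that satisfies every
  required outcome jointly;
* **min_bound** — for correlated outcomes that cannot be simulated from
  summaries: the smallest component power, an upper bound that favors
  the article.

Also included: Hedges' *g* with noncentral-*t* confidence intervals
(`effect_estimate()`), and meta-simulations of the test's own operating
characteristics under unbiased reporting, file-drawer censoring, and
optional stopping (`simulate_unbiased_tes()`, `simulate_file_drawer()`,
`simulate_optional_stopping()`).

## Worked example

Experiment sets are declared in YAML (one file = one article; schema in
`?read_experiment_set`, full example in
`inst/extdata/five_experiments.yaml`). The shipped demonstration set
holds five experiments from five unrelated articles:

```r
library(tes)
res <- run_analysis(table1_fixture(), seed = 1)
print(res)
#> Excess-success analysis
#>   Exp 1      rho1            0.843
#>   Exp 1      rho2            0.518
#>   Exp 1      rho3            0.675
#>   Exp 1      joint           0.518  [min_bound]
#>   Exp 2      omnibus         0.688
#>   Exp 2      c13             0.700
#>   Exp 2      c23             0.624
#>   Exp 2      c12             0.945
#>   Exp 2      joint           0.488  [monte_carlo]
#>   Exp 3      joint           0.524  [analytic]
#>   Exp 4      x               0.496
#>   Exp 4      y               0.528
#>   Exp 4      joint           0.317  [monte_carlo]
#>   Exp 5      interaction     0.916
#>   Exp 5      simple_a        0.630
#>   Exp 5      simple_b        0.681
#>   Exp 5      joint           0.434  [monte_carlo]
#> P_TES = 0.018 (criterion 0.10): excess success indicated
```

Reading the output: each experiment's `joint` line is the estimated
probability that a replication reproduces *all* of that experiment's
required outcomes (e.g. Exp 2 needs a significant ANOVA, two significant
contrasts, *and* a non-significant difference between its two
experimental conditions — individually likely outcomes whose conjunction
has probability only ≈ 0.49). No single experiment looks suspicious;
the probability that all five succeed is ≈ 0.018, far below 0.1, so
uniform success across such a set would be strong evidence of a biased
experiment set. `table2_fixture()` carries published set-level
probabilities for 18 audited articles; 15 fall below 0.1.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/tes.R analyze inst/extdata/five_experiments.yaml --seed 1 --out report.json
Rscript inst/cli/tes.R effects inst/extdata/five_experiments.yaml
Rscript inst/cli/tes.R oc --scenario stopping --d 0 --reps 5000 --seed 2
```

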