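Package: tes
Title: Test for Excess Success in Sets of Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects implausibly uniform success across the experiments of a
    single article. Each experiment's probability of reproducing its reported
    pattern of significant and non-significant outcomes is estimated from the
    reported summary statistics (post hoc power via noncentral t, F and
    Fisher-z calculations, or Monte Carlo simulation for compound criteria);
    the per-experiment probabilities are multiplied into a joint probability
    for the whole set, which is flagged when it falls below a conventional
    criterion. Also provides standardized effect sizes (Hedges' g) with
    noncentral-t confidence intervals, and meta-simulations of the test's own
    operating characteristics under unbiased reporting, file-drawer censoring,
    and optional stopping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
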