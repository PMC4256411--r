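## Shipped reference fixtures. Both are stored as plain-text config/data
## files under inst/extdata and parsed through the ordinary readers, so
## the files double as worked examples of the config schema.

#' Five-experiment demonstration set
#'
#' The demonstration set of five experiments (drawn from five different
#' articles and artificially brought together) that exercises every
#' estimation route: post hoc correlation powers combined by the
#' minimum-upper-bound rule, Monte Carlo simulation of an ANOVA plus
#' contrasts with a required null result, a single t-test judged at a
#' relaxed 0.1 criterion, correlated bivariate outcomes with effects
#' derived from F values, and a 2x2 interaction with the common SD
#' recovered from the reported F.
#'
#' @return A validated `tes_experiment_set` of five experiments.
#' @seealso [run_analysis()] for the full excess-success analysis of
#'   this set.
#' @export
table1_fixture <- function() {
  read_experiment_set(system.file("extdata", "five_experiments.yaml",
                                  package = "tes", mustWork = TRUE))
}

#' Published excess-success probabilities for 18 psychology articles
#'
#' The joint success probabilities (P_TES) reported for the eighteen
#' psychology/education articles from a single prominent journal
#' (2005-2012) that contained four or more experiments and sufficient
#' statistical detail for analysis. Fifteen of the eighteen fall below
#' the conventional 0.1 excess-success criterion.
#'
#' @return A data frame with columns `year`, `authors`, `short_title`,
#'   `p_tes` (18 rows).
#' @export
table2_fixture <- function() {
  utils::read.csv(
    system.file("extdata", "science_psychology_ptes.csv",
                package = "tes", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}
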