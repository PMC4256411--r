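## Combining per-experiment joint success probabilities into the
## set-level excess-success statistic and decision.

#' Construct a success-probability estimate
#'
#' @param value Probability in \[0, 1\].
#' @param se Monte Carlo standard error (0 for analytic estimates).
#' @param method `"analytic"`, `"monte_carlo"`, or `"min_bound"`.
#' @param components Optional named vector of per-test probabilities.
#' @param reps Replicate count behind a Monte Carlo estimate.
#' @return A `tes_success` object.
#' @export
success_estimate <- function(value, se = 0, method = "analytic",
                             components = NULL, reps = NULL) {
  if (value < 0 || value > 1) stopf("success probability must lie in [0, 1]")
  if (se < 0) stopf("standard error must be >= 0")
  structure(
    list(value = value, se = se, method = method,
         components = components, reps = reps),
    class = "tes_success"
  )
}

#' @export
print.tes_success <- function(x, ...) {
  cat(sprintf("Success probability: %.4f (%s%s)\n", x$value, x$method,
              if (x$se > 0) sprintf(", MC se %.4f", x$se) else ""))
  if (!is.null(x$components)) {
    cat("Components:\n")
    for (nm in names(x$components)) {
      cat(sprintf("  %-12s %.4f\n", nm, x$components[nm]))
    }
  }
  invisible(x)
}

#' Upper bound on a joint probability of correlated outcomes
#'
#' When the outcomes required by a success criterion are correlated and
#' cannot be jointly simulated from the reported summaries, the joint
#' probability still cannot exceed any single component, so the smallest
#' component probability is an estimated upper bound — the conservative
#' direction, favoring the article under scrutiny.
#'
#' @param components Non-empty vector of component probabilities in
#'   \[0, 1\], optionally named by test id.
#' @return A [success_estimate()] with `method = "min_bound"`.
#' @examples
#' joint_upper_bound(c(0.844, 0.518, 0.675))$value  # 0.518
#' @export
joint_upper_bound <- function(components) {
  if (length(components) == 0) stopf("need at least one component probability")
  if (any(components < 0 | components > 1)) {
    stopf("component probabilities must lie in [0, 1]")
  }
  success_estimate(
    value = min(components),
    se = 0,
    method = "min_bound",
    components = components
  )
}

#' Combine per-experiment joint probabilities into the set-level statistic
#'
#' The probability that every experiment in an unbiased set succeeds is
#' the product of the per-experiment joint success probabilities
#' (experiments are treated as independent). A product below the
#' criterion (conventionally 0.1) flags the set: uniform success this
#' improbable suggests selective reporting or flawed analysis.
#'
#' @param probabilities Numeric vector of per-experiment joint success
#'   probabilities (or a list of `tes_success` objects).
#' @param criterion Flagging threshold, default 0.1.
#' @param labels Optional experiment labels.
#' @return A `tes_result` with fields `experiments` (data frame of
#'   per-experiment values), `p_tes`, `criterion`, `flagged`.
#' @examples
#' compute_p_tes(c(0.518, 0.482, 0.517, 0.318, 0.438))$p_tes  # about 0.018
#' @export
compute_p_tes <- function(probabilities, criterion = 0.1, labels = NULL) {
  if (length(probabilities) == 0) stopf("need at least one probability")
  ests <- lapply(seq_along(probabilities), function(i) {
    p <- if (is.list(probabilities)) probabilities[[i]] else probabilities[[i]]
    if (inherits(p, "tes_success")) p else success_estimate(p)
  })
  vals <- vapply(ests, `[[`, 0, "value")
  if (is.null(labels)) {
    labels <- names(probabilities) %||% paste0("experiment_", seq_along(vals))
  }
  if (length(vals) < 4) {
    warning(sprintf(paste0(
      "P_TES computed from %d experiment(s); the excess-success test has ",
      "adequate power only for sets of four or more"), length(vals)),
      call. = FALSE)
  }
  p_tes <- prod(vals)
  structure(
    list(
      experiments = data.frame(
        label = labels,
        joint = vals,
        se = vapply(ests, `[[`, 0, "se"),
        method = vapply(ests, `[[`, "", "method"),
        stringsAsFactors = FALSE
      ),
      estimates = stats::setNames(ests, labels),
      p_tes = p_tes,
      criterion = criterion,
      flagged = p_tes < criterion
    ),
    class = "tes_result"
  )
}

#' Run the full excess-success analysis on an experiment set
#'
#' Dispatches each experiment to its estimation route — analytic power,
#' Monte Carlo simulation, or the minimum upper bound — and multiplies
#' the per-experiment joint success probabilities into the set-level
#' statistic. Each experiment draws its Monte Carlo stream from a
#' sub-seed keyed by (master seed, experiment label), so results do not
#' depend on the order in which experiments are listed.
#'
#' @param set A validated `tes_experiment_set`.
#' @param seed Master seed (default 1).
#' @param reps Optional override of every experiment's Monte Carlo
#'   replicate count (e.g. lowered for smoke tests).
#' @param criterion Flagging threshold for P_TES, default 0.1.
#' @return A `tes_result`; its `estimates` field holds each experiment's
#'   full [success_estimate()] including per-test components.
#' @examples
#' \donttest{
#' res <- run_analysis(table1_fixture(), seed = 1)
#' res$p_tes  # about 0.018
#' }
#' @export
run_analysis <- function(set, seed = 1, reps = NULL, criterion = 0.1) {
  stopifnot(inherits(set, "tes_experiment_set"))
  ests <- lapply(set$experiments, function(exp) {
    estimate_experiment_success(exp, seed = sub_seed(seed, exp$label),
                                reps = reps)
  })
  compute_p_tes(ests, criterion = criterion,
                labels = vapply(set$experiments, `[[`, "", "label"))
}

#' Estimate one experiment's joint success probability
#'
#' Routes the experiment to the estimation method it declares:
#' `"analytic"` (closed-form power of the single criterion test),
#' `"monte_carlo"` ([estimate_joint_success()]), or `"min_bound"`
#' (analytic per-test powers combined by [joint_upper_bound()]).
#'
#' @param experiment A `tes_experiment`.
#' @param seed Seed for Monte Carlo methods.
#' @param reps Optional Monte Carlo replicate override.
#' @return A [success_estimate()].
#' @export
estimate_experiment_success <- function(experiment, seed = 1, reps = NULL) {
  switch(experiment$method,
    monte_carlo = estimate_joint_success(experiment, reps = reps, seed = seed),
    min_bound = {
      comps <- vapply(experiment$tests[experiment$success_criterion],
                      analytic_test_success, 0, exp = experiment)
      joint_upper_bound(comps)
    },
    analytic = {
      tt <- experiment$tests[[experiment$success_criterion]]
      success_estimate(
        value = analytic_test_success(tt, experiment),
        method = "analytic",
        components = stats::setNames(analytic_test_success(tt, experiment), tt$id)
      )
    },
    stopf("unknown method '%s'", experiment$method)
  )
}

## Closed-form probability that one test meets its *required* outcome,
## under the experiment's population model.
analytic_test_success <- function(tt, exp) {
  pow <- analytic_test_power(tt, exp)
  if (tt$required == "significant") pow else prob_nonsignificant(pow)
}

## Closed-form rejection probability of one test under the population.
analytic_test_power <- function(tt, exp) {
  if (tt$family == "correlation_zero") {
    rho <- exp$correlations$r[[tt$groups[1]]]
    return(power_correlation(exp$correlations$n, rho, tt$alpha, tt$sides))
  }
  pop <- exp$model
  m <- measure_index(tt, pop)
  gi <- match(tt$groups, pop$labels)
  switch(tt$family,
    two_sample_t = {
      d <- (pop$means[gi[1], m] - pop$means[gi[2], m]) / pop$sigma[m]
      power_two_sample_t(pop$n[gi[1]], pop$n[gi[2]], d, tt$alpha, tt$sides)
    },
    cell_contrast = {
      d <- (pop$means[gi[1], m] - pop$means[gi[2], m]) / pop$sigma[m]
      power_cell_contrast(pop$n[gi[1]], pop$n[gi[2]], d,
                          df_error = sum(pop$n) - length(pop$n),
                          alpha = tt$alpha, sides = tt$sides)
    },
    oneway_anova_omnibus =
      power_oneway_anova(pop$n[gi], pop$means[gi, m], pop$sigma[m], tt$alpha),
    interaction_2x2 =
      power_interaction_2x2(pop$n[gi], pop$means[gi, m], pop$sigma[m],
                            tt$alpha, tt$sides),
    stopf("no analytic power for family '%s'", tt$family)
  )
}

#' @export
print.tes_result <- function(x, digits = 3, ...) {
  cat("Excess-success analysis\n")
  df <- x$experiments
  for (i in seq_len(nrow(df))) {
    est <- x$estimates[[i]]
    if (!is.null(est$components) && length(est$components) > 1) {
      for (nm in names(est$components)) {
        cat(sprintf("  %-10s %-12s %*.3f\n", df$label[i], nm, digits + 5,
                    est$components[[nm]]))
      }
    }
    cat(sprintf("  %-10s %-12s %*.3f  [%s]\n", df$label[i], "joint",
                digits + 5, round(df$joint[i], digits), df$method[i]))
  }
  cat(sprintf("P_TES = %.*f (criterion %.2f): %s\n", digits,
              round(x$p_tes, digits), x$criterion,
              if (x$flagged) "excess success indicated" else "no excess success"))
  invisible(x)
}
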