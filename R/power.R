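## Closed-form success probabilities for single hypothesis tests.
## These are the building blocks of every excess-success analysis: the
## observed effect is treated as the population value and the rejection
## probability of an exact replication is computed from the noncentral
## t / F (or Fisher-z normal) distribution.

#' Power of a test that a correlation is zero (Fisher-z approximation)
#'
#' Probability that a test of H0: rho = 0 rejects when the population
#' correlation equals `rho`, using the Fisher z-transform normal
#' approximation: `z = atanh(rho)` with standard error `1/sqrt(n - 3)`.
#' This is the method used by standard power software for correlations.
#'
#' @param n Sample size (number of paired observations), at least 4.
#' @param rho Assumed population correlation, `|rho| < 1`. Only the
#'   magnitude matters for two-sided tests.
#' @param alpha Significance criterion in (0, 1). Default 0.05.
#' @param sides `"two_sided"` (default) or `"one_sided"`. One-sided tests
#'   assume the effect lies in the predicted direction.
#' @return Rejection probability in \[0, 1\].
#' @examples
#' power_correlation(179, 0.22)  # about 0.844
#' @export
power_correlation <- function(n, rho, alpha = 0.05, sides = c("two_sided", "one_sided")) {
  sides <- match.arg(sides)
  if (n < 4) stopf("power_correlation requires n >= 4 (got %s)", n)
  if (abs(rho) >= 1) stopf("|rho| must be < 1 (got %s)", rho)
  check_alpha(alpha)
  z <- atanh(abs(rho)) * sqrt(n - 3)
  if (sides == "two_sided") {
    q <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(z - q) + stats::pnorm(-z - q)
  } else {
    stats::pnorm(z - stats::qnorm(1 - alpha))
  }
}

#' Power of a two-sample pooled-variance t-test
#'
#' Exact noncentral-t power with `df = n1 + n2 - 2` and noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))`.
#'
#' @param n1,n2 Group sizes, each at least 2.
#' @param d Standardized mean difference assumed for the population.
#' @param alpha Significance criterion in (0, 1).
#' @param sides `"two_sided"` (default) or `"one_sided"`.
#' @return Rejection probability in \[0, 1\].
#' @examples
#' power_two_sample_t(17, 18, (316 - 186) / 152)  # about 0.69
#' @export
power_two_sample_t <- function(n1, n2, d, alpha = 0.05, sides = c("two_sided", "one_sided")) {
  sides <- match.arg(sides)
  if (n1 < 2 || n2 < 2) stopf("group sizes must be >= 2 (got %s, %s)", n1, n2)
  check_alpha(alpha)
  noncentral_t_power(d * sqrt(n1 * n2 / (n1 + n2)), n1 + n2 - 2, alpha, sides)
}

#' Power of a two-cell contrast tested against a pooled (omnibus) error term
#'
#' Within multi-group designs, follow-up contrasts between two cells are
#' customarily tested against the mean squared error pooled across *all*
#' cells of the design, with `df_error = N - k`. The noncentrality is the
#' same as for the plain two-sample test; only the error degrees of
#' freedom differ.
#'
#' @param n1,n2 Sizes of the two cells being contrasted.
#' @param d Standardized mean difference between the two cells (in units
#'   of the common within-cell SD).
#' @param df_error Error degrees of freedom of the pooled variance
#'   estimate (total N minus number of cells).
#' @param alpha Significance criterion in (0, 1).
#' @param sides `"two_sided"` (default) or `"one_sided"`.
#' @return Rejection probability in \[0, 1\].
#' @export
power_cell_contrast <- function(n1, n2, d, df_error, alpha = 0.05,
                                sides = c("two_sided", "one_sided")) {
  sides <- match.arg(sides)
  if (n1 < 2 || n2 < 2) stopf("cell sizes must be >= 2 (got %s, %s)", n1, n2)
  if (df_error < 1) stopf("df_error must be >= 1 (got %s)", df_error)
  check_alpha(alpha)
  noncentral_t_power(d * sqrt(n1 * n2 / (n1 + n2)), df_error, alpha, sides)
}

#' Success probability of a required non-significant outcome
#'
#' When a theory predicts the *absence* of an effect, the experiment
#' "succeeds" by not rejecting; the success probability is the complement
#' of power.
#'
#' @param p Power of the test, in \[0, 1\].
#' @return `1 - p`.
#' @export
prob_nonsignificant <- function(p) {
  if (any(p < 0 | p > 1)) stopf("power must lie in [0, 1]")
  1 - p
}

#' Power of the one-way ANOVA omnibus F-test
#'
#' Noncentral-F power with `df1 = k - 1`, `df2 = N - k` and noncentrality
#' `lambda = sum(n_i * (mu_i - mu_bar)^2) / sigma^2`, where `mu_bar` is
#' the size-weighted grand mean.
#'
#' @param ns Vector of group sizes (k >= 2 groups).
#' @param mus Vector of group means, same length as `ns`.
#' @param sigma Common within-group standard deviation, > 0.
#' @param alpha Significance criterion in (0, 1).
#' @return Rejection probability in \[0, 1\].
#' @examples
#' power_oneway_anova(c(17, 17, 18), c(316, 305, 186), 152)  # about 0.685
#' @export
power_oneway_anova <- function(ns, mus, sigma, alpha = 0.05) {
  if (length(ns) < 2) stopf("need at least 2 groups")
  if (length(ns) != length(mus)) stopf("ns and mus must have equal length")
  if (sigma <= 0) stopf("sigma must be > 0")
  check_alpha(alpha)
  N <- sum(ns)
  k <- length(ns)
  mbar <- sum(ns * mus) / N
  lambda <- sum(ns * (mus - mbar)^2) / sigma^2
  q <- stats::qf(1 - alpha, k - 1, N - k)
  1 - stats::pf(q, k - 1, N - k, ncp = lambda)
}

#' Power of the interaction contrast in a 2x2 between-subjects design
#'
#' The interaction is the contrast `(mu1 - mu2) - (mu3 - mu4)` on the four
#' cell means (cells ordered so that the first and last pairs are the two
#' simple effects), tested with a t statistic against the error variance
#' pooled across all four cells (`df = N - 4`).
#'
#' @param ns Cell sizes, length 4.
#' @param mus Cell means, length 4, ordered `(1, 2, 3, 4)` so the
#'   interaction contrast is `(mu1 - mu2) - (mu3 - mu4)`.
#' @param sigma Common within-cell standard deviation, > 0.
#' @param alpha Significance criterion in (0, 1).
#' @param sides `"two_sided"` (default) or `"one_sided"`.
#' @return Rejection probability in \[0, 1\].
#' @examples
#' power_interaction_2x2(rep(17, 4), c(3.87, 7.00, 7.59, 4.28), 3.91)  # about 0.917
#' @export
power_interaction_2x2 <- function(ns, mus, sigma, alpha = 0.05,
                                  sides = c("two_sided", "one_sided")) {
  sides <- match.arg(sides)
  if (length(ns) != 4 || length(mus) != 4) stopf("a 2x2 design has exactly 4 cells")
  if (sigma <= 0) stopf("sigma must be > 0")
  check_alpha(alpha)
  w <- c(1, -1, -1, 1)
  L <- sum(w * mus)
  se <- sigma * sqrt(sum(w^2 / ns))
  noncentral_t_power(L / se, sum(ns) - 4, alpha, sides)
}

#' Standardized mean difference implied by a between-groups F value
#'
#' Inverts the identity `t^2 = F` for a two-group comparison reported only
#' as an F statistic with one numerator degree of freedom:
#' `d = sqrt(F * (n1 + n2) / (n1 * n2))`. The sign of the difference is
#' not recoverable; the positive magnitude is returned.
#'
#' @param f_value Reported F statistic (numerator df = 1), >= 0.
#' @param n1,n2 Group sizes.
#' @return Standardized mean difference magnitude.
#' @examples
#' effect_from_F(4.08, 28, 26)  # about 0.550
#' @export
effect_from_F <- function(f_value, n1, n2) {
  if (f_value < 0) stopf("F must be >= 0 (got %s)", f_value)
  sqrt(f_value * (n1 + n2) / (n1 * n2))
}

#' Within-cell SD implied by the F value of a stated contrast
#'
#' Recovers the pooled within-cell standard deviation that makes the
#' stated contrast's F statistic equal the reported value — useful when an
#' article's reported SDs are inconsistent with its reported F statistics.
#' For contrast value `L = sum(w * mus)` tested with
#' `t = L / (sigma * sqrt(sum(w^2 / ns)))` and `F = t^2`,
#' `sigma = |L| / sqrt(F * sum(w^2 / ns))`.
#'
#' @param mus Cell means.
#' @param ns Cell sizes, same length as `mus`.
#' @param f_value Reported F statistic of the contrast, > 0.
#' @param weights Contrast weights, same length as `mus`. Defaults to the
#'   2x2 interaction contrast `c(1, -1, -1, 1)` when there are 4 cells,
#'   or `c(1, -1)` for two cells.
#' @return The implied common within-cell SD.
#' @export
sd_from_F <- function(mus, ns, f_value, weights = NULL) {
  if (length(mus) != length(ns)) stopf("mus and ns must have equal length")
  if (is.null(weights)) {
    weights <- switch(as.character(length(mus)),
      "2" = c(1, -1),
      "4" = c(1, -1, -1, 1),
      stopf("supply contrast weights for a %d-cell design", length(mus))
    )
  }
  if (f_value <= 0) stopf("F must be > 0 (got %s)", f_value)
  L <- sum(weights * mus)
  if (abs(L) < .Machine$double.eps^0.5) {
    stopf("contrast value is zero: no SD can reproduce a positive F")
  }
  abs(L) / sqrt(f_value * sum(weights^2 / ns))
}

#' Hedges' small-sample correction factor
#'
#' `J = 1 - 3 / (4 * df - 1)`, the standard approximation to the exact
#' gamma-function correction that removes the small-sample bias of the
#' observed standardized mean difference.
#'
#' @param df Degrees of freedom of the SD estimate (`n1 + n2 - 2` for two
#'   independent groups).
#' @return Correction factor in (0, 1).
#' @export
hedges_J <- function(df) {
  if (any(df < 2)) stopf("df must be >= 2")
  1 - 3 / (4 * df - 1)
}

## Two- or one-sided rejection probability of a t-test with noncentrality
## `ncp` and `df` degrees of freedom. At ncp = 0 this equals alpha exactly.
noncentral_t_power <- function(ncp, df, alpha, sides = "two_sided") {
  if (sides == "two_sided") {
    q <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(q, df, ncp = ncp) + stats::pt(-q, df, ncp = ncp)
  } else {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = abs(ncp))
  }
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stopf("alpha must be a single number strictly between 0 and 1")
  }
  invisible(alpha)
}
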