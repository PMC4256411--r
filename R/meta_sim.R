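## Operating characteristics of the excess-success test itself, measured
## by meta-simulation: how often does it flag truly unbiased experiment
## sets (its real Type I error), what does file-drawer censoring do to
## published effects and to detectability, and how badly does optional
## stopping inflate the per-experiment Type I error rate?
##
## All meta-simulations use two-sample designs with unit SD. Within each
## simulated set the joint success probabilities are computed
## analytically from the observed (bias-corrected) effects — exact for
## single-test success criteria — rather than by nested Monte Carlo.

#' Describe a reporting-bias model
#'
#' @param kind `"none"`, `"file_drawer"` (publish only significant
#'   experiments), or `"optional_stopping"` (re-test as data accumulate,
#'   stop at significance).
#' @param n_init Initial per-group sample size (optional stopping).
#' @param increment Participants added per group between looks, >= 1.
#' @param n_max Maximum per-group sample size, >= `n_init`.
#' @param alpha Significance criterion applied at each look.
#' @return A `tes_bias_model`.
#' @export
bias_model <- function(kind = c("none", "file_drawer", "optional_stopping"),
                       n_init = 20, increment = 10, n_max = 100, alpha = 0.05) {
  kind <- match.arg(kind)
  if (kind == "optional_stopping") {
    if (increment < 1) stopf("increment must be >= 1")
    if (n_max < n_init) stopf("n_max must be >= n_init")
    if (n_init < 2) stopf("n_init must be >= 2")
    check_alpha(alpha)
  }
  structure(list(kind = kind, n_init = n_init, increment = increment,
                 n_max = n_max, alpha = alpha),
            class = "tes_bias_model")
}

## Observed two-sample t statistics -> bias-corrected standardized
## effects -> post hoc power, all vectorized. This is the estimate a
## reader could form from each published experiment's summary statistics.
posthoc_power_from_t <- function(tv, n, alpha) {
  df <- 2 * n - 2
  mult <- sqrt(n / 2)
  g <- abs(tv) / mult * hedges_J(df)
  q <- stats::qt(1 - alpha / 2, df)
  ncp <- g * mult
  1 - stats::pt(q, df, ncp = ncp) + stats::pt(-q, df, ncp = ncp)
}

#' Flag rate of the excess-success test on unbiased, fully reported sets
#'
#' Simulates sets of `k` properly run two-sample experiments with true
#' standardized effect `d` and `n` per group. The excess-success test is
#' only applied when an article reports uniform success, so each
#' replicate set is retained only if all `k` experiments are significant;
#' the set-level probability is then the product of the post hoc powers
#' implied by the *observed* effects, and the set is flagged when that
#' product falls below `criterion`. The flag rate among retained sets is
#' the test's realized Type I error for concluding bias. It sits well
#' below the nominal criterion (typically near 0.01): conditioning on
#' all-significant outcomes selects sets whose observed effects — and
#' hence estimated powers — are large.
#'
#' @param k Experiments per set, >= 1.
#' @param d True standardized effect, common to all experiments.
#' @param n Per-group sample size.
#' @param reps Simulated sets (before conditioning), >= 100.
#' @param seed RNG seed.
#' @param alpha Per-test significance criterion.
#' @param criterion Excess-success flagging threshold on the set-level
#'   probability, default 0.1.
#' @return A `tes_oc` object: `flag_rate`, `p_tes_quantiles`,
#'   `mean_published_effect` (mean observed |d| among retained sets),
#'   `n_sets` (retained count), `reps`, `seed`.
#' @export
simulate_unbiased_tes <- function(k, d, n, reps = 1000, seed = 1,
                                  alpha = 0.05, criterion = 0.1) {
  if (k < 1) stopf("k must be >= 1")
  if (reps < 100) stopf("reps must be >= 100")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  q <- stats::qt(1 - alpha / 2, df)
  tv <- with_seed(seed, matrix(stats::rt(reps * k, df, ncp = ncp), reps, k))
  sig <- abs(tv) > q
  keep <- rowSums(sig) == k
  tv_k <- tv[keep, , drop = FALSE]
  if (nrow(tv_k) == 0) {
    stopf(paste0("no replicate produced %d significant experiments; ",
                 "increase reps or the true effect"), k)
  }
  pow <- matrix(posthoc_power_from_t(tv_k, n, alpha), nrow(tv_k), k)
  p_tes <- apply(pow, 1, prod)
  new_oc(
    scenario = "unbiased",
    flag_rate = mean(p_tes < criterion),
    p_tes_quantiles = stats::quantile(p_tes, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    mean_published_effect = mean(abs(tv_k) / sqrt(n / 2)),
    n_sets = sum(keep), reps = reps, seed = seed,
    params = list(k = k, d = d, n = n, alpha = alpha, criterion = criterion)
  )
}

#' Excess-success test under file-drawer censoring
#'
#' Each replicate runs `attempts` proper experiments but "publishes" only
#' the significant ones. The excess-success analysis sees only the
#' published subset (uniformly successful by construction). Selection
#' inflates the published effect sizes, which inflates the estimated
#' success probabilities, so the test frequently fails to flag sets that
#' are in fact completely censored — the known blind spot of the method.
#'
#' @param d True standardized effect.
#' @param n Per-group sample size.
#' @param attempts Experiments attempted per set.
#' @param reps Simulated sets, >= 100.
#' @param seed RNG seed.
#' @param alpha Per-test significance criterion.
#' @param criterion Flagging threshold, default 0.1.
#' @return A `tes_oc` object; `n_sets` counts replicates with at least
#'   one published experiment, `mean_published_effect` the mean observed
#'   |d| among published experiments.
#' @export
simulate_file_drawer <- function(d, n, attempts, reps = 1000, seed = 1,
                                 alpha = 0.05, criterion = 0.1) {
  if (attempts < 1) stopf("attempts must be >= 1")
  if (reps < 100) stopf("reps must be >= 100")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  q <- stats::qt(1 - alpha / 2, df)
  tv <- with_seed(seed, matrix(stats::rt(reps * attempts, df, ncp = ncp),
                               reps, attempts))
  sig <- abs(tv) > q
  published <- rowSums(sig) >= 1
  if (!any(published)) {
    stopf("no replicate published any experiment; increase reps")
  }
  pow <- matrix(posthoc_power_from_t(tv, n, alpha), reps, attempts)
  ## product over the published (significant) experiments only
  pow[!sig] <- 1
  p_tes <- apply(pow, 1, prod)[published]
  new_oc(
    scenario = "file_drawer",
    flag_rate = mean(p_tes < criterion),
    p_tes_quantiles = stats::quantile(p_tes, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    mean_published_effect = mean((abs(tv) / sqrt(n / 2))[sig]),
    n_sets = sum(published), reps = reps, seed = seed,
    params = list(d = d, n = n, attempts = attempts, alpha = alpha,
                  criterion = criterion)
  )
}

#' Type I error and p-value distribution under optional stopping
#'
#' Simulates two-sample experiments that test after every `increment`
#' added participants per group (first look at `n_init`, last at or
#' below `n_max`) and stop at the first significant result. At `d = 0`
#' the realized rejection rate exceeds the nominal `alpha` — each
#' additional look is another chance at a false positive — and the
#' p-values among rejections pile up just below the criterion.
#'
#' @param model A [bias_model()] with `kind = "optional_stopping"`.
#' @param d True standardized effect (0 for Type I error).
#' @param reps Simulated experiments, >= 100.
#' @param seed RNG seed.
#' @return A `tes_stopping` object: `rejection_rate`, `final_p`
#'   (p-value at stopping, all replicates), `rejected` (logical),
#'   `final_n` (per-group size at stopping), `looks`, `reps`, `seed`.
#' @export
simulate_optional_stopping <- function(model, d = 0, reps = 5000, seed = 1) {
  stopifnot(inherits(model, "tes_bias_model"))
  if (model$kind != "optional_stopping") {
    stopf("model kind is '%s', not optional_stopping", model$kind)
  }
  if (reps < 100) stopf("reps must be >= 100")
  looks <- seq(model$n_init, model$n_max, by = model$increment)
  n_max <- max(looks)
  alpha <- model$alpha

  sim <- with_seed(seed, {
    x1 <- matrix(stats::rnorm(reps * n_max, mean = d), reps, n_max)
    x2 <- matrix(stats::rnorm(reps * n_max), reps, n_max)
    list(x1 = x1, x2 = x2)
  })
  cs1 <- rowCumsum(sim$x1); cq1 <- rowCumsum(sim$x1^2)
  cs2 <- rowCumsum(sim$x2); cq2 <- rowCumsum(sim$x2^2)

  p_at <- vapply(looks, function(n) {
    m1 <- cs1[, n] / n; m2 <- cs2[, n] / n
    ss1 <- cq1[, n] - n * m1^2
    ss2 <- cq2[, n] - n * m2^2
    sp2 <- (ss1 + ss2) / (2 * n - 2)
    tv <- (m1 - m2) / sqrt(sp2 * 2 / n)
    2 * stats::pt(-abs(tv), 2 * n - 2)
  }, numeric(reps))
  p_at <- matrix(p_at, nrow = reps)

  sig <- p_at <= alpha
  first <- apply(sig, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  rejected <- !is.na(first)
  stop_at <- ifelse(rejected, first, length(looks))
  final_p <- p_at[cbind(seq_len(reps), stop_at)]

  structure(
    list(rejection_rate = mean(rejected), final_p = final_p,
         rejected = rejected, final_n = looks[stop_at], looks = looks,
         alpha = alpha, d = d, reps = reps, seed = seed),
    class = "tes_stopping"
  )
}

rowCumsum <- function(x) t(apply(x, 1, cumsum))

new_oc <- function(scenario, flag_rate, p_tes_quantiles, mean_published_effect,
                   n_sets, reps, seed, params) {
  structure(
    list(scenario = scenario, flag_rate = flag_rate,
         p_tes_quantiles = p_tes_quantiles,
         mean_published_effect = mean_published_effect,
         n_sets = n_sets, reps = reps, seed = seed, params = params),
    class = "tes_oc"
  )
}

#' @export
print.tes_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s scenario)\n", x$scenario))
  cat(sprintf("  sets analyzed: %d of %d replicates\n", x$n_sets, x$reps))
  cat(sprintf("  flag rate at criterion %.2f: %.4f\n",
              x$params$criterion, x$flag_rate))
  cat(sprintf("  mean published |effect|: %.3f (true |d| = %.3f)\n",
              x$mean_published_effect, abs(x$params$d)))
  cat("  set-probability quantiles:\n")
  q <- x$p_tes_quantiles
  cat(sprintf("    %s\n", paste(sprintf("%s=%.3f", names(q), q), collapse = " ")))
  invisible(x)
}

#' @export
print.tes_stopping <- function(x, ...) {
  cat("Optional stopping simulation\n")
  cat(sprintf("  looks at n = %s (per group), alpha = %.3f, true d = %.2f\n",
              paste(x$looks, collapse = ", "), x$alpha, x$d))
  cat(sprintf("  rejection rate: %.4f over %d replicates\n",
              x$rejection_rate, x$reps))
  if (any(x$rejected)) {
    cat(sprintf("  p-values among rejections: median %.4f, share in (%.2f, %.2f]: %.3f\n",
                stats::median(x$final_p[x$rejected]), 0.8 * x$alpha, x$alpha,
                mean(x$final_p[x$rejected] > 0.8 * x$alpha)))
  }
  invisible(x)
}
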