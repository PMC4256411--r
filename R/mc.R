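## Monte Carlo estimation of the joint probability that a simulated
## replication satisfies a compound success criterion. Replications are
## drawn from the experiment's population model; every test family
## depends on the data only through per-group means and within-group
## sums of squares, so the bulk engine simulates those sufficient
## statistics in vectorized chunks. `simulate_dataset()` and
## `evaluate_tests()` expose the single-replication path on raw data,
## which the tests cross-check against standard routines.

#' Draw one simulated replication dataset from a population model
#'
#' Independent draws per participant, multivariate-normal across the
#' dependent measures with the population's within-participant
#' correlation matrix, scaled by the common SD(s) and shifted by the
#' group means.
#'
#' @param population A `tes_population` (see [population_spec()]).
#' @param seed Optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return A named list (one entry per group) of `n x M` matrices with
#'   one column per dependent measure.
#' @export
simulate_dataset <- function(population, seed = NULL) {
  stopifnot(inherits(population, "tes_population"))
  draw <- function() {
    U <- chol(population$corr, pivot = FALSE)
    out <- lapply(seq_along(population$labels), function(g) {
      n <- population$n[g]
      m <- length(population$measures)
      Z <- matrix(stats::rnorm(n * m), n, m) %*% U
      X <- sweep(Z, 2, population$sigma, `*`)
      X <- sweep(X, 2, population$means[g, ], `+`)
      colnames(X) <- population$measures
      X
    })
    names(out) <- population$labels
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Evaluate a battery of tests on one simulated dataset
#'
#' Computes each test's p-value on the raw data — pooled-variance
#' two-sample t, one-way ANOVA F, or contrast t against the design's
#' pooled error — and records whether it met its required outcome
#' (significant: `p <= alpha`; non-significant: `p > alpha`).
#'
#' @param dataset A dataset as returned by [simulate_dataset()].
#' @param tests A list of [test_spec()] objects (no `correlation_zero`
#'   tests: those have no simulatable raw data here).
#' @return A data frame with columns `id`, `p_value`, `met`.
#' @export
evaluate_tests <- function(dataset, tests) {
  labels <- names(dataset)
  measures <- colnames(dataset[[1]])
  n <- vapply(dataset, nrow, 0L)
  stats_of <- function(m) {
    mean_g <- vapply(dataset, function(X) mean(X[, m]), 0)
    ss_g <- vapply(dataset, function(X) sum((X[, m] - mean(X[, m]))^2), 0)
    list(mean = mean_g, ss = ss_g)
  }
  rows <- lapply(tests, function(tt) {
    if (tt$family == "correlation_zero") {
      stopf("test '%s': correlation tests have no simulatable raw data", tt$id)
    }
    m <- if (is.null(tt$measure)) 1L else if (is.numeric(tt$measure)) {
      as.integer(tt$measure)
    } else match(tt$measure, measures)
    st <- stats_of(m)
    gi <- match(tt$groups, labels)
    if (anyNA(gi)) stopf("test '%s' references groups absent from the dataset", tt$id)
    p <- switch(tt$family,
      two_sample_t = {
        i <- gi[1]; j <- gi[2]
        df <- n[i] + n[j] - 2
        sp2 <- (st$ss[i] + st$ss[j]) / df
        tv <- (st$mean[i] - st$mean[j]) / sqrt(sp2 * (1 / n[i] + 1 / n[j]))
        p_from_t(tv, df, tt$sides)
      },
      cell_contrast = {
        i <- gi[1]; j <- gi[2]
        df <- sum(n) - length(n)
        mse <- sum(st$ss) / df
        tv <- (st$mean[i] - st$mean[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
        p_from_t(tv, df, tt$sides)
      },
      oneway_anova_omnibus = {
        k <- length(gi)
        N <- sum(n[gi])
        gm <- sum(n[gi] * st$mean[gi]) / N
        msb <- sum(n[gi] * (st$mean[gi] - gm)^2) / (k - 1)
        mse <- sum(st$ss[gi]) / (N - k)
        1 - stats::pf(msb / mse, k - 1, N - k)
      },
      interaction_2x2 = {
        w <- c(1, -1, -1, 1)
        df <- sum(n[gi]) - 4
        mse <- sum(st$ss[gi]) / df
        L <- sum(w * st$mean[gi])
        tv <- L / sqrt(mse * sum(w^2 / n[gi]))
        p_from_t(tv, df, tt$sides)
      },
      stopf("unknown test family '%s'", tt$family)
    )
    met <- if (tt$required == "significant") p <= tt$alpha else p > tt$alpha
    data.frame(id = tt$id, p_value = p, met = met, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

p_from_t <- function(tv, df, sides) {
  if (sides == "two_sided") 2 * stats::pt(-abs(tv), df) else stats::pt(-tv, df)
}

#' Monte Carlo estimate of an experiment's joint success probability
#'
#' Simulates `reps` replications of the experiment from its population
#' model, evaluates the full test battery on each, and returns the
#' proportion in which *all* criterion tests met their required outcome,
#' with its binomial standard error and the per-test marginal
#' proportions as components.
#'
#' @param experiment A `tes_experiment` with `method = "monte_carlo"`.
#' @param reps Number of simulated replications (>= 1000); defaults to
#'   the experiment's own setting (100000 unless configured otherwise).
#' @param seed Seed for the simulation stream; the caller's RNG state is
#'   preserved. Defaults to the experiment's `seed`, else 1.
#' @return A [success_estimate()] with `method = "monte_carlo"`.
#' @export
estimate_joint_success <- function(experiment, reps = NULL, seed = NULL) {
  stopifnot(inherits(experiment, "tes_experiment"))
  if (experiment$method != "monte_carlo") {
    stopf("experiment '%s' has method '%s', not monte_carlo",
          experiment$label, experiment$method)
  }
  pop <- experiment$model
  if (is.null(pop)) stopf("experiment '%s' has no simulatable population", experiment$label)
  reps <- as.integer(reps %||% experiment$reps)
  if (reps < 1000) stopf("reps must be >= 1000 (got %d)", reps)
  seed <- seed %||% experiment$seed %||% 1L

  tests <- experiment$tests
  crit <- experiment$success_criterion
  n_success <- 0
  met_totals <- stats::setNames(numeric(length(tests)), names(tests))

  with_seed(seed, {
    done <- 0L
    chunk <- min(reps, 20000L)
    while (done < reps) {
      r <- min(chunk, reps - done)
      st <- sim_sufficient(pop, r)
      met <- vapply(tests, function(tt) test_met_vec(tt, st, pop), logical(r))
      met <- matrix(met, nrow = r,
                    dimnames = list(NULL, names(tests)))
      n_success <- n_success + sum(rowSums(met[, crit, drop = FALSE]) == length(crit))
      met_totals <- met_totals + colSums(met)
      done <- done + r
    }
  })

  v <- n_success / reps
  success_estimate(
    value = v,
    se = sqrt(v * (1 - v) / reps),
    method = "monte_carlo",
    components = met_totals / reps,
    reps = reps
  )
}

## Sufficient statistics (per-group, per-measure means and within-group
## sums of squares) for `r` simulated replications: matrices mean[[m]]
## and ss[[m]], each r x G.
sim_sufficient <- function(pop, r) {
  G <- length(pop$labels)
  M <- length(pop$measures)
  U <- chol(pop$corr, pivot = FALSE)
  mean_arr <- lapply(seq_len(M), function(m) matrix(0, r, G))
  ss_arr <- lapply(seq_len(M), function(m) matrix(0, r, G))
  for (g in seq_len(G)) {
    n <- pop$n[g]
    Z <- matrix(stats::rnorm(r * n * M), r * n, M)
    if (M > 1) Z <- Z %*% U
    for (m in seq_len(M)) {
      X <- matrix(Z[, m] * pop$sigma[m] + pop$means[g, m], r, n)
      mu <- rowMeans(X)
      mean_arr[[m]][, g] <- mu
      ss_arr[[m]][, g] <- rowSums((X - mu)^2)
    }
  }
  list(mean = mean_arr, ss = ss_arr, n = pop$n, labels = pop$labels)
}

## Vector of "met its required outcome" over replications for one test,
## computed from sufficient statistics. Matches evaluate_tests() exactly
## on any given dataset.
test_met_vec <- function(tt, st, pop) {
  m <- measure_index(tt, pop)
  gi <- match(tt$groups, st$labels)
  n <- st$n
  mean_m <- st$mean[[m]]
  ss_m <- st$ss[[m]]
  p <- switch(tt$family,
    two_sample_t = {
      i <- gi[1]; j <- gi[2]
      df <- n[i] + n[j] - 2
      sp2 <- (ss_m[, i] + ss_m[, j]) / df
      tv <- (mean_m[, i] - mean_m[, j]) / sqrt(sp2 * (1 / n[i] + 1 / n[j]))
      p_from_t(tv, df, tt$sides)
    },
    cell_contrast = {
      i <- gi[1]; j <- gi[2]
      df <- sum(n) - length(n)
      mse <- rowSums(ss_m) / df
      tv <- (mean_m[, i] - mean_m[, j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
      p_from_t(tv, df, tt$sides)
    },
    oneway_anova_omnibus = {
      k <- length(gi)
      N <- sum(n[gi])
      gm <- mean_m[, gi, drop = FALSE] %*% n[gi] / N
      msb <- (mean_m[, gi, drop = FALSE] - as.vector(gm))^2 %*% n[gi] / (k - 1)
      mse <- rowSums(ss_m[, gi, drop = FALSE]) / (N - k)
      1 - stats::pf(as.vector(msb) / mse, k - 1, N - k)
    },
    interaction_2x2 = {
      w <- c(1, -1, -1, 1)
      df <- sum(n[gi]) - 4
      mse <- rowSums(ss_m[, gi, drop = FALSE]) / df
      L <- mean_m[, gi, drop = FALSE] %*% w
      tv <- as.vector(L) / sqrt(mse * sum(w^2 / n[gi]))
      p_from_t(tv, df, tt$sides)
    },
    stopf("test family '%s' cannot be simulated", tt$family)
  )
  if (tt$required == "significant") p <= tt$alpha else p > tt$alpha
}
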