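## Domain types: one hypothesis test (test_spec), the generating model
## assumed for replications (population_spec), one experiment with its
## success criterion (experiment_spec), and an article's ordered set of
## experiments (experiment_set). Validation turns a declarative config
## (YAML/JSON, or an equivalent R list) into a fully-checked set.

TEST_FAMILIES <- c(
  "correlation_zero", "two_sample_t", "oneway_anova_omnibus",
  "cell_contrast", "interaction_2x2"
)

#' Specify one hypothesis test within an experiment
#'
#' @param id Short unique label for the test.
#' @param family One of `"correlation_zero"`, `"two_sample_t"`,
#'   `"oneway_anova_omnibus"`, `"cell_contrast"`, `"interaction_2x2"`.
#'   `cell_contrast` is a two-cell comparison tested against the error
#'   variance pooled over *all* cells of the design; `two_sample_t` pools
#'   over the two cells only.
#' @param groups Labels of the groups (or, for `correlation_zero`, the
#'   correlation measure) the test compares. `interaction_2x2` takes the
#'   four cells in the order `(1, 2, 3, 4)` such that the contrast is
#'   `(mu1 - mu2) - (mu3 - mu4)`.
#' @param alpha Significance criterion, strictly between 0 and 1.
#' @param sides `"two_sided"` (default) or `"one_sided"`.
#' @param required Whether success needs this test `"significant"`
#'   (default) or `"nonsignificant"`.
#' @param measure For multivariate populations, the dependent measure the
#'   test is applied to (label or index; default the first).
#' @return A `tes_test_spec` object.
#' @export
test_spec <- function(id, family, groups, alpha = 0.05,
                      sides = c("two_sided", "one_sided"),
                      required = c("significant", "nonsignificant"),
                      measure = NULL) {
  sides <- match.arg(sides)
  required <- match.arg(required)
  if (!family %in% TEST_FAMILIES) {
    stopf("unknown test family '%s' (must be one of: %s)",
          family, paste(TEST_FAMILIES, collapse = ", "))
  }
  check_alpha(alpha)
  if (length(groups) < 1) stopf("test '%s' references no groups", id)
  ngr <- c(correlation_zero = 1L, two_sample_t = 2L, cell_contrast = 2L,
           interaction_2x2 = 4L)[family]
  if (!is.na(ngr) && length(groups) != ngr) {
    stopf("family '%s' requires exactly %d group reference(s), got %d",
          family, ngr, length(groups))
  }
  if (family == "oneway_anova_omnibus" && length(groups) < 2) {
    stopf("omnibus ANOVA needs at least 2 groups")
  }
  structure(
    list(id = as.character(id), family = family,
         groups = as.character(groups), alpha = alpha, sides = sides,
         required = required, measure = measure),
    class = "tes_test_spec"
  )
}

#' Specify the population model assumed for replications
#'
#' Encodes the generating model from which simulated replications are
#' drawn: groups with sizes and mean vectors (one entry per dependent
#' measure), a common within-group SD per measure, and the correlation
#' between measures within a participant.
#'
#' @param groups A list of groups, each `list(label =, n =, mean =)`;
#'   `mean` is a vector with one entry per dependent measure (length-1
#'   for univariate designs).
#' @param sigma Common within-group SD, one value per dependent measure.
#' @param corr Correlation matrix between dependent measures within a
#'   participant; `NULL` (identity) for uncorrelated or univariate
#'   designs.
#' @param measures Optional labels for the dependent measures.
#' @return A `tes_population` object.
#' @export
population_spec <- function(groups, sigma, corr = NULL, measures = NULL) {
  if (length(groups) < 1) stopf("population needs at least one group")
  labels <- vapply(groups, function(g) as.character(g$label), "")
  if (anyDuplicated(labels)) stopf("duplicate group labels")
  n <- vapply(groups, function(g) as.numeric(g$n), 0)
  if (any(n < 2)) stopf("all group sizes must be >= 2")
  means <- do.call(rbind, lapply(groups, function(g) as.numeric(g$mean)))
  m <- ncol(means)
  if (any(vapply(groups, function(g) length(g$mean), 0L) != m)) {
    stopf("all groups must have the same number of dependent measures")
  }
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1 && m > 1) sigma <- rep(sigma, m)
  if (length(sigma) != m) stopf("sigma must have one entry per dependent measure")
  if (any(sigma <= 0)) stopf("sigma must be > 0")
  if (is.null(measures)) measures <- paste0("m", seq_len(m))
  measures <- as.character(measures)
  if (length(measures) != m) stopf("need one measure label per column of means")
  if (is.null(corr)) {
    corr <- diag(m)
  } else {
    corr <- as.matrix(corr)
    if (!isTRUE(all.equal(dim(corr), c(m, m)))) {
      stopf("corr must be a %dx%d matrix", m, m)
    }
    if (max(abs(corr - t(corr))) > 1e-8) stopf("corr must be symmetric")
    if (max(abs(diag(corr) - 1)) > 1e-8) stopf("corr must have unit diagonal")
    if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stopf("corr must be positive semi-definite")
    }
  }
  dimnames(means) <- list(labels, measures)
  dimnames(corr) <- list(measures, measures)
  structure(
    list(labels = labels, n = as.integer(round(n)), means = means,
         sigma = stats::setNames(sigma, measures), corr = corr,
         measures = measures),
    class = "tes_population"
  )
}

#' Specify one experiment: summary statistics plus its success criterion
#'
#' An experiment is described either by an explicit [population_spec()],
#' by correlation summary statistics (`correlations`), or by F values
#' from which a standardized population is derived (`from_f`). The
#' success criterion names the subset of tests that must *all* meet their
#' required outcome for the experiment to count as successful.
#'
#' @param label Unique experiment label.
#' @param tests List of [test_spec()] objects.
#' @param success_criterion Character vector of test ids; non-empty
#'   subset of `tests`. Defaults to all tests.
#' @param method How the joint success probability is estimated:
#'   `"analytic"` (single-test criteria only), `"monte_carlo"`, or
#'   `"min_bound"` (smallest component probability as an upper bound,
#'   for correlated outcomes that cannot be simulated from summaries).
#' @param population A [population_spec()], or `NULL` when
#'   `correlations` / `from_f` is given.
#' @param correlations For correlation designs: `list(n =, r =)` with `r`
#'   a (optionally named) vector of observed correlations; names become
#'   the measure labels referenced by `correlation_zero` tests (default
#'   `r1`, `r2`, ...).
#' @param from_f For two-group designs reported only as F values:
#'   `list(groups = list(list(label =, n =), ...), f =, corr =)` with `f`
#'   a named vector of F statistics (one per dependent measure) and
#'   `corr` the between-measure correlation (scalar or matrix). Group
#'   mean offsets are `effect_from_F` of each F value, on the
#'   standardized scale.
#' @param effect_scale `"raw"` (default: use the population as given) or
#'   `"hedges"`: for two-group designs, replace the group mean
#'   differences by their Hedges-bias-corrected standardized values (SD
#'   1). Observed standardized differences overestimate the population
#'   value in small samples; the corrected value is the better estimate
#'   of a replication's true effect. `from_f` derivations default to
#'   `"hedges"`.
#' @param reps Monte Carlo replicate count (default 100000).
#' @param seed Optional per-experiment seed; normally left `NULL` so the
#'   analysis seed keys a sub-stream from the experiment label.
#' @return A `tes_experiment` object.
#' @export
experiment_spec <- function(label, tests, success_criterion = NULL,
                            method = c("monte_carlo", "analytic", "min_bound"),
                            population = NULL, correlations = NULL,
                            from_f = NULL, effect_scale = NULL,
                            reps = 100000, seed = NULL) {
  method <- match.arg(method)
  if (is.null(label) || !nzchar(label)) stopf("experiment needs a non-empty label")
  if (length(tests) < 1) stopf("experiment '%s' has no tests", label)
  tests <- lapply(tests, function(tt) {
    if (!inherits(tt, "tes_test_spec")) tt <- do.call(test_spec, tt)
    tt
  })
  ids <- vapply(tests, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("duplicate test ids in experiment '%s'", label)
  names(tests) <- ids
  if (is.null(success_criterion)) success_criterion <- ids
  success_criterion <- as.character(success_criterion)
  if (length(success_criterion) == 0) {
    stopf("experiment '%s': success criterion is empty", label)
  }
  if (!all(success_criterion %in% ids)) {
    stopf("experiment '%s': criterion references unknown test(s): %s", label,
          paste(setdiff(success_criterion, ids), collapse = ", "))
  }
  n_sources <- sum(!is.null(population), !is.null(correlations), !is.null(from_f))
  if (n_sources != 1) {
    stopf("experiment '%s': give exactly one of population, correlations, from_f", label)
  }
  if (method == "analytic" && length(success_criterion) > 1) {
    stopf(paste0("experiment '%s': method 'analytic' is only valid for a ",
                 "single-test criterion; use monte_carlo or min_bound"), label)
  }
  if (reps < 1000) stopf("reps must be >= 1000 (got %s)", reps)

  if (!is.null(correlations)) {
    r <- correlations$r
    if (is.null(r) || is.null(correlations$n)) stopf("correlations needs n and r")
    r <- unlist(r)
    if (is.null(names(r))) names(r) <- paste0("r", seq_along(r))
    if (any(abs(r) >= 1)) stopf("observed correlations must satisfy |r| < 1")
    if (correlations$n < 4) stopf("correlation design needs n >= 4")
    correlations <- list(n = as.integer(correlations$n), r = unlist(r))
  }
  if (!is.null(from_f)) {
    if (length(from_f$groups) != 2) stopf("from_f derivation requires two groups")
    if (is.null(from_f$f)) stopf("from_f needs reported F values")
    if (is.null(effect_scale)) effect_scale <- "hedges"
  }
  effect_scale <- effect_scale %||% "raw"
  if (!effect_scale %in% c("raw", "hedges")) {
    stopf("effect_scale must be 'raw' or 'hedges'")
  }
  if (!is.null(population) && !inherits(population, "tes_population")) {
    population <- do.call(population_spec, population)
  }

  exp <- structure(
    list(label = as.character(label), tests = tests,
         success_criterion = success_criterion, method = method,
         population = population, correlations = correlations,
         from_f = from_f, effect_scale = effect_scale,
         reps = as.integer(reps), seed = seed),
    class = "tes_experiment"
  )
  exp$model <- derive_population(exp)
  check_group_references(exp)
  exp
}

## The population actually used for computation: explicit population
## (optionally Hedges-standardized), or one derived from F values.
## Correlation-only experiments have no simulatable population (NULL).
derive_population <- function(exp) {
  if (!is.null(exp$correlations)) return(NULL)
  if (!is.null(exp$from_f)) {
    labels <- vapply(exp$from_f$groups, function(g) as.character(g$label), "")
    n <- vapply(exp$from_f$groups, function(g) as.numeric(g$n), 0)
    f <- unlist(exp$from_f$f)
    if (is.null(names(f))) names(f) <- paste0("m", seq_along(f))
    d <- vapply(f, effect_from_F, 0, n1 = n[1], n2 = n[2])
    if (exp$effect_scale == "hedges") d <- d * hedges_J(sum(n) - 2)
    m <- length(d)
    corr <- exp$from_f$corr
    if (is.null(corr)) corr <- diag(m)
    if (length(corr) == 1 && m == 2) {
      corr <- matrix(c(1, corr, corr, 1), 2)
    }
    return(population_spec(
      groups = list(list(label = labels[1], n = n[1], mean = d),
                    list(label = labels[2], n = n[2], mean = rep(0, m))),
      sigma = rep(1, m), corr = corr, measures = names(f)
    ))
  }
  pop <- exp$population
  if (exp$effect_scale == "hedges") {
    if (length(pop$labels) != 2) {
      stopf("experiment '%s': effect_scale 'hedges' is defined for two-group designs",
            exp$label)
    }
    J <- hedges_J(sum(pop$n) - 2)
    d <- (pop$means[1, ] - pop$means[2, ]) / pop$sigma * J
    pop <- population_spec(
      groups = list(list(label = pop$labels[1], n = pop$n[1], mean = as.numeric(d)),
                    list(label = pop$labels[2], n = pop$n[2],
                         mean = rep(0, length(d)))),
      sigma = rep(1, length(d)), corr = pop$corr, measures = pop$measures
    )
  }
  pop
}

check_group_references <- function(exp) {
  available <- if (!is.null(exp$correlations)) {
    names(exp$correlations$r)
  } else {
    exp$model$labels
  }
  measures <- if (is.null(exp$model)) character() else exp$model$measures
  for (tt in exp$tests) {
    if (tt$family == "correlation_zero") {
      if (is.null(exp$correlations)) {
        stopf("experiment '%s': correlation test '%s' but no correlation summaries",
              exp$label, tt$id)
      }
    }
    missing <- setdiff(tt$groups, available)
    if (length(missing) > 0) {
      stopf("experiment '%s': test '%s' references unknown group(s): %s",
            exp$label, tt$id, paste(missing, collapse = ", "))
    }
    if (!is.null(tt$measure) && !is.null(exp$model)) {
      ok <- tt$measure %in% measures ||
        (is.numeric(tt$measure) && tt$measure <= length(measures))
      if (!ok) {
        stopf("experiment '%s': test '%s' references unknown measure '%s'",
              exp$label, tt$id, tt$measure)
      }
    }
  }
  invisible(exp)
}

## Column index of the measure a test applies to.
measure_index <- function(test, pop) {
  if (is.null(test$measure)) return(1L)
  if (is.numeric(test$measure)) return(as.integer(test$measure))
  match(test$measure, pop$measures)
}

#' Assemble and validate an article's experiment set
#'
#' @param experiments List of [experiment_spec()] objects.
#' @param authors,year,title Article metadata.
#' @return A `tes_experiment_set` object. Sets with fewer than four
#'   experiments are accepted with a warning: the excess-success test has
#'   little power below four experiments, but the arithmetic is well
#'   defined regardless.
#' @export
experiment_set <- function(experiments, authors = NULL, year = NULL, title = NULL) {
  if (length(experiments) < 1) stopf("an experiment set needs at least one experiment")
  experiments <- lapply(experiments, function(e) {
    if (!inherits(e, "tes_experiment")) e <- do.call(experiment_spec, e)
    e
  })
  labels <- vapply(experiments, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("experiment labels must be unique")
  names(experiments) <- labels
  if (length(experiments) < 4) {
    warning(sprintf(paste0(
      "set has %d experiment(s); the excess-success test has adequate power ",
      "only for sets of four or more"), length(experiments)), call. = FALSE)
  }
  structure(
    list(authors = authors, year = year, title = title,
         experiments = experiments),
    class = "tes_experiment_set"
  )
}

#' Validate a raw (parsed-config) experiment-set description
#'
#' Accepts the list produced by parsing a YAML/JSON config file (see
#' [read_experiment_set()] for the schema) — or an already-built
#' `tes_experiment_set` — fills defaults (`alpha = 0.05`, two-sided,
#' `reps = 100000`, criterion = all tests) and returns a fully validated
#' set, or raises an informative error.
#'
#' @param raw A named list with fields `article` (optional: `authors`,
#'   `year`, `title`) and `experiments`.
#' @return A `tes_experiment_set`.
#' @export
validate_experiment_set <- function(raw) {
  if (inherits(raw, "tes_experiment_set")) {
    return(experiment_set(raw$experiments, raw$authors, raw$year, raw$title))
  }
  if (!is.list(raw)) stopf("expected a parsed config list")
  exps <- raw$experiments %||% stopf("config has no 'experiments' entry")
  experiments <- lapply(exps, function(e) {
    args <- e[intersect(names(e),
      c("label", "tests", "success_criterion", "method", "population",
        "correlations", "from_f", "effect_scale", "reps", "seed"))]
    do.call(experiment_spec, args)
  })
  meta <- raw$article %||% list()
  experiment_set(experiments, authors = meta$authors, year = meta$year,
                 title = meta$title)
}

#' Read an experiment set from a YAML (or JSON) config file
#'
#' One file describes one experiment set. Top-level keys: `article`
#' (optional metadata: `authors`, `year`, `title`) and `experiments`, a
#' list in which each entry has
#' \itemize{
#'   \item `label` — unique name;
#'   \item `method` — `analytic` | `monte_carlo` | `min_bound`;
#'   \item one of `population` (`groups`: list of `label`/`n`/`mean`,
#'     plus `sigma`, optional `corr`, `measures`), `correlations`
#'     (`n`, `r`), or `from_f` (`groups`, `f`, `corr`);
#'   \item optional `effect_scale` — `raw` | `hedges`;
#'   \item `tests` — list of `id`/`family`/`groups`/`alpha`/`sides`/
#'     `required`/`measure`, with defaults `alpha = 0.05`, `two_sided`,
#'     `significant`;
#'   \item `success_criterion` — test ids (default: all tests);
#'   \item optional `reps`, `seed`.
#' }
#' JSON files (parsed by yaml, of which JSON is a subset) are accepted.
#'
#' @param path Path to the config file.
#' @return A validated `tes_experiment_set`.
#' @export
read_experiment_set <- function(path) {
  validate_experiment_set(fix_yaml_bool_keys(yaml::read_yaml(path)))
}

## YAML 1.1 parses a bare `n` key as boolean FALSE (and `y` as TRUE);
## restore the sample-size key so configs need not quote it.
fix_yaml_bool_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, fix_yaml_bool_keys)
}

#' Serialize an experiment set back to a config list or YAML file
#'
#' Emits the declarative description (the original population /
#' correlation / F-value summaries, not the derived standardized model),
#' so that `validate -> serialize` round-trips exactly.
#'
#' @param set A `tes_experiment_set`.
#' @param path Optional file path; when given, YAML is written there.
#' @return The config list, invisibly when `path` is given.
#' @export
write_experiment_set <- function(set, path = NULL) {
  stopifnot(inherits(set, "tes_experiment_set"))
  cfg <- list(
    article = Filter(Negate(is.null),
                     list(authors = set$authors, year = set$year,
                          title = set$title)),
    experiments = lapply(unname(set$experiments), experiment_config)
  )
  if (length(cfg$article) == 0) cfg$article <- NULL
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

experiment_config <- function(exp) {
  pop <- NULL
  if (!is.null(exp$population)) {
    p <- exp$population
    pop <- list(
      groups = lapply(seq_along(p$labels), function(i) {
        list(label = p$labels[i], n = p$n[i], mean = as.numeric(p$means[i, ]))
      }),
      sigma = as.numeric(p$sigma)
    )
    if (max(abs(p$corr - diag(nrow(p$corr)))) > 0) {
      pop$corr <- unname(apply(p$corr, 1, as.numeric, simplify = FALSE))
    }
    if (!identical(p$measures, paste0("m", seq_along(p$measures)))) {
      pop$measures <- p$measures
    }
  }
  corrs <- if (!is.null(exp$correlations)) {
    list(n = exp$correlations$n, r = as.list(exp$correlations$r))
  }
  from_f <- if (!is.null(exp$from_f)) {
    list(groups = lapply(exp$from_f$groups,
                         function(g) list(label = g$label, n = g$n)),
         f = as.list(unlist(exp$from_f$f)),
         corr = exp$from_f$corr)
  }
  Filter(Negate(is.null), list(
    label = exp$label,
    method = exp$method,
    effect_scale = if (!identical(exp$effect_scale, "raw") ||
                       !is.null(exp$from_f)) exp$effect_scale,
    population = pop,
    correlations = corrs,
    from_f = from_f,
    tests = lapply(unname(exp$tests), function(tt) {
      Filter(Negate(is.null), list(
        id = tt$id, family = tt$family, groups = as.list(tt$groups),
        alpha = tt$alpha, sides = tt$sides, required = tt$required,
        measure = tt$measure))
    }),
    success_criterion = as.list(exp$success_criterion),
    reps = exp$reps,
    seed = exp$seed
  ))
}

#' @export
print.tes_experiment_set <- function(x, ...) {
  hdr <- paste(Filter(nzchar, c(x$authors %||% "", x$year %||% "", x$title %||% "")),
               collapse = " — ")
  if (nzchar(hdr)) cat(hdr, "\n")
  cat(sprintf("Experiment set with %d experiment(s)\n", length(x$experiments)))
  for (e in x$experiments) {
    cat(sprintf("  %s [%s]: %d test(s), criterion {%s}\n", e$label, e$method,
                length(e$tests), paste(e$success_criterion, collapse = ", ")))
  }
  invisible(x)
}
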