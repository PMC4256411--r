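test_that("validation fills defaults and enforces invariants", {
  raw <- list(experiments = list(list(
    label = "E1",
    method = "monte_carlo",
    population = list(
      groups = list(list(label = "g1", n = 17, mean = 316),
                    list(label = "g2", n = 17, mean = 305),
                    list(label = "g3", n = 18, mean = 186)),
      sigma = 152
    ),
    tests = list(
      list(id = "omnibus", family = "oneway_anova_omnibus",
           groups = c("g1", "g2", "g3")),
      list(id = "c13", family = "cell_contrast", groups = c("g1", "g3")),
      list(id = "c23", family = "cell_contrast", groups = c("g2", "g3")),
      list(id = "c12", family = "cell_contrast", groups = c("g1", "g2"),
           required = "nonsignificant")
    )
  )))
  set <- suppressWarnings(validate_experiment_set(raw))
  expect_s3_class(set, "tes_experiment_set")
  expect_length(set$experiments, 1)
  e <- set$experiments[[1]]
  expect_equal(e$tests$omnibus$alpha, 0.05)           # default alpha
  expect_equal(e$tests$c13$sides, "two_sided")        # default sidedness
  expect_equal(e$reps, 100000L)                       # default reps
  expect_setequal(e$success_criterion, names(e$tests)) # default criterion

  # boundary alpha rejected
  bad <- raw
  bad$experiments[[1]]$tests[[1]]$alpha <- 0
  expect_error(suppressWarnings(validate_experiment_set(bad)), "alpha")

  # dangling group reference rejected
  bad <- raw
  bad$experiments[[1]]$tests[[2]]$groups <- c("g1", "g4")
  expect_error(suppressWarnings(validate_experiment_set(bad)), "g4")

  # empty criterion rejected
  bad <- raw
  bad$experiments[[1]]$success_criterion <- character()
  expect_error(suppressWarnings(validate_experiment_set(bad)), "criterion")
})

test_that("population invariants are enforced", {
  expect_error(population_spec(list(list(label = "a", n = 1, mean = 0)), 1),
               ">= 2")
  expect_error(population_spec(list(list(label = "a", n = 5, mean = 0)), 0),
               "sigma")
  bad_corr <- matrix(c(1, 2, 2, 1), 2)  # not a correlation matrix (not PSD)
  expect_error(
    population_spec(list(list(label = "a", n = 5, mean = c(0, 0)),
                         list(label = "b", n = 5, mean = c(1, 1))),
                    c(1, 1), corr = bad_corr),
    "positive semi-definite"
  )
  asym <- matrix(c(1, 0.2, 0.4, 1), 2)
  expect_error(
    population_spec(list(list(label = "a", n = 5, mean = c(0, 0))),
                    c(1, 1), corr = asym),
    "symmetric"
  )
})

test_that("sets smaller than four experiments warn but are accepted", {
  e <- two_group_exp(0.5, label = "only")
  expect_warning(s <- experiment_set(list(e)), "four or more")
  expect_length(s$experiments, 1)
})

test_that("five-experiment fixture matches its published description", {
  set <- table1_fixture()
  expect_length(set$experiments, 5)

  e1 <- set$experiments[["Exp 1"]]
  expect_equal(e1$correlations$n, 179L)
  expect_equal(unname(e1$correlations$r), c(-0.22, -0.15, -0.18))
  expect_equal(e1$method, "min_bound")

  e3 <- set$experiments[["Exp 3"]]
  expect_length(e3$success_criterion, 1)
  expect_equal(e3$tests[[e3$success_criterion]]$alpha, 0.1)

  # Exp 4's population is derived from F values on the standardized scale
  e4 <- set$experiments[["Exp 4"]]
  expect_equal(unname(e4$model$sigma), c(1, 1))
  expect_equal(unname(e4$model$corr[1, 2]), 0.36)
  expect_equal(unname(e4$model$n), c(28L, 26L))

  e5 <- set$experiments[["Exp 5"]]
  expect_equal(unname(e5$model$means[, 1]), c(3.87, 7.00, 7.59, 4.28))
  expect_equal(unname(e5$model$sigma), 3.91)
})

test_that("published per-article probabilities fixture is complete", {
  tab <- table2_fixture()
  expect_equal(nrow(tab), 18)
  expect_equal(tab$p_tes[tab$short_title == "Optimally Interacting Minds"], 0.332)
  expect_equal(
    tab$p_tes[tab$short_title == "Stop Signals Provide Inhibition in Honeybee Swarms"],
    0.957)
})

test_that("serialization round-trips through validation", {
  set <- table1_fixture()
  cfg1 <- write_experiment_set(set)
  set2 <- validate_experiment_set(cfg1)
  cfg2 <- write_experiment_set(set2)
  expect_identical(cfg1, cfg2)

  # and through an actual file
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_set(set, path)
  set3 <- read_experiment_set(path)
  expect_identical(write_experiment_set(set3), cfg1)
})

test_that("every criterion test resolves to population groups on fixtures", {
  set <- table1_fixture()
  for (e in set$experiments) {
    avail <- if (!is.null(e$correlations)) names(e$correlations$r) else e$model$labels
    for (id in e$success_criterion) {
      expect_true(all(e$tests[[id]]$groups %in% avail))
    }
  }
})
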