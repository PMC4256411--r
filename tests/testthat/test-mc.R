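test_that("simulated datasets respect the population model", {
  pop <- population_spec(
    groups = list(list(label = "a", n = 30, mean = c(1, 2)),
                  list(label = "b", n = 40, mean = c(0, 0))),
    sigma = c(2, 3),
    corr = matrix(c(1, 0.5, 0.5, 1), 2)
  )
  d <- simulate_dataset(pop, seed = 11)
  expect_named(d, c("a", "b"))
  expect_equal(dim(d$a), c(30, 2))
  expect_equal(dim(d$b), c(40, 2))

  # identical seed, identical dataset; RNG state of the caller untouched
  set.seed(99); before <- runif(1)
  d2 <- simulate_dataset(pop, seed = 11)
  set.seed(99); after <- runif(1)
  expect_identical(d, d2)
  expect_identical(before, after)

  # degenerate noise: draws collapse onto the group means
  pop0 <- population_spec(
    groups = list(list(label = "a", n = 10, mean = 3.5)), sigma = 1e-12)
  d0 <- simulate_dataset(pop0, seed = 1)
  expect_equal(as.numeric(d0$a), rep(3.5, 10), tolerance = 1e-9)

  # law of large numbers: pooled sample means near population means
  big <- simulate_dataset(pop, seed = 2)
  expect_equal(colMeans(big$a), c(m1 = 1, m2 = 2),
               tolerance = 4 * max(pop$sigma) / sqrt(30) / 1)
  # and the induced correlation is near its target
  r_obs <- cor(big$b[, 1], big$b[, 2])
  expect_equal(r_obs, 0.5, tolerance = 0.35)
})

test_that("evaluate_tests reproduces reference p-values on a fixed dataset", {
  pop <- population_spec(
    groups = list(list(label = "g1", n = 17, mean = 316),
                  list(label = "g2", n = 17, mean = 305),
                  list(label = "g3", n = 18, mean = 186)),
    sigma = 152
  )
  d <- simulate_dataset(pop, seed = 5)
  tests <- list(
    test_spec("tt", "two_sample_t", c("g1", "g3")),
    test_spec("omnibus", "oneway_anova_omnibus", c("g1", "g2", "g3")),
    test_spec("c12", "cell_contrast", c("g1", "g2"),
              required = "nonsignificant")
  )
  out <- evaluate_tests(d, tests)

  # plain two-sample t against stats::t.test with pooled variance
  ref_t <- t.test(d$g1[, 1], d$g3[, 1], var.equal = TRUE)$p.value
  expect_equal(out$p_value[out$id == "tt"], ref_t, tolerance = 1e-10)

  # omnibus F against stats::aov
  y <- c(d$g1[, 1], d$g2[, 1], d$g3[, 1])
  grp <- factor(rep(c("g1", "g2", "g3"), times = c(17, 17, 18)))
  ref_f <- summary(aov(y ~ grp))[[1]][["Pr(>F)"]][1]
  expect_equal(out$p_value[out$id == "omnibus"], ref_f, tolerance = 1e-10)

  # contrast against the MSE-pooled t implied by the ANOVA fit
  fit <- aov(y ~ grp)
  mse <- deviance(fit) / fit$df.residual
  tv <- (mean(d$g1[, 1]) - mean(d$g2[, 1])) / sqrt(mse * (1 / 17 + 1 / 17))
  ref_c <- 2 * pt(-abs(tv), fit$df.residual)
  expect_equal(out$p_value[out$id == "c12"], ref_c, tolerance = 1e-10)

  # required outcomes are judged against each test's own alpha
  expect_equal(out$met[out$id == "tt"], ref_t <= 0.05)
  expect_equal(out$met[out$id == "c12"], ref_c > 0.05)
})

test_that("required-significant and required-nonsignificant are complements", {
  pop <- population_spec(
    groups = list(list(label = "a", n = 10, mean = 10),
                  list(label = "b", n = 10, mean = 0)),
    sigma = 1
  )
  d <- simulate_dataset(pop, seed = 3)  # enormous separation
  sig <- evaluate_tests(d, list(test_spec("s", "two_sample_t", c("a", "b"))))
  non <- evaluate_tests(d, list(test_spec("s", "two_sample_t", c("a", "b"),
                                          required = "nonsignificant")))
  expect_true(sig$met)
  expect_false(non$met)
})

test_that("joint estimates are reproducible, bounded by marginals, and shrink with reps", {
  e <- three_group_exp(reps = 20000)
  est1 <- estimate_joint_success(e, seed = 42)
  est2 <- estimate_joint_success(e, seed = 42)
  expect_identical(est1, est2)            # bit-for-bit reproducibility
  expect_false(isTRUE(all.equal(est1$value,
                                estimate_joint_success(e, seed = 43)$value)))

  # conjunction bound: joint never exceeds any marginal, on every run
  for (s in 1:5) {
    est <- estimate_joint_success(e, reps = 2000, seed = s)
    expect_lte(est$value, min(est$components[e$success_criterion]))
  }

  # standard error scales as 1/sqrt(reps)
  se_by_reps <- vapply(c(1000, 10000, 100000), function(r) {
    estimate_joint_success(e, reps = r, seed = 1)$se
  }, 0)
  expect_equal(se_by_reps[1] / se_by_reps[2], sqrt(10), tolerance = 0.2)
  expect_equal(se_by_reps[2] / se_by_reps[3], sqrt(10), tolerance = 0.2)
})

test_that("a single-test criterion reproduces analytic power", {
  e <- two_group_exp(0.6, n1 = 25, n2 = 30, reps = 50000)
  est <- estimate_joint_success(e, seed = 17)
  expect_lt(abs(est$value - power_two_sample_t(25, 30, 0.6)), 3 * est$se)
})

test_that("adding a required test never increases the joint estimate", {
  base <- three_group_exp(reps = 5000)
  fewer <- experiment_spec(
    label = base$label, method = "monte_carlo",
    population = base$population, tests = base$tests,
    success_criterion = c("omnibus", "c13"), reps = 5000
  )
  # same seed-stream: the simulated replications are identical
  est_fewer <- estimate_joint_success(fewer, seed = 8)
  est_all <- estimate_joint_success(base, seed = 8)
  expect_lte(est_all$value, est_fewer$value)
  expect_identical(est_fewer$components, est_all$components)
})
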