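# Builders for small synthetic experiments used across the tests.

two_group_exp <- function(d, n1 = 20, n2 = 20, alpha = 0.05, label = "exp",
                          required = "significant", reps = 20000,
                          method = "monte_carlo") {
  experiment_spec(
    label = label,
    method = method,
    population = list(
      groups = list(list(label = "a", n = n1, mean = d),
                    list(label = "b", n = n2, mean = 0)),
      sigma = 1
    ),
    tests = list(test_spec("t", "two_sample_t", c("a", "b"), alpha = alpha,
                           required = required)),
    reps = reps
  )
}

three_group_exp <- function(mus = c(316, 305, 186), ns = c(17, 17, 18),
                            sigma = 152, reps = 20000) {
  experiment_spec(
    label = "three-group",
    method = "monte_carlo",
    population = list(
      groups = list(list(label = "g1", n = ns[1], mean = mus[1]),
                    list(label = "g2", n = ns[2], mean = mus[2]),
                    list(label = "g3", n = ns[3], mean = mus[3])),
      sigma = sigma
    ),
    tests = list(
      test_spec("omnibus", "oneway_anova_omnibus", c("g1", "g2", "g3")),
      test_spec("c13", "cell_contrast", c("g1", "g3")),
      test_spec("c23", "cell_contrast", c("g2", "g3")),
      test_spec("c12", "cell_contrast", c("g1", "g2"),
                required = "nonsignificant")
    ),
    reps = reps
  )
}
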