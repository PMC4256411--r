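test_that("single-experiment flag rate matches a brute-force conditional probability", {
  n <- 30; alpha <- 0.05
  df <- 2 * n - 2
  q <- qt(1 - alpha / 2, df)
  # oracle: integrate the distribution of the observed t over the rejection
  # region and average the indicator that the implied post hoc power is
  # below the criterion (written out independently of the package code)
  oracle <- function(d, criterion) {
    tt <- seq(-40, 40, length.out = 400001)
    dens <- suppressWarnings(dt(tt, df, ncp = d * sqrt(n / 2)))
    sig <- abs(tt) > q
    g <- abs(tt) / sqrt(n / 2) * (1 - 3 / (4 * df - 1))
    pow <- 1 - pt(q, df, ncp = g * sqrt(n / 2)) +
      pt(-q, df, ncp = g * sqrt(n / 2))
    sum(dens[sig] * (pow[sig] < criterion)) / sum(dens[sig])
  }
  oc1 <- simulate_unbiased_tes(k = 1, d = 0.4, n = n, reps = 4000, seed = 2)
  expect_lt(abs(oc1$flag_rate - oracle(0.4, 0.1)), 0.02)

  # at a raised criterion the conditional probability is interior
  oc5 <- simulate_unbiased_tes(k = 1, d = 0.4, n = n, reps = 4000, seed = 2,
                               criterion = 0.7)
  orc <- oracle(0.4, 0.7)
  expect_gt(orc, 0.05); expect_lt(orc, 0.95)
  expect_lt(abs(oc5$flag_rate - orc),
            4 * sqrt(orc * (1 - orc) / oc5$n_sets))
})

test_that("huge true effects make the unbiased flag rate vanish", {
  oc <- simulate_unbiased_tes(k = 4, d = 3, n = 50, reps = 500, seed = 1)
  expect_equal(oc$flag_rate, 0)
  expect_equal(oc$n_sets, 500)  # power ~ 1: every set retained
})

test_that("file-drawer censoring inflates published effects", {
  oc <- simulate_file_drawer(d = 0.3, n = 25, attempts = 6, reps = 1500, seed = 4)
  expect_gt(oc$mean_published_effect, 0.3)  # selection inflates |effect|

  # null effects: published sets exist and mostly evade the flag
  oc0 <- simulate_file_drawer(d = 0, n = 25, attempts = 6, reps = 2000, seed = 5)
  expect_gt(oc0$n_sets, 0)
  expect_lt(oc0$flag_rate, 1)
  expect_gt(oc0$mean_published_effect, 0)
})

test_that("with power near one the file drawer has nothing to censor", {
  un <- simulate_unbiased_tes(k = 5, d = 3, n = 50, reps = 400, seed = 9)
  fd <- simulate_file_drawer(d = 3, n = 50, attempts = 5, reps = 400, seed = 9)
  expect_equal(fd$flag_rate, un$flag_rate)
  expect_equal(fd$p_tes_quantiles, un$p_tes_quantiles)
  expect_equal(fd$mean_published_effect, un$mean_published_effect)
})

test_that("optional stopping inflates the Type I error rate", {
  model <- bias_model("optional_stopping", n_init = 20, increment = 10,
                      n_max = 100, alpha = 0.05)
  st <- simulate_optional_stopping(model, d = 0, reps = 4000, seed = 3)
  expect_gt(st$rejection_rate, 0.05)
  expect_true(all(st$final_p[st$rejected] <= 0.05))

  # a step so large that only one look occurs reduces to the fixed-n test
  one_look <- bias_model("optional_stopping", n_init = 20, increment = 1000,
                         n_max = 25, alpha = 0.05)
  st1 <- simulate_optional_stopping(one_look, d = 0, reps = 4000, seed = 3)
  expect_length(st1$looks, 1)
  expect_lt(abs(st1$rejection_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("type I error is nondecreasing in the number of looks", {
  coarse <- bias_model("optional_stopping", n_init = 20, increment = 40,
                       n_max = 100)
  fine <- bias_model("optional_stopping", n_init = 20, increment = 10,
                     n_max = 100)
  st_c <- simulate_optional_stopping(coarse, d = 0, reps = 2000, seed = 6)
  st_f <- simulate_optional_stopping(fine, d = 0, reps = 2000, seed = 6)
  # same seed-stream: the underlying samples are identical, and every
  # coarse look is also a fine look, so rejections can only accumulate
  expect_true(all(st_f$rejected[st_c$rejected]))
  expect_gte(st_f$rejection_rate, st_c$rejection_rate)
})

test_that("stopped experiments pile p-values just under the criterion", {
  stopping <- bias_model("optional_stopping", n_init = 20, increment = 10,
                         n_max = 100)
  fixed <- bias_model("optional_stopping", n_init = 20, increment = 1000,
                      n_max = 20)
  st <- simulate_optional_stopping(stopping, d = 0, reps = 5000, seed = 12)
  fx <- simulate_optional_stopping(fixed, d = 0, reps = 5000, seed = 12)
  in_band <- function(p) mean(p > 0.04 & p <= 0.05)
  expect_gt(in_band(st$final_p), in_band(fx$final_p))
})

test_that("operating characteristics are well-formed and reproducible", {
  oc_a <- simulate_unbiased_tes(k = 3, d = 0.6, n = 40, reps = 500, seed = 21)
  oc_b <- simulate_unbiased_tes(k = 3, d = 0.6, n = 40, reps = 500, seed = 21)
  expect_identical(oc_a, oc_b)
  expect_gte(oc_a$flag_rate, 0); expect_lte(oc_a$flag_rate, 1)
  expect_true(all(oc_a$p_tes_quantiles >= 0 & oc_a$p_tes_quantiles <= 1))
  expect_true(all(diff(oc_a$p_tes_quantiles) >= 0))
  expect_error(bias_model("optional_stopping", n_init = 20, increment = 0),
               "increment")
  expect_error(bias_model("optional_stopping", n_init = 20, n_max = 10),
               "n_max")
})
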