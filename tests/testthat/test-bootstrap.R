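test_that("extreme-parameter substitution draws from the remaining distribution", {
  beta <- c(0.5, -0.3, 15)
  flags <- c(FALSE, FALSE, TRUE)
  out <- substitute_extreme_parameters(beta, flags, seed = 1)
  expect_equal(out[1:2], beta[1:2])
  expect_gte(out[3], -0.3); expect_lte(out[3], 0.5)

  # no flags: identity
  expect_identical(substitute_extreme_parameters(beta, rep(FALSE, 3)), beta)
  expect_error(substitute_extreme_parameters(beta, rep(TRUE, 3)), "flagged")

  # distributional check: draws reproduce the interpolated empirical CDF
  pool <- c(-1, 0, 1)
  draws <- withr::with_seed(2, {
    b <- c(pool, rep(99, 10000))
    substitute_extreme_parameters(b, c(rep(FALSE, 3), rep(TRUE, 10000)),
                                  seed = 3)[-(1:3)]
  })
  expected_q <- unname(quantile(pool, c(0.25, 0.5, 0.75), type = 7))
  expect_equal(unname(quantile(draws, c(0.25, 0.5, 0.75))), expected_q,
               tolerance = 0.05)
  expect_gte(min(draws), -1); expect_lte(max(draws), 1)
})

test_that("bootstrap p-values follow the add-one exceedance formula", {
  d <- small_dataset(n = 50, events = 4, sigma2_specific = 1, seed = 30)
  res <- test_D(d, bootstrap_settings(B = 49, seed = 31))
  k <- sum(abs(res$boot) >= abs(res$observed$D))
  expect_equal(res$p_value, (1 + k) / 50)
  expect_equal(res$se, sd(res$boot))
  expect_true(all(is.finite(res$boot)))

  # reproducible bit for bit given the seed
  res2 <- test_D(d, bootstrap_settings(B = 49, seed = 31))
  expect_identical(res$boot, res2$boot)
  expect_identical(res$p_value, res2$p_value)

  # results do not depend on the worker count
  res4 <- test_D(d, bootstrap_settings(B = 49, seed = 31, workers = 2))
  expect_identical(res$boot, res4$boot)
})

test_that("difference-test bootstrap respects formula, direction and nulls", {
  des <- simulation_design(60, c("a", "b"), events = 6)
  dat <- simulate_dataset(des, generative_parameters(1, c(2.5, 0.2)), seed = 33)
  parts <- split_conditions(dat)
  res <- test_D_difference(parts$a, parts$b,
                           bootstrap_settings(B = 39, seed = 34))
  k <- sum(res$boot >= res$observed_diff)
  expect_equal(res$p_value, (1 + k) / 40)
  expect_equal(res$observed_diff, res$D_a - res$D_b)
  expect_equal(res$null_sigma2_specific,
               min(res$fit_a$sigma2_specific, res$fit_b$sigma2_specific))
  expect_lt(res$p_value, 0.2)  # large true difference, correct direction

  # hypothesised direction opposite to a large true difference: p near 1
  res_rev <- test_D_difference(parts$a, parts$b,
                               bootstrap_settings(B = 39, seed = 34),
                               direction = "b_greater")
  expect_gt(res_rev$p_value, 0.8)

  # swapping the condition labels and the direction flips the sign of the
  # observed difference and leaves the conclusion intact
  res_sw <- test_D_difference(parts$b, parts$a,
                              bootstrap_settings(B = 39, seed = 34),
                              direction = "b_greater")
  expect_equal(res_sw$observed_diff, -res$observed_diff)
  expect_lt(abs(res_sw$p_value - res$p_value), 0.2)
})

test_that("the difference test holds its level when conditions are exchangeable", {
  des <- simulation_design(60, c("a", "b"), events = 6)
  seeds <- withr::with_seed(35, sample.int(1e6, 30))
  rej <- vapply(seeds, function(s) {
    dat <- simulate_dataset(des, generative_parameters(1, 1), seed = s)
    parts <- split_conditions(dat)
    r <- test_D_difference(parts$a, parts$b,
                           bootstrap_settings(B = 39, seed = s + 1))
    r$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.17)  # binomial 95% upper band around 0.05, n = 30
})

test_that("the bootstrap SE of D shrinks with the sample size", {
  se_at <- function(n) {
    d <- small_dataset(n = n, events = 6, sigma2_specific = 0, seed = 36)
    test_D(d, bootstrap_settings(B = 60, seed = 37))$se
  }
  ses <- vapply(c(100, 400, 1600), se_at, numeric(1))
  expect_true(all(diff(ses) < 0))
  # roughly 1/sqrt(n): a factor 16 in n gives about a factor 4 in SE
  expect_equal(ses[1] / ses[3], 4, tolerance = 0.5)
})
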