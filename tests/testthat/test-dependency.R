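make_fit_stub <- function(beta, sigma2 = 1, guessing = 1 / 6) {
  structure(list(beta = beta, sigma2 = sigma2, guessing = guessing,
                 control = irt_control()),
            class = "unidimensional_fit")
}

test_that("residuals are observed minus model probability", {
  fit <- make_fit_stub(beta = c(0, 0))
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  r <- residual_matrix(m, fit, eap = c(0, 0))  # P = 7/12 everywhere
  expect_equal(r, matrix(c(5 / 12, -7 / 12, -7 / 12, 5 / 12), 2, 2))
})

test_that("item residual means are centred under the true model", {
  des <- simulation_design(2000, conditions = "a", events = 12)
  d <- simulate_dataset(des, generative_parameters(1, 0), seed = 31)
  m <- response_matrix(d)
  f <- fit_unidimensional(m)
  r <- residual_matrix(m, f)
  expect_lt(max(abs(colMeans(r))), 0.03)
})

test_that("Q3 entries equal hand-computed Pearson correlations", {
  set.seed(17)
  res <- matrix(rnorm(5 * 4), 5, 4,
                dimnames = list(NULL, paste0("i", 1:4)))
  q3 <- q3_statistics(res, events = c("a", "a", "b", "b"))
  for (j in 1:3) for (k in (j + 1):4) {
    x <- res[, j] - mean(res[, j]); y <- res[, k] - mean(res[, k])
    hand <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_equal(q3$raw[j, k], hand, tolerance = 1e-12)
  }
  # symmetry and centering identity
  expect_equal(q3$raw, t(q3$raw))
  expect_equal(mean(q3$corrected[upper.tri(q3$corrected)], na.rm = TRUE), 0,
               tolerance = 1e-12)
  # identical columns correlate perfectly
  res2 <- cbind(res, res[, 1])
  colnames(res2) <- paste0("i", 1:5)
  q32 <- q3_statistics(res2, events = c("a", "a", "b", "b", "c"))
  expect_equal(q32$raw[1, 5], 1)
})

test_that("zero-variance residual columns are dropped, not poisoned", {
  set.seed(18)
  res <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("i", 1:3)))
  res[, 2] <- 0.25
  q3 <- q3_statistics(res, events = c("a", "a", "b"))
  expect_equal(q3$dropped_items, "i2")
  expect_true(all(is.na(q3$raw[2, ])))
  expect_false(anyNA(q3$raw[1, 3]))
})

test_that("D is the within-minus-between mean and is shift invariant", {
  # direct arithmetic on a constructed Q3 object
  corr <- matrix(NA_real_, 4, 4, dimnames = list(paste0("i", 1:4),
                                                 paste0("i", 1:4)))
  corr[1, 2] <- 0.10; corr[1, 3] <- 0.06; corr[2, 3] <- 0.02  # within
  corr[1, 4] <- 0.01; corr[2, 4] <- -0.01; corr[3, 4] <- 0    # between
  corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
  same <- outer(c(1, 1, 1, 2), c(1, 1, 1, 2), "==")
  diag(same) <- NA
  q3 <- structure(list(raw = corr, corrected = corr, same_event = same),
                  class = "q3_result")
  dep <- dependency_D(q3)
  expect_equal(dep$D, 0.06)
  expect_equal(dep$within_mean, 0.06)
  expect_equal(dep$between_mean, 0)
  expect_equal(dep$K, 3); expect_equal(dep$L, 3)

  # adding a constant to every entry leaves D unchanged
  q3b <- q3; q3b$corrected <- corr + 0.37
  expect_equal(dependency_D(q3b)$D, dep$D, tolerance = 1e-12)

  # a constant matrix gives D = 0
  q3c <- q3; q3c$corrected[] <- 0.2; diag(q3c$corrected) <- NA
  expect_equal(dependency_D(q3c)$D, 0)
})

test_that("D from raw and bias-corrected matrices agrees to 1e-12", {
  d <- small_dataset(n = 80, events = 6, sigma2_specific = 1, seed = 19)
  out <- estimate_dependency(d)
  q3_raw <- out$q3; q3_raw$corrected <- q3_raw$raw
  expect_equal(dependency_D(q3_raw)$D, out$dependency$D, tolerance = 1e-12)
})

test_that("pair counts follow the design combinatorics", {
  # 24 events x 3 items: K = 24 * C(3,2) = 72, K + L = C(72,2) = 2556
  des <- simulation_design(40, conditions = "a")
  d <- simulate_dataset(des, seed = 20)
  out <- estimate_dependency(d)
  expect_equal(out$dependency$K, 72)
  expect_equal(out$dependency$L, 2484)
  expect_equal(out$dependency$K + out$dependency$L, choose(72, 2))
})

test_that("missing responses are excluded pairwise", {
  d <- small_dataset(n = 50, events = 4, seed = 21)
  m <- response_matrix(d)
  m[1:5, 1] <- NA
  f <- fit_unidimensional(m)
  r <- residual_matrix(m, f)
  expect_true(anyNA(r[, 1]) && !anyNA(r[, 2]))
  q3 <- q3_statistics(r, events = attr(m, "events"))
  expect_equal(q3$n_persons[1, 2], 45)
  expect_equal(q3$n_persons[2, 3], 50)
  expect_false(anyNA(q3$raw[upper.tri(q3$raw)]))
})

test_that("Q3 long export lists every unordered pair once", {
  d <- small_dataset(n = 40, events = 4, seed = 22)
  out <- estimate_dependency(d)
  long <- q3_long(out$q3)
  expect_equal(nrow(long), choose(12, 2))
  expect_equal(sum(long$same_event), 12)  # 4 events x C(3,2)
})
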