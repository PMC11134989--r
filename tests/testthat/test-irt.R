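test_that("response probability follows the fixed-guessing logistic curve", {
  expect_equal(response_probability(0, 0), 7 / 12)
  expect_equal(response_probability(1.3, 1.3, guessing = 0.25),
               0.25 + 0.75 * 0.5)
  # guessing floor in the low-trait limit
  expect_equal(response_probability(-30, 0), 1 / 6, tolerance = 1e-12)
  expect_equal(response_probability(2, 0), 1 / 6 + 5 / 6 * plogis(2))
  # numerically stable far into the tails
  expect_equal(response_probability(-700, 0), 1 / 6)
  expect_equal(response_probability(700, 0), 1)
  expect_error(response_probability(0, 0, guessing = 1), "guessing")
})

test_that("quadrature marginal likelihood matches dense-grid summation", {
  # 2-person x 2-item toys against brute force over a dense trait grid
  set.seed(11)
  for (k in 1:4) {
    m <- matrix(rbinom(4, 1, 0.5), 2, 2)
    if (all(m == m[1])) m[1, 1] <- 1 - m[1, 1]
    beta <- runif(2, -1, 1)
    s2 <- runif(1, 0.5, 2)
    ll_q <- quadrature_loglik(m, beta, s2)
    ll_d <- dense_grid_loglik(m, beta, s2)
    expect_equal(ll_q, ll_d, tolerance = 1e-4)  # 4 significant digits
  }
})

test_that("unidimensional fit recovers generating parameters", {
  des <- simulation_design(2000, conditions = "a")
  d <- simulate_dataset(des, generative_parameters(1, 0, beta = rep(0, 72)),
                        seed = 42)
  f <- fit_unidimensional(response_matrix(d))
  expect_true(f$converged)
  expect_lt(abs(f$sigma2 - 1), 0.15)
  expect_lt(mean(abs(f$beta)), 0.1)
  # EM never decreases the marginal log-likelihood
  expect_true(all(diff(f$loglik_trace) > -1e-6))
})

test_that("degenerate items pin at the box bound and are flagged extreme", {
  set.seed(2)
  m <- simulate_from_fit(rnorm(12), 1, 80, seed = 3)
  m[, 1] <- 1  # answered correctly by everyone
  f <- suppressWarnings(fit_unidimensional(m))
  expect_equal(unname(f$beta[1]), -f$control$beta_bound)
  expect_true(f$extreme[1])
  expect_false(any(f$extreme[-1]))
})

test_that("estimates are invariant to person replication and permutation", {
  set.seed(4)
  m <- simulate_from_fit(rnorm(9), 1, 60, seed = 5)
  f1 <- fit_unidimensional(m)
  f2 <- fit_unidimensional(rbind(m, m))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
  perm <- sample(ncol(m))
  f3 <- fit_unidimensional(m[, perm])
  expect_equal(f3$beta, f1$beta[perm], tolerance = 1e-6)
})

test_that("EAP scores are monotone in the response pattern", {
  set.seed(6)
  m <- simulate_from_fit(rep(0, 10), 1, 50, seed = 7)
  m[1, ] <- 1; m[2, ] <- 0
  f <- fit_unidimensional(m)
  expect_gt(f$eap[1], f$eap[2])
  # flipping any single 0 to 1 never decreases the EAP
  base <- m[3, , drop = FALSE]
  e0 <- eap_traits(f, base)$eap
  for (j in which(base == 0)) {
    b2 <- base; b2[j] <- 1
    expect_gte(eap_traits(f, b2)$eap, e0)
  }
})

test_that("EAP matches a dense-grid posterior mean and reflects guessing", {
  set.seed(8)
  m <- simulate_from_fit(rep(0, 12), 1, 40, seed = 9)
  f <- fit_unidimensional(m)
  e_fit <- eap_traits(f, m)
  e_dense <- eap_traits(f, m, n_quad = 20001)
  expect_lt(max(abs(e_fit$eap - e_dense$eap)), 1e-6)
  # half the items correct: because of guessing, an observed rate of 1/2 is
  # below the average success rate, so the matching trait is negative:
  # solve 1/6 + 5/6 plogis(t) = 1/2  =>  t = qlogis(0.4)
  half <- matrix(rep(c(1, 0), 6), 1)
  e_half <- eap_traits(f, half)$eap
  t_match <- qlogis(0.4)
  expect_lt(e_half, 0)
  expect_gt(e_half, t_match)       # shrunk toward the prior mean 0
  expect_equal(e_half, t_match, tolerance = 0.35)
})

test_that("bifactor fit recovers specific variance and nests the 1-D model", {
  des <- simulation_design(2000, conditions = "a")
  d <- simulate_dataset(des, generative_parameters(1, 2), seed = 11)
  m <- response_matrix(d)
  bf <- fit_bifactor(m)
  expect_lt(abs(bf$sigma2_specific - 2), 0.4)
  expect_lt(abs(bf$sigma2_general - 1), 0.3)
  expect_true(all(diff(bf$loglik_trace) > -1e-6))
  uf <- fit_unidimensional(m)
  expect_gte(bf$loglik, uf$loglik)

  # under local independence the specific variance collapses
  d0 <- simulate_dataset(des, generative_parameters(1, 0), seed = 12)
  bf0 <- fit_bifactor(response_matrix(d0))
  expect_lte(bf0$sigma2_specific, 0.1)

  # events of a single item are rejected
  expect_error(fit_bifactor(m[, 1:4], events = c("a", "a", "b", "c")),
               "two items")
})

test_that("simulate_from_fit is the exact generative counterpart", {
  beta <- c(-1, 0, 1)
  # specific variance 0 equals direct sampling from the 1-D model
  p_item <- vapply(beta, function(b) {
    integrate(function(t) response_probability(t, b) * dnorm(t), -10, 10)$value
  }, numeric(1))
  m <- simulate_from_fit(beta, 1, 50000, seed = 13)
  expect_equal(unname(colMeans(m)), p_item, tolerance = 0.02)

  expect_identical(simulate_from_fit(beta, 1, 20, seed = 1),
                   simulate_from_fit(beta, 1, 20, seed = 1))
  expect_equal(nrow(simulate_from_fit(beta, 1, 0)), 0)
  expect_warning(simulate_from_fit(beta, 1, 5, extreme = c(TRUE, FALSE, FALSE)),
                 "substitute")
  expect_error(simulate_from_fit(beta, -1, 5), ">= 0")
})
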