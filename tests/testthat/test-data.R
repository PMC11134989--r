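test_that("read/write round-trip is lossless and order-invariant", {
  tr <- tiny_trials()
  d1 <- response_dataset(tr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(d1, path)
  d2 <- read_trials(path)
  expect_equal(d1$trials, d2$trials)
  expect_equal(d1$items, d2$items)

  # permuting input rows yields the identical dataset after canonical sorting
  set.seed(3)
  for (k in 1:5) {
    d3 <- response_dataset(tr[sample(nrow(tr)), ])
    expect_identical(d3$trials, d1$trials)
  }

  # property: round-trip on random designs
  for (seed in 1:3) {
    des <- simulation_design(sample(3:8, 1), conditions = c("x", "y"),
                             events = sample(2:5, 1))
    d <- withr::with_seed(seed, simulate_dataset(des, seed = seed))
    p <- withr::local_tempfile(fileext = ".csv")
    write_trials(d, p)
    expect_equal(read_trials(p)$trials, d$trials)
  }
})

test_that("dataset validation rejects malformed input with informative errors", {
  tr <- tiny_trials()
  expect_error(response_dataset(rbind(tr, tr[3, ])),
               "duplicated.*p1.*e01_i3")
  tr2 <- tr; tr2$response[4] <- 2
  expect_error(response_dataset(tr2), "non-binary")
  tr3 <- tr; tr3$event[7] <- "e02"  # item e01_i1 now maps to two events
  expect_error(response_dataset(tr3), "more than one event")
  tr4 <- tr; tr4$condition <- rep(c("a", "b", "c"), 4)
  expect_error(response_dataset(tr4), "two levels|two conditions")
  expect_error(response_dataset(tr[-1, ]), "same item set")
})

test_that("response_matrix carries events and condition in canonical order", {
  d <- response_dataset(tiny_trials())
  m <- response_matrix(d)
  expect_equal(dim(m), c(2, 6))
  expect_equal(unname(attr(m, "events")),
               sprintf("e%02d", rep(1:2, each = 3)))
  expect_equal(unname(attr(m, "condition")), c("a", "b"))
  expect_true(all(m %in% 0:1))
})

test_that("performance summary computes person and condition aggregates", {
  tr <- tiny_trials()
  tr$response <- c(1, 0, 0, 1, 0, 0, rep(1, 6))  # p1: 2/6, p2: 6/6
  s <- summarize_performance(response_dataset(tr))
  expect_equal(s$per_person$proportion, c(2 / 6, 1))
  expect_equal(s$per_condition$mean, c(2 / 6, 1))

  # one person, responses 1 0 0 1 -> 0.5; two persons .2/.4 -> mean .3
  des <- simulation_design(2, conditions = "a", events = 5, items_per_event = 2)
  d <- simulate_dataset(des, seed = 1)
  d$trials$response <- c(rep(c(1, 0), 5), rep(c(0, 1, 0, 0, 0), 2))
  s2 <- summarize_performance(d)
  expect_equal(s2$per_person$proportion, c(0.5, 0.2))

  # invariance to row order
  d2 <- response_dataset(d$trials[sample(nrow(d$trials)), ])
  expect_equal(summarize_performance(d2)$per_condition,
               s2$per_condition)

  # all-correct boundary
  tr_all <- tiny_trials(); tr_all$response <- 1
  expect_equal(summarize_performance(response_dataset(tr_all))$per_person$proportion,
               c(1, 1))
})

test_that("signed-rank test matches the all-positive and symmetric cases", {
  # all proportions above chance, no ties: V = n(n+1)/2
  x <- 1 / 6 + (1:10) / 20
  w <- wilcoxon_vs_chance(x)
  expect_equal(w$V, 55)
  expect_lt(w$p_value, 0.01)
  expect_lte(w$r, 1)

  # symmetric around chance: p ~ 0.5 under the normal approximation
  x2 <- 1 / 6 + c(-5:-1, 1:5) / 30
  w2 <- wilcoxon_vs_chance(x2)
  expect_equal(w2$p_value, 0.5, tolerance = 0.12)

  expect_error(wilcoxon_vs_chance(rep(1 / 6, 8)), "zero")
  expect_error(wilcoxon_vs_chance(c(0.2, 0.3)), "at least 5")
})

test_that("signed-rank implementation agrees with stats::wilcox.test", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(5:8, 1)
    x <- round(runif(n, 0, 1), 2)     # rounding induces occasional ties
    x <- x[x != 1 / 6]
    if (length(x) < 5) next
    mine <- wilcoxon_vs_chance(x, chance = 1 / 6, alternative = "greater")
    ref <- suppressWarnings(
      wilcox.test(x, mu = 1 / 6, alternative = "greater",
                  exact = FALSE, correct = TRUE))
    expect_equal(mine$V, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("signed-rank test holds its nominal level under the null", {
  set.seed(7)
  rej <- replicate(1000, {
    x <- 1 / 6 + rnorm(30, 0, 0.05)
    wilcoxon_vs_chance(x)$p_value <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})
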