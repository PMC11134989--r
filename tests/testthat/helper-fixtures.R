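# shared fixture builders (everything is generated in code)

# small long-format trials table: 2 persons x (2 events x 3 items)
tiny_trials <- function() {
  items <- sprintf("e%02d_i%d", rep(1:2, each = 3), rep(1:3, 2))
  events <- sprintf("e%02d", rep(1:2, each = 3))
  data.frame(
    person = rep(c("p1", "p2"), each = 6),
    condition = rep(c("a", "b"), each = 6),
    event = rep(events, 2),
    item = rep(items, 2),
    association = rep(c("ab", "bc", "ca"), 4),
    response = c(1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 0, 1))
}

# single-condition simulated dataset at a reduced design
small_dataset <- function(n = 60, events = 6, sigma2_specific = 0, seed = 1,
                          sigma2_general = 1) {
  des <- simulation_design(n, conditions = "a", events = events)
  simulate_dataset(des,
                   generative_parameters(sigma2_general = sigma2_general,
                                         sigma2_specific = sigma2_specific),
                   seed = seed)
}

# marginal log-likelihood of the unidimensional model at given parameters,
# by direct summation over a dense trait grid (independent oracle)
dense_grid_loglik <- function(m, beta, sigma2, guessing = 1 / 6,
                              n_grid = 200001, lim = 8) {
  grid <- seq(-lim, lim, length.out = n_grid)
  w <- dnorm(grid, 0, sqrt(sigma2))
  w <- w / sum(w)
  sum(vapply(seq_len(nrow(m)), function(i) {
    lik <- rep(1, n_grid)
    for (j in seq_len(ncol(m))) {
      p <- guessing + (1 - guessing) * plogis(grid - beta[j])
      lik <- lik * (if (m[i, j] == 1) p else 1 - p)
    }
    log(sum(w * lik))
  }, numeric(1)))
}

# marginal log-likelihood of the fitted model evaluated at supplied
# parameters (one E-step, no M-step applied before the first trace entry)
quadrature_loglik <- function(m, beta, sigma2, guessing = 1 / 6) {
  ctl <- irt_control(max_iter = 1)
  f <- suppressWarnings(fit_unidimensional(m, guessing, ctl,
                                           init = list(beta = beta,
                                                       sigma2 = sigma2)))
  f$loglik_trace[1]
}
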