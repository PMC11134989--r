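#' Item response probability of the fixed-guessing logistic model
#'
#' `P(u = 1) = c + (1 - c) * exp(theta - beta) / (1 + exp(theta - beta))`:
#' a three-parameter logistic model with discrimination fixed to 1 and the
#' guessing parameter fixed to the stochastic guessing probability of the
#' forced-choice test. Numerically stable over the full double range of
#' `theta - beta`.
#'
#' @param theta latent trait value(s) — for the bifactor model, the total
#'   trait `theta + eta`.
#' @param beta item difficulty value(s).
#' @param guessing guessing probability in `[0, 1)`; default 1/6.
#' @return success probabilities, recycled over `theta` and `beta`.
#' @export
response_probability <- function(theta, beta, guessing = 1 / 6) {
  if (any(guessing < 0 | guessing >= 1)) stopf("guessing must be in [0, 1)")
  guessing + (1 - guessing) * stats::plogis(theta - beta)
}

#' Estimation settings for the EM fitters
#'
#' The latent trait is integrated over a fixed, equally spaced quadrature grid
#' with normalised normal prior weights; trapezoid-type quadrature on this grid
#' is spectrally accurate for the smooth posterior integrands involved, and
#' keeping the grid fixed across EM iterations makes the marginal
#' log-likelihood monotone by construction.
#'
#' @param n_quad quadrature points for the unidimensional trait (default 61).
#' @param theta_lim half-width of the unidimensional grid in logits.
#' @param n_quad_general,n_quad_specific points for the bifactor outer
#'   (general) and inner (event-specific) grids (defaults 61 and 21; the
#'   general-trait posterior is narrow when many items load on it, so the
#'   outer grid matches the unidimensional one).
#' @param general_lim,specific_lim half-widths of the bifactor grids.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param beta_bound difficulty box bound in logits; estimates pinned at the
#'   bound are flagged extreme.
#' @return list of class `irt_control`.
#' @export
irt_control <- function(n_quad = 61L, theta_lim = 8,
                        n_quad_general = 61L, n_quad_specific = 21L,
                        general_lim = 8, specific_lim = 6,
                        max_iter = 500L, tol = 1e-4, beta_bound = 15) {
  stopifnot(n_quad >= 5, n_quad_general >= 5, n_quad_specific >= 5,
            max_iter >= 1, tol > 0, beta_bound > 0)
  structure(list(n_quad = as.integer(n_quad), theta_lim = theta_lim,
                 n_quad_general = as.integer(n_quad_general),
                 n_quad_specific = as.integer(n_quad_specific),
                 general_lim = general_lim, specific_lim = specific_lim,
                 max_iter = as.integer(max_iter), tol = tol,
                 beta_bound = beta_bound),
            class = "irt_control")
}

check_matrix <- function(m, allow_missing = TRUE) {
  if (inherits(m, "response_dataset")) m <- response_matrix(m)
  if (!is.matrix(m)) stopf("expected a matrix or response_dataset")
  vals <- m[!is.na(m)]
  if (!all(vals %in% c(0, 1))) stopf("responses must be binary 0/1")
  if (!allow_missing && anyNA(m)) stopf("missing responses are not supported here")
  if (any(rowSums(!is.na(m)) == 0)) stopf("person with no observed responses")
  if (any(colSums(!is.na(m)) == 0)) stopf("item with no observed responses")
  m
}

init_beta <- function(m, guessing, bound) {
  p <- colMeans(m, na.rm = TRUE)
  # invert the marginal success probability at trait 0
  q <- pmin(pmax((p - guessing) / (1 - guessing), 1e-3), 1 - 1e-3)
  pmin(pmax(-stats::qlogis(q), -bound), bound)
}

#' Fit the unidimensional fixed-guessing model by marginal maximum likelihood
#'
#' Estimates all item difficulties and the latent trait variance (trait mean
#' fixed at 0, discrimination fixed at 1, guessing fixed) by an EM algorithm
#' over a quadrature grid. Difficulty estimates that hit the box bound are
#' flagged extreme. Expected a posteriori (EAP) trait scores and posterior SDs
#' are returned for every person.
#'
#' @param m binary person-by-item matrix (or a [response_dataset()]).
#'   `NA` entries are treated as missing at random.
#' @param guessing fixed guessing probability (default 1/6).
#' @param control an [irt_control()].
#' @param init optional warm start: list with `beta` and/or `sigma2` (e.g. the
#'   generating parameters inside a parametric bootstrap); affects only the
#'   number of EM iterations, not the estimates.
#' @return object of class `unidimensional_fit`: `beta` (named difficulties),
#'   `sigma2`, `extreme` (logical flags), `loglik`, `loglik_trace`, `eap`,
#'   `psd`, `converged`, `n_iter`, plus `guessing` and `control`.
#' @export
fit_unidimensional <- function(m, guessing = 1 / 6, control = irt_control(),
                               init = NULL) {
  m <- check_matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stopf("need at least 2 persons and 2 items")
  A <- m; A[is.na(A)] <- 0
  M <- 1 - is.na(m)
  b0 <- init$beta %||% init_beta(m, guessing, control$beta_bound)
  b0 <- pmin(pmax(unname(b0), -control$beta_bound), control$beta_bound)
  s0 <- sqrt(init$sigma2 %||% 1)
  fit <- em_unidimensional(A, M, guessing, control$n_quad, control$theta_lim,
                           control$tol, control$max_iter, control$beta_bound,
                           b0, s0)
  if (!fit$converged)
    warning("EM did not converge within ", control$max_iter, " iterations")
  beta <- stats::setNames(as.numeric(fit$beta), colnames(m))
  structure(list(beta = beta,
                 sigma2 = fit$sigma2,
                 extreme = abs(beta) >= control$beta_bound - 1e-6,
                 loglik = fit$loglik,
                 loglik_trace = as.numeric(fit$loglik_trace),
                 eap = stats::setNames(as.numeric(fit$eap), rownames(m)),
                 psd = stats::setNames(as.numeric(fit$psd), rownames(m)),
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 guessing = guessing,
                 control = control),
            class = "unidimensional_fit")
}

#' @export
print.unidimensional_fit <- function(x, ...) {
  cat(sprintf("<unidimensional_fit> %d items, sigma2 = %.3f, logLik = %.2f (%s, %d EM iterations)\n",
              length(x$beta), x$sigma2, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (any(x$extreme))
    cat(sprintf("  %d difficulty estimate(s) flagged extreme\n", sum(x$extreme)))
  invisible(x)
}

#' Expected a posteriori trait scores
#'
#' Posterior mean and SD of the latent trait under the fitted
#' `N(0, sigma2)` prior, computed on a quadrature grid. This is the scoring
#' rule used to form model residuals; it is exposed separately so other rules
#' can be swapped in.
#'
#' @param fit a [fit_unidimensional()] result.
#' @param m binary matrix of the persons to score (defaults to the persons the
#'   fit already scored); `NA` allowed.
#' @param n_quad optional grid refinement (default: the fit's control).
#' @return data.frame with columns `eap` and `psd`.
#' @export
eap_traits <- function(fit, m = NULL, n_quad = NULL) {
  stopifnot(inherits(fit, "unidimensional_fit"))
  if (is.null(m))
    return(data.frame(eap = fit$eap, psd = fit$psd))
  m <- check_matrix(m)
  if (ncol(m) != length(fit$beta)) stopf("item count mismatch with fit")
  nq <- n_quad %||% fit$control$n_quad
  nodes <- seq(-fit$control$theta_lim, fit$control$theta_lim, length.out = nq)
  lw <- stats::dnorm(nodes, 0, sqrt(fit$sigma2), log = TRUE)
  lw <- lw - max(lw) - log(sum(exp(lw - max(lw))))
  P <- response_probability(outer(rep(1, length(fit$beta)), nodes),
                            fit$beta, fit$guessing)  # J x Q
  A <- m; A[is.na(A)] <- 0
  Mk <- 1 - is.na(m)
  LL <- A %*% log(P) + (Mk - A) %*% log(1 - P)
  LL <- sweep(LL, 2, lw, "+")
  mx <- apply(LL, 1, max)
  W <- exp(LL - mx)
  W <- W / rowSums(W)
  eap <- as.numeric(W %*% nodes)
  m2 <- as.numeric(W %*% nodes^2)
  data.frame(eap = eap, psd = sqrt(pmax(m2 - eap^2, 0)),
             row.names = rownames(m))
}

#' Fit the bifactor extension with equality-constrained specific variances
#'
#' Extends the unidimensional model by one latent trait per event:
#' `P(u = 1) = c + (1 - c) * plogis(theta + eta_e - beta_j)` with
#' `theta ~ N(0, sigma2_general)` and `eta_e` i.i.d.
#' `N(0, sigma2_specific)` — a single specific variance shared by all events
#' (the equality constraint motivated by randomly generated events). The
#' marginal likelihood uses bifactor dimension reduction: an outer quadrature
#' over the general trait and independent inner quadratures per event, never a
#' full joint grid.
#'
#' @param m complete binary person-by-item matrix (or [response_dataset()]).
#' @param events item -> event map (character/factor, one entry per column);
#'   taken from the matrix attribute or dataset when omitted.
#' @param guessing fixed guessing probability.
#' @param control an [irt_control()].
#' @param init optional warm start: list with any of `beta`, `sigma2_general`,
#'   `sigma2_specific`.
#' @return object of class `bifactor_fit` with `beta`, `sigma2_general`,
#'   `sigma2_specific`, `extreme`, `loglik`, `loglik_trace`, `converged`.
#' @export
fit_bifactor <- function(m, events = NULL, guessing = 1 / 6,
                         control = irt_control(), init = NULL) {
  if (inherits(m, "response_dataset") && is.null(events)) {
    mm <- response_matrix(m)
    events <- attr(mm, "events")
    m <- mm
  }
  events <- events %||% attr(m, "events")
  if (is.null(events)) stopf("an item -> event map is required")
  m <- check_matrix(m, allow_missing = FALSE)
  if (length(events) != ncol(m)) stopf("event map length mismatch")
  ev <- as.integer(factor(as.character(events))) - 1L
  if (min(table(ev)) < 2) stopf("every event needs at least two items")
  b0 <- init$beta %||% init_beta(m, guessing, control$beta_bound)
  b0 <- pmin(pmax(unname(b0), -control$beta_bound), control$beta_bound)
  fit <- em_bifactor(matrix(as.integer(m), nrow(m)), ev, guessing,
                     control$n_quad_general, control$general_lim,
                     control$n_quad_specific, control$specific_lim,
                     control$tol, control$max_iter, control$beta_bound,
                     b0, sqrt(init$sigma2_general %||% 1),
                     sqrt(init$sigma2_specific %||% 0.25))
  if (!fit$converged)
    warning("EM did not converge within ", control$max_iter, " iterations")
  beta <- stats::setNames(as.numeric(fit$beta), colnames(m))
  structure(list(beta = beta,
                 sigma2_general = fit$sigma2_general,
                 sigma2_specific = fit$sigma2_specific,
                 extreme = abs(beta) >= control$beta_bound - 1e-6,
                 events = stats::setNames(as.character(events), colnames(m)),
                 loglik = fit$loglik,
                 loglik_trace = as.numeric(fit$loglik_trace),
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 guessing = guessing,
                 control = control),
            class = "bifactor_fit")
}

#' @export
print.bifactor_fit <- function(x, ...) {
  cat(sprintf("<bifactor_fit> %d items, sigma2_general = %.3f, sigma2_specific = %.3f, logLik = %.2f (%s)\n",
              length(x$beta), x$sigma2_general, x$sigma2_specific, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (any(x$extreme))
    cat(sprintf("  %d difficulty estimate(s) flagged extreme\n", sum(x$extreme)))
  invisible(x)
}

#' Simulate a response matrix from fitted (or specified) model parameters
#'
#' Exact generative counterpart of the fitted model: persons are drawn from
#' `N(0, sigma2_general)` (plus independent `N(0, sigma2_specific)` event
#' traits when a specific variance is given) and responses from the
#' fixed-guessing logistic model. This is the sampling step of the parametric
#' bootstrap.
#'
#' @param beta difficulty vector (named or not).
#' @param sigma2_general general trait variance.
#' @param n number of persons; `n = 0` yields an empty matrix.
#' @param guessing fixed guessing probability.
#' @param sigma2_specific event-specific variance (default 0 = unidimensional).
#' @param events item -> event map, required when `sigma2_specific > 0`.
#' @param seed integer seed, or `NULL`.
#' @param extreme optional logical flags; if any are `TRUE` a warning reminds
#'   the caller to substitute extreme parameters first.
#' @return binary matrix (`n` x items).
#' @export
simulate_from_fit <- function(beta, sigma2_general, n, guessing = 1 / 6,
                              sigma2_specific = 0, events = NULL, seed = NULL,
                              extreme = NULL) {
  if (sigma2_general < 0 || sigma2_specific < 0) stopf("variances must be >= 0")
  if (!is.null(extreme) && any(extreme))
    warning("extreme item parameters present; substitute them before bootstrapping")
  J <- length(beta)
  if (n == 0) return(matrix(numeric(0), 0, J, dimnames = list(NULL, names(beta))))
  with_seed(seed, {
    theta <- stats::rnorm(n, 0, sqrt(sigma2_general))
    tot <- matrix(theta, n, J)
    if (sigma2_specific > 0) {
      if (is.null(events)) stopf("events required when sigma2_specific > 0")
      ev <- as.integer(factor(as.character(events)))
      eta <- matrix(stats::rnorm(n * max(ev), 0, sqrt(sigma2_specific)), n)
      tot <- tot + eta[, ev, drop = FALSE]
    }
    p <- response_probability(tot, matrix(beta, n, J, byrow = TRUE), guessing)
    matrix(stats::rbinom(n * J, 1L, p), n, J,
           dimnames = list(NULL, names(beta)))
  })
}
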