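#' Settings for the parametric bootstrap
#'
#' @param B number of bootstrap samples (default 1000).
#' @param seed integer seed for the whole bootstrap; per-sample seeds are
#'   derived from it so results do not depend on the worker count.
#' @param refit refit the measurement model on every bootstrap sample before
#'   computing D (default `TRUE`, the canonical parametric bootstrap). The
#'   fast no-refit mode evaluates residuals at the generating parameters and
#'   is for exploration only.
#' @param smooth add-one smoothing of the p-value
#'   (`p = (1 + exceedances) / (B + 1)`), avoiding p = 0 at finite B.
#' @param workers parallel workers for the bootstrap loop (forked; 1 = serial).
#' @param max_retries redraws allowed for bootstrap samples whose fit fails.
#' @return list of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(B = 1000L, seed = NULL, refit = TRUE,
                               smooth = TRUE, workers = 1L,
                               max_retries = 10L) {
  stopifnot(B >= 1, workers >= 1, max_retries >= 0)
  structure(list(B = as.integer(B), seed = seed, refit = isTRUE(refit),
                 smooth = isTRUE(smooth), workers = as.integer(workers),
                 max_retries = as.integer(max_retries)),
            class = "bootstrap_settings")
}

#' Substitute extreme item parameters by empirical-distribution draws
#'
#' Flagged difficulties are replaced by independent draws from the empirical
#' distribution of the unflagged difficulties (inverse CDF with linear
#' interpolation between order statistics); unflagged parameters are returned
#' unchanged. Extreme difficulties would otherwise produce bootstrap items
#' with (near-)constant responses, which breaks refitting.
#'
#' @param beta difficulty vector.
#' @param extreme logical flags, same length as `beta`.
#' @param seed integer seed, or `NULL`.
#' @return `beta` with flagged entries replaced.
#' @export
substitute_extreme_parameters <- function(beta, extreme, seed = NULL) {
  stopifnot(length(beta) == length(extreme))
  if (!any(extreme)) return(beta)
  pool <- beta[!extreme]
  if (!length(pool)) stopf("all parameters are flagged extreme")
  with_seed(seed, {
    u <- stats::runif(sum(extreme))
    beta[extreme] <- as.numeric(stats::quantile(pool, u, type = 7, names = FALSE))
  })
  beta
}

smooth_p <- function(k, B, smooth) {
  if (smooth) (1 + k) / (B + 1) else max(k, 1L) / B
}

boot_lapply <- function(n, workers, fun) {
  if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(seq_len(n), fun, mc.cores = workers)
  else
    lapply(seq_len(n), fun)
}

# one bootstrap replicate of the single-condition pipeline; returns D or NA
boot_D_once <- function(beta, sigma2, n, guessing, events, control, refit,
                        seed, max_retries) {
  for (try in 0:max_retries) {
    s <- if (try == 0) seed else with_seed(seed + try, sample.int(.Machine$integer.max - 1L, 1))
    u <- simulate_from_fit(beta, sigma2, n, guessing, seed = s)
    d <- tryCatch({
      if (refit) {
        f <- suppressWarnings(fit_unidimensional(
          u, guessing, control, init = list(beta = beta, sigma2 = sigma2)))
        res <- residual_matrix(u, f)
      } else {
        f <- structure(list(beta = beta, sigma2 = sigma2, guessing = guessing,
                            control = control),
                       class = "unidimensional_fit")
        res <- residual_matrix(u, f, eap = eap_traits(f, u)$eap)
      }
      dependency_D(q3_statistics(res, events = events))$D
    }, error = function(e) NA_real_)
    if (!is.na(d)) return(d)
  }
  NA_real_
}

#' Parametric-bootstrap test of D against zero
#'
#' Fits the unidimensional fixed-guessing model, computes the observed D, and
#' compares it with the distribution of D over `B` datasets simulated from the
#' fitted model — which embodies local independence, hence D = 0. Extreme
#' difficulty estimates are substituted before simulating. The p-value is
#' two-tailed around 0: `p = (1 + #{|D*| >= |D_obs|}) / (B + 1)`; the SE is
#' the SD of the bootstrap distribution.
#'
#' @param data single-condition [response_dataset()] or binary matrix with an
#'   `events` attribute.
#' @param settings a [bootstrap_settings()].
#' @param guessing fixed guessing probability.
#' @param control an [irt_control()].
#' @return object of class `bootstrap_result`: `observed`
#'   (a `dependency_estimate`), `boot` (vector of D*), `se`, `p_value`,
#'   `n_failed`, `n_substituted`, `fit`, `settings`.
#' @export
test_D <- function(data, settings = bootstrap_settings(), guessing = 1 / 6,
                   control = irt_control()) {
  stopifnot(inherits(settings, "bootstrap_settings"))
  m <- if (inherits(data, "response_dataset")) response_matrix(data) else data
  events <- attr(m, "events")
  if (is.null(events)) stopf("an item -> event map is required")
  obs <- estimate_dependency(m, guessing, control)
  seeds <- derive_seeds(settings$seed, settings$B + 1L)
  beta0 <- substitute_extreme_parameters(obs$fit$beta, obs$fit$extreme,
                                         seed = seeds[settings$B + 1L])
  boot <- unlist(boot_lapply(settings$B, settings$workers, function(b) {
    boot_D_once(beta0, obs$fit$sigma2, nrow(m), guessing, events, control,
                settings$refit, seeds[b], settings$max_retries)
  }))
  ok <- !is.na(boot)
  k <- sum(abs(boot[ok]) >= abs(obs$dependency$D))
  structure(list(observed = obs$dependency,
                 boot = boot,
                 se = stats::sd(boot[ok]),
                 p_value = smooth_p(k, sum(ok), settings$smooth),
                 n_failed = sum(!ok),
                 n_substituted = sum(obs$fit$extreme),
                 fit = obs$fit,
                 settings = settings),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Parametric bootstrap test of D = 0: D = %.4f, SE = %.4f, two-tailed p = %.4g (B = %d)\n",
              x$observed$D, x$se, x$p_value, length(x$boot)))
  invisible(x)
}

#' Parametric-bootstrap test of a between-condition difference in D
#'
#' Fits the bifactor model (equality-constrained event-specific variance)
#' separately per condition, substitutes extreme difficulties, and simulates
#' `B` dataset pairs from a null in which each condition keeps its own
#' difficulties and general variance but both share the smaller of the two
#' estimated specific variances — a model with dependency present but no
#' difference in dependency. Each simulated condition runs through the full
#' single-condition pipeline (unidimensional fit, Q3, D). One-tailed
#' `p = (1 + #{D*_diff >= D_obs_diff}) / (B + 1)` in the hypothesised
#' direction.
#'
#' @param data_a,data_b single-condition datasets (or matrices with `events`).
#'   The hypothesis is that `data_a` shows the larger dependency when
#'   `direction = "a_greater"` (the default), i.e. `D_diff = D_A - D_B`.
#' @param settings a [bootstrap_settings()].
#' @param direction `"a_greater"` or `"b_greater"`.
#' @param guessing fixed guessing probability.
#' @param control an [irt_control()].
#' @return object of class `diff_bootstrap_result`: `observed_diff`, `D_a`,
#'   `D_b`, `boot` (D*_diff), `se`, `p_value`, `null_sigma2_specific`,
#'   per-condition bifactor fits, `settings`.
#' @export
test_D_difference <- function(data_a, data_b, settings = bootstrap_settings(),
                              direction = c("a_greater", "b_greater"),
                              guessing = 1 / 6, control = irt_control()) {
  direction <- match.arg(direction)
  stopifnot(inherits(settings, "bootstrap_settings"))
  ma <- if (inherits(data_a, "response_dataset")) response_matrix(data_a) else data_a
  mb <- if (inherits(data_b, "response_dataset")) response_matrix(data_b) else data_b
  ev_a <- attr(ma, "events"); ev_b <- attr(mb, "events")
  if (is.null(ev_a) || is.null(ev_b)) stopf("item -> event maps are required")
  if (ncol(ma) != ncol(mb)) stopf("conditions must share the same design")

  obs_a <- estimate_dependency(ma, guessing, control)
  obs_b <- estimate_dependency(mb, guessing, control)
  d_obs <- obs_a$dependency$D - obs_b$dependency$D
  sgn <- if (direction == "a_greater") 1 else -1

  bf_a <- fit_bifactor(ma, ev_a, guessing, control,
                       init = list(beta = obs_a$fit$beta))
  bf_b <- fit_bifactor(mb, ev_b, guessing, control,
                       init = list(beta = obs_b$fit$beta))
  s2_null <- min(bf_a$sigma2_specific, bf_b$sigma2_specific)

  seeds <- derive_seeds(settings$seed, 2L * settings$B + 2L)
  beta_a <- substitute_extreme_parameters(bf_a$beta, bf_a$extreme,
                                          seed = seeds[2L * settings$B + 1L])
  beta_b <- substitute_extreme_parameters(bf_b$beta, bf_b$extreme,
                                          seed = seeds[2L * settings$B + 2L])

  one_diff <- function(b) {
    da <- boot_D_diff_arm(beta_a, bf_a$sigma2_general, s2_null, nrow(ma),
                          guessing, ev_a, control, settings$refit,
                          seeds[2L * b - 1L], settings$max_retries)
    db <- boot_D_diff_arm(beta_b, bf_b$sigma2_general, s2_null, nrow(mb),
                          guessing, ev_b, control, settings$refit,
                          seeds[2L * b], settings$max_retries)
    da - db
  }
  boot <- unlist(boot_lapply(settings$B, settings$workers, one_diff))
  ok <- !is.na(boot)
  k <- sum(sgn * boot[ok] >= sgn * d_obs)
  structure(list(observed_diff = d_obs,
                 D_a = obs_a$dependency$D,
                 D_b = obs_b$dependency$D,
                 boot = boot,
                 se = stats::sd(boot[ok]),
                 p_value = smooth_p(k, sum(ok), settings$smooth),
                 null_sigma2_specific = s2_null,
                 direction = direction,
                 n_failed = sum(!ok),
                 n_substituted = c(a = sum(bf_a$extreme), b = sum(bf_b$extreme)),
                 fit_a = bf_a, fit_b = bf_b,
                 settings = settings),
            class = "diff_bootstrap_result")
}

# one bootstrap arm for the difference test: simulate from the bifactor null
# (shared specific variance), then the unidimensional pipeline
boot_D_diff_arm <- function(beta, sigma2_g, sigma2_s, n, guessing, events,
                            control, refit, seed, max_retries) {
  for (try in 0:max_retries) {
    s <- if (try == 0) seed else with_seed(seed + try, sample.int(.Machine$integer.max - 1L, 1))
    u <- simulate_from_fit(beta, sigma2_g, n, guessing,
                           sigma2_specific = sigma2_s, events = events,
                           seed = s)
    d <- tryCatch({
      f <- suppressWarnings(fit_unidimensional(
        u, guessing, control,
        init = list(beta = beta, sigma2 = sigma2_g + sigma2_s)))
      res <- residual_matrix(u, f)
      dependency_D(q3_statistics(res, events = events))$D
    }, error = function(e) NA_real_)
    if (!is.na(d)) return(d)
  }
  NA_real_
}

#' @export
print.diff_bootstrap_result <- function(x, ...) {
  cat(sprintf("Parametric bootstrap test of D_a - D_b (%s): D_diff = %.4f (D_a = %.4f, D_b = %.4f), SE = %.4f, one-tailed p = %.4g\n",
              x$direction, x$observed_diff, x$D_a, x$D_b, x$se, x$p_value))
  cat(sprintf("  null event-specific variance = %.4f (smaller of the two fits)\n",
              x$null_sigma2_specific))
  invisible(x)
}
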