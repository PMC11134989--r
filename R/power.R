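#' Configuration of a simulation-based a priori power analysis
#'
#' Power for the one-tailed between-condition difference test is estimated by
#' simulating replicate experiment pairs — one condition at the baseline
#' event-specific trait variance, the other at baseline + `delta` — and
#' counting rejections of [test_D_difference()] at level `alpha`.
#'
#' @param design a [simulation_design()] template (two conditions); persons
#'   per condition is overridden by the candidate sample size.
#' @param baseline_variance event-specific trait variance of the weaker
#'   condition (default 2).
#' @param delta variance difference under the alternative (default 1, a
#'   medium difference; 0.75 is small-to-medium).
#' @param sigma2_general general trait variance (default 1).
#' @param difficulty_mean,difficulty_sd item difficulty distribution.
#' @param alpha one-tailed significance level (default .05).
#' @param replicates simulated experiment pairs per sample size (default 250).
#' @param bootstrap_samples bootstrap samples per replicate (default 199;
#'   rejection decisions at alpha = .05 are stable from B = 199 on, and the
#'   bootstrap-within-power cost is quadratic).
#' @param seed integer seed.
#' @param workers parallel workers over replicates.
#' @return list of class `power_config`.
#' @export
power_config <- function(design = simulation_design(),
                         baseline_variance = 2, delta = 1,
                         sigma2_general = 1,
                         difficulty_mean = 0, difficulty_sd = 1,
                         alpha = 0.05, replicates = 250L,
                         bootstrap_samples = 199L,
                         seed = NULL, workers = 1L) {
  stopifnot(inherits(design, "simulation_design"),
            baseline_variance >= 0, delta >= 0,
            alpha > 0, alpha < 1, replicates >= 1, bootstrap_samples >= 1)
  if (length(design$conditions) != 2L)
    stopf("the power analysis needs a two-condition design")
  structure(list(design = design, baseline_variance = baseline_variance,
                 delta = delta, sigma2_general = sigma2_general,
                 difficulty_mean = difficulty_mean,
                 difficulty_sd = difficulty_sd,
                 alpha = alpha, replicates = as.integer(replicates),
                 bootstrap_samples = as.integer(bootstrap_samples),
                 seed = seed, workers = as.integer(workers)),
            class = "power_config")
}

power_one_replicate <- function(config, n_per_condition, seed,
                                control = irt_control()) {
  design <- config$design
  design$persons_per_condition <- as.integer(n_per_condition)
  params <- generative_parameters(
    sigma2_general = config$sigma2_general,
    sigma2_specific = c(config$baseline_variance + config$delta,
                        config$baseline_variance),
    difficulty_mean = config$difficulty_mean,
    difficulty_sd = config$difficulty_sd)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2))
  data <- simulate_dataset(design, params, seed = seeds[1])
  parts <- split_conditions(data)
  res <- tryCatch(
    suppressWarnings(test_D_difference(
      parts[[1]], parts[[2]],
      settings = bootstrap_settings(B = config$bootstrap_samples,
                                    seed = seeds[2]),
      direction = "a_greater", guessing = design$guessing,
      control = control)),
    error = function(e) NULL)
  if (is.null(res)) return(NA)
  res$p_value <= config$alpha
}

#' Estimate power of the difference test at one sample size
#'
#' @param config a [power_config()].
#' @param n_per_condition participants per condition.
#' @param control an [irt_control()].
#' @return one-row data.frame: `n_per_condition`, `power`, exact 95% binomial
#'   `ci_low`/`ci_high`, `replicates_used`, `replicates_failed`.
#' @export
estimate_power <- function(config, n_per_condition,
                           control = irt_control()) {
  stopifnot(inherits(config, "power_config"))
  seeds <- derive_seeds(config$seed, config$replicates)
  rej <- unlist(boot_lapply(config$replicates, config$workers, function(r) {
    power_one_replicate(config, n_per_condition, seeds[r], control)
  }))
  ok <- !is.na(rej)
  k <- sum(rej[ok]); n <- sum(ok)
  ci <- stats::binom.test(k, n)$conf.int
  data.frame(n_per_condition = n_per_condition,
             power = k / n,
             ci_low = ci[1], ci_high = ci[2],
             replicates_used = n,
             replicates_failed = sum(!ok))
}

#' Smallest sample size reaching a target power
#'
#' Estimates the power curve over candidate per-condition sample sizes,
#' smooths it monotonically by pool-adjacent-violators, and selects the
#' smallest candidate whose smoothed power reaches the target.
#'
#' @param config a [power_config()].
#' @param candidate_n sorted vector of candidate per-condition sample sizes.
#' @param target target power (default 0.8).
#' @param control an [irt_control()].
#' @return object of class `power_estimate`: the power `table` (with smoothed
#'   powers), `selected_n_per_condition` (`NA` with `reached = FALSE` if no
#'   candidate suffices), `target`, `config` echo.
#' @export
required_sample_size <- function(config, candidate_n, target = 0.8,
                                 control = irt_control()) {
  stopifnot(inherits(config, "power_config"))
  if (!length(candidate_n)) stopf("candidate_n must be non-empty")
  if (is.unsorted(candidate_n, strictly = TRUE))
    stopf("candidate_n must be strictly increasing")
  sub_seeds <- derive_seeds(config$seed, length(candidate_n))
  tab <- do.call(rbind, lapply(seq_along(candidate_n), function(i) {
    cfg <- config
    cfg$seed <- sub_seeds[i]
    estimate_power(cfg, candidate_n[i], control)
  }))
  tab$power_smoothed <- if (nrow(tab) > 1)
    stats::isoreg(tab$n_per_condition, tab$power)$yf else tab$power
  hit <- which(tab$power_smoothed >= target)
  structure(list(table = tab,
                 selected_n_per_condition =
                   if (length(hit)) tab$n_per_condition[min(hit)] else NA,
                 reached = length(hit) > 0,
                 target = target,
                 config = config),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> target power %.2f: %s\n", x$target,
              if (x$reached)
                sprintf("selected n = %d per condition (total N = %d)",
                        as.integer(x$selected_n_per_condition),
                        2L * as.integer(x$selected_n_per_condition))
              else "target not reached by any candidate"))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
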