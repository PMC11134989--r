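#' Design of a simulated cued-recognition experiment
#'
#' Describes the test-phase layout that the generator emulates: every
#' participant studies a set of multi-element events and is then probed with
#' several forced-choice association tests per event. With six response
#' alternatives the stochastic guessing probability is 1/6.
#'
#' @param persons_per_condition participants per between-subjects condition.
#' @param conditions character vector of one or two condition labels.
#' @param events number of events per participant (default 24).
#' @param items_per_event association tests per event (default 3).
#' @param n_alternatives response alternatives per test (default 6); the
#'   guessing probability is `1 / n_alternatives`.
#' @param association_labels labels cycled over the items within each event so
#'   every label occurs equally often across the design; metadata only.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(persons_per_condition = 100L,
                              conditions = c("a", "b"),
                              events = 24L,
                              items_per_event = 3L,
                              n_alternatives = 6L,
                              association_labels = NULL) {
  stopifnot(persons_per_condition >= 1, events >= 1, items_per_event >= 1,
            n_alternatives >= 2)
  conditions <- as.character(conditions)
  if (!length(conditions) || length(conditions) > 2L)
    stopf("need one or two condition labels")
  if (is.null(association_labels))
    association_labels <- paste0("assoc", seq_len(items_per_event))
  structure(list(persons_per_condition = as.integer(persons_per_condition),
                 conditions = conditions,
                 events = as.integer(events),
                 items_per_event = as.integer(items_per_event),
                 n_alternatives = as.integer(n_alternatives),
                 guessing = 1 / n_alternatives,
                 association_labels = as.character(association_labels)),
            class = "simulation_design")
}

#' Generative parameters for the bifactor response model
#'
#' Responses are generated from
#' `P(u = 1) = c + (1 - c) * plogis(theta + eta_e - beta_j)` with a general
#' memory trait `theta ~ N(0, sigma2_general)` and independent event-specific
#' traits `eta_e ~ N(0, sigma2_specific)` shared across the events of a
#' condition. `sigma2_specific = 0` removes all within-event dependency and
#' reduces the model to the unidimensional fixed-guessing 3PL.
#'
#' @param sigma2_general variance of the general trait (default 1).
#' @param sigma2_specific event-specific trait variance; scalar or one value
#'   per condition.
#' @param difficulty_mean,difficulty_sd normal distribution from which item
#'   difficulties are drawn when `beta` is not supplied (defaults 0 and 1).
#' @param beta optional explicit difficulty vector (length events x items).
#' @return object of class `generative_parameters`.
#' @export
generative_parameters <- function(sigma2_general = 1,
                                  sigma2_specific = 0,
                                  difficulty_mean = 0,
                                  difficulty_sd = 1,
                                  beta = NULL) {
  if (any(sigma2_general < 0) || any(sigma2_specific < 0))
    stopf("variances must be non-negative")
  if (difficulty_sd < 0) stopf("difficulty_sd must be non-negative")
  if (!is.null(beta) && any(!is.finite(beta)))
    stopf("explicit difficulties must be finite")
  structure(list(sigma2_general = sigma2_general,
                 sigma2_specific = sigma2_specific,
                 difficulty_mean = difficulty_mean,
                 difficulty_sd = difficulty_sd,
                 beta = beta),
            class = "generative_parameters")
}

#' Draw item difficulties for a simulated design
#'
#' One difficulty per item, i.i.d. `N(mean, sd^2)`; deterministic given the
#' seed. `sd = 0` yields the constant vector `mean`.
#'
#' @param design a [simulation_design()].
#' @param mean,sd difficulty distribution parameters.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return named numeric vector of length `events * items_per_event`.
#' @export
draw_item_difficulties <- function(design, mean = 0, sd = 1, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.finite(mean) || !is.finite(sd)) stopf("non-finite distribution parameters")
  if (sd < 0) stopf("sd must be non-negative")
  n <- design$events * design$items_per_event
  b <- with_seed(seed, stats::rnorm(n, mean, sd))
  names(b) <- item_ids(design)
  b
}

item_ids <- function(design) {
  sprintf("e%02d_i%d", rep(seq_len(design$events), each = design$items_per_event),
          rep(seq_len(design$items_per_event), design$events))
}

event_ids <- function(design) {
  sprintf("e%02d", rep(seq_len(design$events), each = design$items_per_event))
}

#' Simulate a cued-recognition dataset from the bifactor model
#'
#' Generates, for each condition, person traits `theta_i ~ N(0, sigma2_general)`
#' and event-specific traits `eta_ie ~ N(0, sigma2_specific[condition])`, then
#' binary responses with success probability
#' `c + (1 - c) * plogis(theta_i + eta_ie - beta_j)`. All draws are
#' independent; the event-specific variance is the only source of within-event
#' dependency beyond the general trait.
#'
#' @param design a [simulation_design()].
#' @param params a [generative_parameters()]; `sigma2_specific` is recycled
#'   across conditions.
#' @param seed integer seed (controls difficulties, traits and responses).
#' @return a [response_dataset()] with attribute `truth` (a list holding the
#'   drawn difficulties and traits per condition).
#' @export
simulate_dataset <- function(design, params = generative_parameters(),
                             seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(params, "generative_parameters"))
  n_cond <- length(design$conditions)
  s2s <- rep(params$sigma2_specific, length.out = n_cond)
  with_seed(seed, {
    beta <- params$beta %||%
      stats::rnorm(design$events * design$items_per_event,
                   params$difficulty_mean, params$difficulty_sd)
    if (length(beta) != design$events * design$items_per_event)
      stopf("difficulty vector length %d does not match design (%d items)",
            length(beta), design$events * design$items_per_event)
    names(beta) <- item_ids(design)
    items <- item_ids(design)
    events <- event_ids(design)
    assoc <- rep(rep(design$association_labels,
                     length.out = design$items_per_event), design$events)
    ev_index <- rep(seq_len(design$events), each = design$items_per_event)

    out <- vector("list", n_cond)
    truth <- list(beta = beta, theta = list(), eta = list())
    for (ci in seq_len(n_cond)) {
      n <- design$persons_per_condition
      theta <- stats::rnorm(n, 0, sqrt(params$sigma2_general))
      eta <- matrix(stats::rnorm(n * design$events, 0, sqrt(s2s[ci])),
                    nrow = n)
      # total trait per person x item
      tot <- outer(theta, rep(1, length(items))) + eta[, ev_index, drop = FALSE]
      p <- design$guessing +
        (1 - design$guessing) * stats::plogis(sweep(tot, 2, beta))
      u <- matrix(stats::rbinom(length(p), 1L, p), nrow = n)
      person <- sprintf("%s_p%03d", design$conditions[ci], seq_len(n))
      out[[ci]] <- data.frame(
        person = rep(person, each = length(items)),
        condition = design$conditions[ci],
        event = rep(events, n),
        item = rep(items, n),
        association = rep(assoc, n),
        response = as.numeric(t(u)))
      truth$theta[[design$conditions[ci]]] <- stats::setNames(theta, person)
      truth$eta[[design$conditions[ci]]] <- eta
    }
    data <- response_dataset(do.call(rbind, out))
    truth$sigma2_general <- params$sigma2_general
    truth$sigma2_specific <- stats::setNames(s2s, design$conditions)
    attr(data, "truth") <- truth
    data
  })
}

#' Write the true generating parameters of a simulated dataset as JSON
#'
#' @param data a dataset produced by [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(data, path) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stopf("dataset carries no truth record")
  jsonlite::write_json(
    list(beta = as.list(truth$beta),
         sigma2_general = truth$sigma2_general,
         sigma2_specific = as.list(truth$sigma2_specific)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
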