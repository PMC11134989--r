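#' Model residuals of a fitted unidimensional model
#'
#' `e_ij = u_ij - P(EAP_i, beta_j)`: the observed response minus the model
#' probability evaluated at the person's EAP trait score. Missing responses
#' propagate as `NA`.
#'
#' @param m binary person-by-item matrix (or [response_dataset()]).
#' @param fit the [fit_unidimensional()] result for the same items.
#' @param eap optional trait scores to use instead of the fit's own.
#' @return numeric matrix of residuals, same shape and dimnames as `m`.
#' @export
residual_matrix <- function(m, fit, eap = NULL) {
  stopifnot(inherits(fit, "unidimensional_fit"))
  if (inherits(m, "response_dataset")) m <- response_matrix(m)
  if (ncol(m) != length(fit$beta)) stopf("item count mismatch between data and fit")
  if (is.null(eap)) {
    eap <- if (nrow(m) == length(fit$eap)) fit$eap
           else eap_traits(fit, m)$eap
  }
  if (length(eap) != nrow(m)) stopf("one trait score per person required")
  P <- response_probability(outer(eap, rep(1, ncol(m))),
                            matrix(fit$beta, nrow(m), ncol(m), byrow = TRUE),
                            fit$guessing)
  r <- m - P
  dimnames(r) <- dimnames(m)
  r
}

#' Q3 residual correlations with bias correction
#'
#' Yen's Q3 statistic for every unordered item pair: the Pearson correlation
#' of the two items' residual columns across persons (pairwise-complete).
#' Under local independence Q3 scatters around a small negative value; the
#' bias-corrected matrix subtracts the mean over all pairs, so corrected
#' entries average exactly zero. Any pair-constant correction cancels in the
#' dependency measure D, so the correction affects reported Q3 values but
#' never D.
#'
#' Residual columns with zero variance cannot be correlated; their pairs are
#' set to missing and the items reported in `dropped_items`.
#'
#' @param residuals person-by-item residual matrix from [residual_matrix()].
#' @param events item -> event map (defaults to the `events` attribute
#'   carried through from [response_matrix()]).
#' @return object of class `q3_result`: `raw` and `corrected` symmetric
#'   matrices (`NA` diagonal), logical `same_event` matrix, `n_pairs`,
#'   `n_persons` per pair, `dropped_items`.
#' @export
q3_statistics <- function(residuals, events = NULL) {
  events <- events %||% attr(residuals, "events")
  J <- ncol(residuals)
  if (J < 2) stopf("need at least two items")
  if (nrow(residuals) < 3) stopf("need at least 3 persons")
  sds <- apply(residuals, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(residuals)[!is.na(sds) & sds == 0]
  raw <- if (anyNA(residuals))
    suppressWarnings(stats::cor(residuals, use = "pairwise.complete.obs"))
  else
    suppressWarnings(stats::cor(residuals))
  diag(raw) <- NA_real_
  if (length(dropped)) {
    raw[dropped, ] <- NA_real_
    raw[, dropped] <- NA_real_
  }
  up <- upper.tri(raw)
  correction <- mean(raw[up], na.rm = TRUE)
  corrected <- raw - correction
  obs <- crossprod(!is.na(residuals))  # persons per pair
  same <- NULL
  if (!is.null(events)) {
    if (length(events) != J) stopf("event map length mismatch")
    same <- outer(events, events, "==")
    dimnames(same) <- dimnames(raw)
    diag(same) <- NA
  }
  structure(list(raw = raw, corrected = corrected, correction = correction,
                 same_event = same, n_persons = obs,
                 n_pairs = sum(up & !is.na(raw)),
                 dropped_items = dropped),
            class = "q3_result")
}

#' @export
print.q3_result <- function(x, ...) {
  cat(sprintf("<q3_result> %d items, %d usable pairs, bias correction = %.4f\n",
              ncol(x$raw), x$n_pairs, x$correction))
  if (length(x$dropped_items))
    cat("  dropped zero-variance items:",
        paste(x$dropped_items, collapse = ", "), "\n")
  invisible(x)
}

#' The dependency measure D
#'
#' `D = mean(Q3 over same-event pairs) - mean(Q3 over different-event pairs)`.
#' The same-event mean picks up the within-event dependency induced by binding;
#' subtracting the different-event mean removes baseline dependence shared by
#' all pairs, which also makes D invariant to any constant added to every Q3
#' entry. For a design with `E` events of `k` items,
#' `K = E * choose(k, 2)` same-event pairs and `K + L = choose(E * k, 2)`.
#'
#' @param q3 a [q3_statistics()] result (the bias-corrected matrix is used;
#'   the raw matrix gives the identical D).
#' @param events item -> event map; required if the `q3` object carries none.
#' @return object of class `dependency_estimate`: `D`, `within_mean`,
#'   `between_mean`, nominal pair counts `K` and `L`, effective (non-missing)
#'   counts `K_eff` and `L_eff`.
#' @export
dependency_D <- function(q3, events = NULL) {
  stopifnot(inherits(q3, "q3_result"))
  same <- q3$same_event
  if (is.null(same)) {
    if (is.null(events)) stopf("an item -> event map is required")
    same <- outer(events, events, "==")
    diag(same) <- NA
  }
  up <- upper.tri(q3$corrected)
  w <- q3$corrected[up & same %in% TRUE]
  b <- q3$corrected[up & same %in% FALSE]
  K <- length(w); L <- length(b)
  if (K == 0 || L == 0) stopf("need at least one pair in each class")
  K_eff <- sum(!is.na(w)); L_eff <- sum(!is.na(b))
  if (K_eff == 0 || L_eff == 0) stopf("all pairs missing in one class")
  wm <- mean(w, na.rm = TRUE); bm <- mean(b, na.rm = TRUE)
  structure(list(D = wm - bm, within_mean = wm, between_mean = bm,
                 K = K, L = L, K_eff = K_eff, L_eff = L_eff),
            class = "dependency_estimate")
}

#' @export
print.dependency_estimate <- function(x, ...) {
  cat(sprintf("<dependency_estimate> D = %.4f (within %.4f - between %.4f; K = %d, L = %d)\n",
              x$D, x$within_mean, x$between_mean, x$K, x$L))
  invisible(x)
}

#' Full single-condition dependency pipeline
#'
#' Convenience wrapper: unidimensional fit, EAP residuals, Q3, D.
#'
#' @param data a single-condition [response_dataset()] or a binary matrix with
#'   an `events` attribute.
#' @param guessing fixed guessing probability.
#' @param control an [irt_control()].
#' @return list with elements `fit`, `q3`, `dependency`.
#' @export
estimate_dependency <- function(data, guessing = 1 / 6,
                                control = irt_control()) {
  m <- if (inherits(data, "response_dataset")) response_matrix(data) else data
  events <- attr(m, "events")
  if (is.null(events)) stopf("an item -> event map is required")
  fit <- fit_unidimensional(m, guessing = guessing, control = control)
  res <- residual_matrix(m, fit)
  q3 <- q3_statistics(res, events = events)
  list(fit = fit, q3 = q3, dependency = dependency_D(q3))
}

#' Export a Q3 matrix as a long-format table
#'
#' @param q3 a [q3_statistics()] result.
#' @return data.frame with columns `item_a`, `item_b`, `raw_q3`,
#'   `corrected_q3`, `same_event` (one row per unordered pair).
#' @export
q3_long <- function(q3) {
  stopifnot(inherits(q3, "q3_result"))
  idx <- which(upper.tri(q3$raw), arr.ind = TRUE)
  data.frame(item_a = rownames(q3$raw)[idx[, 1]],
             item_b = colnames(q3$raw)[idx[, 2]],
             raw_q3 = q3$raw[idx],
             corrected_q3 = q3$corrected[idx],
             same_event = if (!is.null(q3$same_event)) q3$same_event[idx] else NA)
}
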