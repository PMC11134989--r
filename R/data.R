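#' Trial-level response dataset
#'
#' Container for binary cued-recognition outcomes in long format. Each row is
#' one test trial: a person responding to one item (one probed association of
#' one event). Items are clustered into events; persons carry a between-subjects
#' condition label with at most two levels.
#'
#' @param trials data.frame with columns `person`, `condition`, `event`,
#'   `item`, `response` and optionally `association`. `response` must be 0/1
#'   (NA allowed only when `allow_missing = TRUE`).
#' @param allow_missing logical; if `TRUE`, missing responses are kept and
#'   excluded pairwise downstream. Default `FALSE`: the matrix must be complete.
#'
#' @return An object of class `response_dataset`: the canonically sorted
#'   trials table plus person and item lookup tables.
#' @export
response_dataset <- function(trials, allow_missing = FALSE) {
  req <- c("person", "condition", "event", "item", "response")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (!"association" %in% names(trials)) trials$association <- NA_character_
  trials$person <- as.character(trials$person)
  trials$condition <- as.character(trials$condition)
  trials$event <- as.character(trials$event)
  trials$item <- as.character(trials$item)

  bad <- !(trials$response %in% c(0, 1) | (allow_missing & is.na(trials$response)))
  if (any(bad))
    stopf("non-binary response value(s) at row(s): %s",
          paste(utils::head(which(bad), 5L), collapse = ", "))

  key <- paste(trials$person, trials$item, sep = "\r")
  if (anyDuplicated(key)) {
    d <- trials[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicated (person, item) pair: person '%s', item '%s'",
          d$person, d$item)
  }

  item_event <- unique(trials[, c("item", "event", "association")])
  if (anyDuplicated(item_event$item)) {
    d <- item_event$item[duplicated(item_event$item)][1L]
    stopf("item '%s' is mapped to more than one event", d)
  }
  if (length(unique(trials$condition)) > 2L)
    stopf("condition must have at most two levels, found %d",
          length(unique(trials$condition)))

  persons <- unique(trials[, c("person", "condition")])
  if (anyDuplicated(persons$person))
    stopf("person '%s' appears under two conditions",
          persons$person[duplicated(persons$person)][1L])

  # all persons share the same item set
  n_items <- length(unique(trials$item))
  per_person <- tapply(trials$item, trials$person,
                       function(x) length(unique(x)))
  if (any(per_person != n_items))
    stopf("all persons must share the same item set (expected %d items)", n_items)

  # equal number of items per event
  ipe <- tapply(item_event$item, item_event$event, length)
  if (length(unique(ipe)) > 1L)
    stopf("all events must have the same number of items")

  # canonical sort: condition, person, event, item
  o <- order(trials$condition, trials$person, trials$event, trials$item)
  trials <- trials[o, , drop = FALSE]
  rownames(trials) <- NULL
  item_event <- item_event[order(item_event$event, item_event$item), ,
                           drop = FALSE]
  rownames(item_event) <- NULL
  persons <- persons[order(persons$condition, persons$person), , drop = FALSE]
  rownames(persons) <- NULL

  structure(list(trials = trials, persons = persons, items = item_event,
                 items_per_event = unname(ipe[1L]),
                 allow_missing = allow_missing),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("<response_dataset>\n")
  cat(sprintf("  %d persons (%s), %d events x %d items, %d trials\n",
              nrow(x$persons),
              paste(sprintf("%s: %d", names(table(x$persons$condition)),
                            table(x$persons$condition)), collapse = ", "),
              length(unique(x$items$event)), x$items_per_event,
              nrow(x$trials)))
  invisible(x)
}

#' Read trial-level data from the canonical long CSV
#'
#' The on-disk format is a UTF-8 CSV with header row and columns
#' `person, condition, event, item, association, response`.
#'
#' @param path file path.
#' @param allow_missing passed to [response_dataset()].
#' @return a [response_dataset()].
#' @export
read_trials <- function(path, allow_missing = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!"response" %in% names(trials)) stopf("column 'response' is required")
  trials$response <- suppressWarnings(as.numeric(trials$response))
  response_dataset(trials, allow_missing = allow_missing)
}

#' Write a response dataset to the canonical long CSV
#'
#' @param data a [response_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "response_dataset"))
  cols <- c("person", "condition", "event", "item", "association", "response")
  utils::write.csv(data$trials[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Binary person-by-item response matrix
#'
#' @param data a [response_dataset()].
#' @return numeric matrix (persons x items, dimnames set) with attributes
#'   `events` (item -> event map, in column order) and `condition`
#'   (per-person label, in row order).
#' @export
response_matrix <- function(data) {
  stopifnot(inherits(data, "response_dataset"))
  persons <- data$persons$person
  items <- data$items$item
  m <- matrix(NA_real_, nrow = length(persons), ncol = length(items),
              dimnames = list(persons, items))
  m[cbind(match(data$trials$person, persons),
          match(data$trials$item, items))] <- data$trials$response
  attr(m, "events") <- stats::setNames(data$items$event, items)
  attr(m, "condition") <- stats::setNames(data$persons$condition, persons)
  m
}

#' Split a two-condition dataset by condition
#'
#' @param data a [response_dataset()].
#' @return named list of single-condition `response_dataset` objects.
#' @export
split_conditions <- function(data) {
  stopifnot(inherits(data, "response_dataset"))
  lapply(split(data$trials, data$trials$condition),
         response_dataset, allow_missing = data$allow_missing)
}

#' Summarise memory performance per person and per condition
#'
#' @param data a [response_dataset()].
#' @param chance chance success probability (default 1/6 for six-alternative
#'   forced choice).
#' @return object of class `performance_summary`: per-person proportion correct
#'   and per-condition mean and SD.
#' @export
summarize_performance <- function(data, chance = 1 / 6) {
  stopifnot(inherits(data, "response_dataset"))
  if (!nrow(data$trials)) stopf("empty dataset")
  if (chance <= 0 || chance >= 1) stopf("chance must be in (0, 1)")
  tr <- data$trials[!is.na(data$trials$response), , drop = FALSE]
  n_per <- table(factor(tr$person, levels = data$persons$person))
  if (any(n_per == 0))
    stopf("person '%s' has no scored responses",
          names(n_per)[which(n_per == 0)[1L]])
  prop <- tapply(tr$response, factor(tr$person, levels = data$persons$person),
                 mean)
  per_person <- data.frame(person = data$persons$person,
                           condition = data$persons$condition,
                           proportion = as.numeric(prop[data$persons$person]))
  agg <- do.call(rbind, lapply(split(per_person, per_person$condition),
                               function(d) data.frame(
                                 condition = d$condition[1L],
                                 mean = mean(d$proportion),
                                 sd = stats::sd(d$proportion),
                                 n = nrow(d))))
  rownames(agg) <- NULL
  structure(list(per_person = per_person, per_condition = agg,
                 chance = chance),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary> chance =", format(x$chance, digits = 4), "\n")
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests whether per-person proportions correct exceed the guessing level,
#' using the signed-rank statistic V with a tie-corrected, continuity-corrected
#' normal approximation for the p-value and the effect size r = |Z| / sqrt(n).
#' Zero differences are dropped before ranking; ties get average ranks.
#'
#' @param proportions numeric vector of per-person proportions correct.
#' @param chance chance level in (0, 1); default 1/6.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return object of class `wilcoxon_result` with fields `V`, `p_value`,
#'   `r`, `z`, `n` (persons entering the ranking).
#' @export
wilcoxon_vs_chance <- function(proportions, chance = 1 / 6,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (chance <= 0 || chance >= 1) stopf("chance must be in (0, 1)")
  x <- proportions[!is.na(proportions)]
  if (length(x) < 5L) stopf("need at least 5 observations")
  d <- x - chance
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("all differences are zero; test undefined")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5  # continuity correction toward the null
  z <- switch(alternative,
              greater = (V - mu - cc) / sqrt(sig2),
              less = (V - mu + cc) / sqrt(sig2),
              two.sided = sign(V - mu) *
                max(0, (abs(V - mu) - cc)) / sqrt(sig2))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(V = V, p_value = p, z = z, r = abs(z) / sqrt(n), n = n,
                 chance = chance, alternative = alternative),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank vs chance %.4g (%s): V = %.1f, p = %.4g, r = %.3f (n = %d)\n",
              x$chance, x$alternative, x$V, x$p_value, x$r, x$n))
  invisible(x)
}
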