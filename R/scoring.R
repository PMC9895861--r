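# Scoring: listwise exclusion, prevalence, severity, sum composites and
# internal consistency for 0-3 ordinal questionnaire data.

#' Listwise exclusion of incomplete records
#'
#' Drops every record with at least one missing item response (listwise
#' deletion) and reports the exclusion rate.
#'
#' @param raw Matrix or data.frame of participant-by-item responses; missing
#'   responses are `NA`. Non-missing cells must be integers in 0-3.
#' @return List with `responses` (complete-case integer matrix),
#'   `n_excluded`, and `pct_excluded` (one decimal, half-away-from-zero).
#' @export
#' @examples
#' raw <- rbind(c(0, 1), c(NA, 2), c(3, 3))
#' exclude_incomplete(raw)$pct_excluded # 33.3
exclude_incomplete <- function(raw) {
  raw <- as.matrix(raw)
  n_raw <- nrow(raw)
  if (n_raw == 0L) stop_symptomnet("no records", "empty_dataset")
  complete <- stats::complete.cases(raw)
  kept <- raw[complete, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop_symptomnet("no complete records after exclusion", "empty_dataset")
  }
  check_scores(kept)
  storage.mode(kept) <- "integer"
  list(
    responses = kept,
    n_excluded = n_raw - nrow(kept),
    pct_excluded = prevalence_pct(n_raw - nrow(kept), n_raw)
  )
}

check_scores <- function(m) {
  bad <- which(matrix(!(m %in% 0:3), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_symptomnet(
      sprintf("score out of range 0-3 at row %d, column %d",
              bad[1, 1], bad[1, 2]),
      "validation_error"
    )
  }
  invisible(m)
}

get_column <- function(responses, item) {
  if (!item %in% colnames(responses)) {
    stop_symptomnet(paste("unknown item:", item), "missing_item")
  }
  responses[, item]
}

#' Item prevalence
#'
#' A symptom is counted as present when its score is at least 1; prevalence
#' is the share of participants with the symptom present.
#'
#' @param responses Complete-case integer matrix with item IDs as column
#'   names.
#' @param item Item ID.
#' @return List with `count` and `pct` (one decimal).
#' @export
item_prevalence <- function(responses, item) {
  x <- get_column(responses, item)
  count <- sum(x >= 1)
  list(count = count, pct = prevalence_pct(count, nrow(responses)))
}

#' Item severity
#'
#' Mean and sample standard deviation (denominator N-1) of an item's 0-3
#' scores.
#'
#' @inheritParams item_prevalence
#' @return List with `mean` and `sd`.
#' @export
item_severity <- function(responses, item) {
  x <- get_column(responses, item)
  if (length(x) < 2L) stop_symptomnet("need N >= 2", "insufficient_data")
  list(mean = mean(x), sd = stats::sd(x))
}

#' Cluster sum composite
#'
#' Per-participant sum of the cluster's item scores; for a k-item cluster
#' the composite ranges over `[0, 3k]`.
#'
#' @inheritParams item_prevalence
#' @param instrument An [instrument_config()].
#' @param cluster Cluster name.
#' @return Integer vector, one composite per participant.
#' @export
cluster_score <- function(responses, instrument, cluster) {
  members <- instrument$clusters[[cluster]]
  if (is.null(members) || length(members) == 0L) {
    stop_symptomnet(paste("unknown or empty cluster:", cluster),
                    "invalid_config")
  }
  cols <- vapply(members, function(it) get_column(responses, it),
                 numeric(nrow(responses)))
  as.integer(rowSums(cols))
}

#' Cluster prevalence
#'
#' A cluster is counted as present for a participant when at least one of
#' its member items scores 1 or more.
#'
#' @inheritParams cluster_score
#' @return List with `count` and `pct` (one decimal).
#' @export
cluster_prevalence <- function(responses, instrument, cluster) {
  members <- instrument$clusters[[cluster]]
  if (is.null(members) || length(members) == 0L) {
    stop_symptomnet(paste("unknown or empty cluster:", cluster),
                    "invalid_config")
  }
  cols <- responses[, members, drop = FALSE]
  count <- sum(apply(cols >= 1, 1, any))
  list(count = count, pct = prevalence_pct(count, nrow(responses)))
}

#' Cronbach's alpha
#'
#' Internal consistency of a k-item cluster:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sum))`,
#' all variances sample-based (denominator N-1). Alpha is at most 1 and may
#' be negative.
#'
#' @inheritParams cluster_score
#' @return Numeric alpha.
#' @export
cronbach_alpha <- function(responses, instrument, cluster) {
  members <- instrument$clusters[[cluster]]
  if (is.null(members) || length(members) < 2L) {
    stop_symptomnet("cluster needs k >= 2 items", "invalid_config")
  }
  if (nrow(responses) < 3L) stop_symptomnet("need N >= 3", "insufficient_data")
  cols <- responses[, members, drop = FALSE]
  total_var <- stats::var(rowSums(cols))
  if (total_var == 0) {
    stop_symptomnet("zero total variance: alpha undefined", "undefined_alpha")
  }
  k <- length(members)
  k / (k - 1) * (1 - sum(apply(cols, 2, stats::var)) / total_var)
}

#' Prevalence / severity summary table
#'
#' Builds the standard instrument summary: one row per item (prevalence
#' count and percentage, severity mean and SD) and one row per cluster
#' (any-member prevalence, sum-composite severity, Cronbach's alpha).
#'
#' @inheritParams cluster_score
#' @return data.frame with columns `node`, `type` ("item" or "cluster"),
#'   `cluster` (membership for items), `count`, `pct`, `mean`, `sd`,
#'   `alpha` (clusters only).
#' @export
score_responses <- function(responses, instrument) {
  item_cluster <- function(id) {
    hit <- vapply(instrument$clusters, function(m) id %in% m, logical(1))
    if (any(hit)) names(instrument$clusters)[hit][1] else ""
  }
  items <- instrument$items$id
  item_rows <- do.call(rbind, lapply(items, function(it) {
    p <- item_prevalence(responses, it)
    s <- item_severity(responses, it)
    data.frame(node = it, type = "item", cluster = item_cluster(it),
               count = p$count, pct = p$pct, mean = s$mean, sd = s$sd,
               alpha = NA_real_, stringsAsFactors = FALSE)
  }))
  cluster_rows <- do.call(rbind, lapply(names(instrument$clusters), function(cl) {
    p <- cluster_prevalence(responses, instrument, cl)
    comp <- cluster_score(responses, instrument, cl)
    alpha <- tryCatch(cronbach_alpha(responses, instrument, cl),
                      symptomnet_error = function(e) NA_real_)
    data.frame(node = cl, type = "cluster", cluster = "",
               count = p$count, pct = p$pct,
               mean = mean(comp), sd = stats::sd(comp),
               alpha = alpha, stringsAsFactors = FALSE)
  }))
  rbind(cluster_rows, item_rows)
}
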