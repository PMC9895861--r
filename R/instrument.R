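#' Instrument configuration
#'
#' An instrument configuration maps item IDs to human-readable labels and to
#' symptom clusters, and lists the standalone items that belong to no cluster.
#' It defines the node sets of both networks: every item is a node of the
#' single-symptom network; each cluster (as a sum composite) plus each
#' standalone item is a node of the cluster network.
#'
#' @param items data.frame with columns `id` and `label`, one row per item,
#'   in instrument order.
#' @param clusters named list of character vectors; each element gives the
#'   item IDs belonging to one cluster. Clusters must be disjoint.
#' @param standalone character vector of item IDs outside every cluster.
#'   Together the clusters and standalone items must partition `items$id`.
#' @return An object of class `instrument_config`.
#' @seealso [mh_instrument()] for the packaged 40-item mental health
#'   instrument.
#' @export
instrument_config <- function(items, clusters, standalone = character()) {
  items <- as.data.frame(items)
  stopifnot(all(c("id", "label") %in% names(items)))
  items$id <- as.character(items$id)
  if (anyDuplicated(items$id)) {
    stop_symptomnet("duplicated item IDs", "invalid_config")
  }
  clusters <- lapply(clusters, as.character)
  if (is.null(names(clusters)) || any(names(clusters) == "")) {
    stop_symptomnet("clusters must be named", "invalid_config")
  }
  member <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(member)) {
    stop_symptomnet("clusters must be disjoint", "invalid_config")
  }
  assigned <- c(member, standalone)
  if (!setequal(assigned, items$id) || length(assigned) != nrow(items)) {
    stop_symptomnet(
      "clusters plus standalone items must partition the item set",
      "invalid_config"
    )
  }
  if (any(lengths(clusters) == 0)) {
    stop_symptomnet("empty cluster", "invalid_config")
  }
  structure(
    list(items = items[, c("id", "label")],
         clusters = clusters,
         standalone = as.character(standalone)),
    class = "instrument_config"
  )
}

#' The packaged 40-item mental health instrument
#'
#' Forty ordinal items (scored 0-3), of which 36 are organized into six
#' clusters -- somatization (7 items), cognitive function (5), negative
#' affect (10), interpersonal communication (4), cognitive processes (7) and
#' social adaptation (3) -- plus four standalone symptoms: sleep disturbance,
#' loneliness, sadness and anger.
#'
#' @return An `instrument_config` with 40 items.
#' @export
#' @examples
#' inst <- mh_instrument()
#' lengths(inst$clusters)
mh_instrument <- function() {
  ref <- reference_marginals()
  clustered <- ref$id[ref$cluster != ""]
  clusters <- split(clustered, factor(ref$cluster[ref$cluster != ""],
                                      levels = unique(ref$cluster[ref$cluster != ""])))
  instrument_config(
    items = ref[, c("id", "label")],
    clusters = as.list(clusters),
    standalone = ref$id[ref$cluster == ""]
  )
}

#' Published marginal statistics for the packaged instrument
#'
#' Per-item prevalence counts/percentages and severity mean/SD observed in a
#' cohort of 503 persons living with HIV, as distributed with the package.
#' These serve as calibration targets for the synthetic-data generator and as
#' inputs to the desk-check arithmetic.
#'
#' @param what `"items"` (default) for the 40 item rows, `"clusters"` for the
#'   six cluster rows (sum-composite severity and Cronbach's alpha).
#' @return data.frame of reference statistics.
#' @export
reference_marginals <- function(what = c("items", "clusters")) {
  what <- match.arg(what)
  file <- switch(what,
    items = "reference_item_stats.csv",
    clusters = "reference_cluster_stats.csv"
  )
  path <- system.file("extdata", file, package = "symptomnet", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = if (what == "items") c(cluster = "character") else NA)
  if (what == "items") out$cluster[is.na(out$cluster)] <- ""
  out
}

#' Node order of the cluster-level network
#'
#' The six cluster composites followed by the four standalone items, in the
#' conventional display order.
#'
#' @param instrument An `instrument_config`.
#' @return Character vector of 10 node IDs (for the packaged instrument).
#' @keywords internal
cluster_node_order <- function(instrument) {
  ord <- c("somatization", "negative_affect", "cognitive_function",
           "interpersonal", "cognitive_processes", "social_adaptation")
  nms <- names(instrument$clusters)
  c(intersect(ord, nms), setdiff(nms, ord), instrument$standalone)
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("Instrument configuration:", nrow(x$items), "items\n")
  cat("Clusters:\n")
  for (nm in names(x$clusters)) {
    cat(sprintf("  %-26s %d items\n", nm, length(x$clusters[[nm]])))
  }
  if (length(x$standalone)) {
    cat("Standalone items:", paste(x$standalone, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read or write an instrument configuration
#'
#' Serialized as YAML (or JSON, by file extension): an `items` table and a
#' `clusters` mapping plus a `standalone` list.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param instrument An `instrument_config` (for writing).
#' @return `read_instrument()` returns an `instrument_config`;
#'   `write_instrument()` returns `path` invisibly.
#' @export
read_instrument <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  items <- if (is.data.frame(obj$items)) {
    obj$items
  } else {
    data.frame(
      id = vapply(obj$items, function(i) i$id, ""),
      label = vapply(obj$items, function(i) i$label, ""),
      stringsAsFactors = FALSE
    )
  }
  instrument_config(items, lapply(obj$clusters, unlist),
                    standalone = as.character(unlist(obj$standalone)))
}

#' @rdname read_instrument
#' @export
write_instrument <- function(instrument, path) {
  obj <- list(
    items = lapply(seq_len(nrow(instrument$items)), function(i) {
      list(id = instrument$items$id[i], label = instrument$items$label[i])
    }),
    clusters = lapply(instrument$clusters, as.list),
    standalone = as.list(instrument$standalone)
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
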