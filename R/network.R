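# Spearman correlation networks over symptoms (40 nodes) or symptom
# clusters (6 sum composites + 4 standalone items = 10 nodes).

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), the
#' association measure used for every network edge.
#'
#' @param x,y Numeric vectors of equal length >= 3, each nonconstant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_symptomnet("need equal-length vectors with n >= 3", "invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_symptomnet("rank correlation undefined for a constant vector",
                    "undefined_correlation")
  }
  stats::cor(x, y, method = "spearman")
}

#' Fit a symptom correlation network
#'
#' The model-fitting entry point: estimates a weighted undirected network
#' whose nodes are either single symptoms (one per instrument item) or
#' symptom clusters (six sum composites plus the standalone items) and whose
#' edge weights are pairwise Spearman correlations of the node scores. No
#' thresholding or regularization is applied by default, giving the fully
#' connected weighted network; `min_abs_weight` optionally zeroes weak
#' edges.
#'
#' @param responses Complete-case integer matrix (participants x items,
#'   scores 0-3) with item IDs as column names, e.g. from
#'   [exclude_incomplete()] or [generate_responses()].
#' @param instrument An [instrument_config()]; required for
#'   `level = "cluster"`, optional (column names suffice) for
#'   `level = "symptom"`.
#' @param level `"symptom"` for the item-level network, `"cluster"` for the
#'   composite-level network.
#' @param min_abs_weight Edges with `|rho|` below this are set to zero
#'   (default 0: keep all).
#' @param constant How to treat constant node columns, for which rank
#'   correlation is undefined: `"drop"` (default) removes the node with a
#'   warning, `"error"` aborts.
#' @return Object of class `symptom_network` with elements `rho` (weight
#'   matrix), `nodes`, `labels`, `level`, `n` (participants), `dropped`,
#'   `min_abs_weight`, and (symptom level) `category_freq` used by
#'   [simulate.symptom_network()].
#' @export
#' @examples
#' spec <- calibrate_spec(n_participants = 200, seed = 7)
#' resp <- generate_responses(spec)
#' net <- symptom_network(resp, mh_instrument())
#' net
symptom_network <- function(responses, instrument = NULL,
                            level = c("symptom", "cluster"),
                            min_abs_weight = 0,
                            constant = c("drop", "error")) {
  level <- match.arg(level)
  constant <- match.arg(constant)
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    stop_symptomnet("responses must carry item IDs as column names",
                    "invalid_input")
  }
  if (!is.null(instrument)) {
    responses <- responses[, instrument$items$id, drop = FALSE]
  }
  if (level == "cluster") {
    if (is.null(instrument)) {
      stop_symptomnet("cluster-level network requires an instrument",
                      "invalid_config")
    }
    node_scores <- build_cluster_nodes(responses, instrument)
    labels <- colnames(node_scores)
  } else {
    node_scores <- responses
    labels <- if (is.null(instrument)) colnames(responses) else {
      instrument$items$label[match(colnames(responses), instrument$items$id)]
    }
  }
  const <- apply(node_scores, 2, function(v) stats::sd(v) == 0)
  dropped <- colnames(node_scores)[const]
  if (any(const)) {
    if (constant == "error") {
      stop_symptomnet(paste("constant node columns:",
                            paste(dropped, collapse = ", ")),
                      "undefined_correlation")
    }
    warning("dropping constant node columns: ",
            paste(dropped, collapse = ", "))
    node_scores <- node_scores[, !const, drop = FALSE]
    labels <- labels[!const]
  }
  rho <- stats::cor(node_scores, method = "spearman")
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  if (min_abs_weight > 0) {
    rho[abs(rho) < min_abs_weight & row(rho) != col(rho)] <- 0
  }
  freq <- NULL
  if (level == "symptom") {
    freq <- t(apply(node_scores, 2, function(v) {
      tabulate(v + 1L, nbins = 4L) / length(v)
    }))
    colnames(freq) <- paste0("p", 0:3)
  }
  structure(
    list(rho = rho, nodes = colnames(node_scores), labels = labels,
         level = level, n = nrow(node_scores), dropped = dropped,
         min_abs_weight = min_abs_weight, category_freq = freq,
         call = match.call()),
    class = "symptom_network"
  )
}

#' Cluster-level node score matrix
#'
#' The six cluster sum composites (in display order) followed by the four
#' standalone item columns: the 10 node variables of the cluster network.
#'
#' @inheritParams cluster_score
#' @return Integer matrix (participants x 10 for the packaged instrument).
#' @export
build_cluster_nodes <- function(responses, instrument) {
  order <- cluster_node_order(instrument)
  cols <- lapply(order, function(node) {
    if (node %in% names(instrument$clusters)) {
      cluster_score(responses, instrument, node)
    } else {
      as.integer(get_column(responses, node))
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- order
  out
}

#' Strongest edges of a network
#'
#' Edges ranked by `|rho|` descending, ties broken lexicographically by the
#' (node_a, node_b) ID pair; the signed weight is reported.
#'
#' @param network A `symptom_network`.
#' @param k Number of edges to return; if larger than the number of edges,
#'   the full list is returned with a warning.
#' @return data.frame with columns `node_a`, `node_b`, `r`.
#' @export
top_edges <- function(network, k = 3) {
  rho <- network$rho
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(rho)[ut[, 1]],
    node_b = colnames(rho)[ut[, 2]],
    r = rho[ut],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-abs(edges$r), edges$node_a, edges$node_b), ]
  rownames(edges) <- NULL
  if (k > nrow(edges)) {
    warning(sprintf("only %d edges available (k = %d)", nrow(edges), k))
    k <- nrow(edges)
  }
  edges[seq_len(k), ]
}

#' Convert a symptom network to an igraph object
#'
#' Undirected weighted graph; node pairs with weight exactly zero carry no
#' edge. The signed Spearman rho is stored as the `weight` edge attribute.
#'
#' @param network A `symptom_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(
    network$rho * (row(network$rho) != col(network$rho)),
    mode = "undirected", weighted = TRUE
  )
  g
}

#' @export
print.symptom_network <- function(x, ...) {
  n_nodes <- length(x$nodes)
  cat(sprintf("Spearman correlation network (%s level): %d nodes, %d participants\n",
              x$level, n_nodes, x$n))
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("edges: %d of %d nonzero; weights in [%.2f, %.2f], mean %.2f\n",
              sum(off != 0), length(off), min(off), max(off), mean(off)))
  if (length(x$dropped)) {
    cat("dropped constant nodes:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.symptom_network <- function(object, k = 3,
                                    mode = c("theoretical-max", "observed-max"),
                                    ...) {
  mode <- match.arg(mode)
  out <- list(
    network = object,
    top_edges = top_edges(object, k),
    centrality = centrality(object, mode = mode)
  )
  class(out) <- "summary.symptom_network"
  out
}

#' @export
print.summary.symptom_network <- function(x, ...) {
  print(x$network)
  cat("\nStrongest edges:\n")
  print(x$top_edges, digits = 3)
  cat("\nMost central nodes (consensus rank):\n")
  ranked <- rank_nodes(x$centrality)
  print(utils::head(ranked, 5), digits = 3)
  invisible(x)
}

#' @export
coef.symptom_network <- function(object, ...) object$rho

#' Simulate new response data from a fitted symptom network
#'
#' Draws synthetic participant-by-item data whose association structure
#' mimics the fitted network: the estimated Spearman matrix is mapped to a
#' latent normal correlation via `2 sin(pi * rho / 6)` (the exact relation
#' between Spearman and Pearson correlation under bivariate normality),
#' repaired to the nearest positive-semidefinite matrix if needed, and
#' combined with the observed per-item category frequencies in a Gaussian
#' copula. Only available for symptom-level networks (cluster composites
#' are not 0-3 ordinal variables).
#'
#' @param object A symptom-level `symptom_network`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param n_participants Rows per replicate (default: the fitted `n`).
#' @param ... Unused.
#' @return A list of `nsim` integer response matrices.
#' @export
simulate.symptom_network <- function(object, nsim = 1, seed = 1,
                                     n_participants = object$n, ...) {
  if (object$level != "symptom" || is.null(object$category_freq)) {
    stop_symptomnet("simulate() requires a symptom-level network",
                    "invalid_input")
  }
  latent <- 2 * sin(pi * object$rho / 6)
  diag(latent) <- 1
  dimnames(latent) <- dimnames(object$rho)
  lapply(seq_len(nsim), function(i) {
    spec <- suppressWarnings(
      copula_spec(n_participants, latent, object$category_freq,
                  seed = seed + i - 1L, repair = TRUE)
    )
    generate_responses(spec)
  })
}
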