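# Strength, closeness and betweenness on weighted correlation networks,
# with explicit standardization to the 0-1 reporting scale (r_S, r_C, r_B).
#
# Association strength |rho| is converted to a path length via d = 1/|rho|
# (stronger correlation = shorter distance, d >= 1); zero-weight pairs carry
# no edge. Shortest-path quantities come from igraph (Dijkstra distances,
# Brandes betweenness with fractional credit across tied geodesics).

#' Edge weight to shortest-path distance
#'
#' `d = 1 / |r|` for nonzero correlations; a zero weight means no edge
#' (infinite distance). Since `|r| <= 1`, every distance is at least 1.
#'
#' @param r Correlation weight(s) in `[-1, 1]`.
#' @return Distance(s) in `[1, Inf]`.
#' @export
#' @examples
#' weight_to_distance(c(1, 0.5, -0.25, 0)) # 1 2 4 Inf
weight_to_distance <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  ifelse(r == 0, Inf, 1 / abs(r))
}

net_graph <- function(network) {
  w <- abs(network$rho)
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
}

#' All-pairs shortest-path distance matrix
#'
#' Distances between nodes under the `1/|r|` edge-length convention;
#' unreachable pairs are `Inf`.
#'
#' @param network A `symptom_network`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
shortest_path_matrix <- function(network) {
  g <- net_graph(network)
  igraph::distances(g, weights = weight_to_distance(igraph::E(g)$weight))
}

check_node <- function(network, node) {
  if (!is.null(node) && !all(node %in% network$nodes)) {
    stop_symptomnet(paste("unknown node:",
                          paste(setdiff(node, network$nodes), collapse = ", ")),
                    "missing_node")
  }
}

#' Raw centrality indices
#'
#' `node_strength()` is the sum of absolute edge weights incident to a node.
#' `node_closeness()` is `(n_reach - 1) / sum(d)` over the node's reachable
#' set, multiplied by `(n_reach - 1)/(n - 1)` so that disconnection is
#' penalized and the value stays in `[0, 1]`; an isolated node scores 0.
#' `node_betweenness()` is the fraction of all-pairs shortest paths passing
#' through the node (fractional credit across tied geodesics), normalized by
#' `(n-1)(n-2)/2`.
#'
#' @param network A `symptom_network`.
#' @param node Optional node ID (or vector of IDs) to extract; default all.
#' @return Named numeric vector (or scalar for a single `node`).
#' @export
node_strength <- function(network, node = NULL) {
  check_node(network, node)
  out <- rowSums(abs(network$rho)) - 1  # diagonal contributes exactly 1
  out <- pmax(out, 0)
  if (is.null(node)) out else unname(out[node])
}

#' @rdname node_strength
#' @export
node_closeness <- function(network, node = NULL) {
  check_node(network, node)
  d <- shortest_path_matrix(network)
  n <- ncol(d)
  out <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    nr <- sum(reach)  # reachable others
    (nr / sum(di[reach])) * (nr / (n - 1))
  }, numeric(1))
  names(out) <- colnames(d)
  if (is.null(node)) out else unname(out[node])
}

#' @rdname node_strength
#' @export
node_betweenness <- function(network, node = NULL) {
  check_node(network, node)
  g <- net_graph(network)
  n <- length(network$nodes)
  if (n < 3) {
    out <- stats::setNames(numeric(n), network$nodes)
  } else {
    raw <- igraph::betweenness(
      g, directed = FALSE,
      weights = weight_to_distance(igraph::E(g)$weight)
    )
    out <- raw / ((n - 1) * (n - 2) / 2)
    names(out) <- network$nodes
  }
  if (is.null(node)) out else unname(out[node])
}

#' Centrality report for a symptom network
#'
#' Computes raw strength, closeness and betweenness for every node and
#' standardizes them to the 0-1 reporting scale. Two standardization modes
#' are provided:
#' \describe{
#'   \item{`"theoretical-max"`}{(default) `r_S = strength/(n-1)` (attainable
#'     maximum, since `|r| <= 1`); `r_C` and `r_B` are the raw values, which
#'     are already bounded by 1 under the `1/|r|` distance convention and
#'     the pair normalization respectively.}
#'   \item{`"observed-max"`}{each index is divided by its maximum over
#'     nodes, so the top node of each index scores exactly 1. An index that
#'     is zero everywhere stays zero, with a warning.}
#' }
#'
#' @param network A `symptom_network`.
#' @param mode Standardization mode.
#' @return data.frame of class `centrality_report` with columns `node`,
#'   `strength_raw`, `closeness_raw`, `betweenness_raw`, `r_S`, `r_C`,
#'   `r_B`; the mode is stored as attribute `"mode"`.
#' @export
#' @examples
#' spec <- calibrate_spec(n_participants = 150, seed = 3)
#' net <- symptom_network(generate_responses(spec), mh_instrument(),
#'                        level = "cluster")
#' centrality(net, mode = "observed-max")
centrality <- function(network, mode = c("theoretical-max", "observed-max")) {
  mode <- match.arg(mode)
  s <- node_strength(network)
  cl <- node_closeness(network)
  b <- node_betweenness(network)
  n <- length(network$nodes)
  std <- switch(mode,
    "theoretical-max" = list(r_S = s / (n - 1), r_C = cl, r_B = b),
    "observed-max" = {
      div <- function(v) {
        if (max(v) == 0) {
          warning("index is zero for every node; observed-max leaves it zero")
          v
        } else v / max(v)
      }
      list(r_S = div(s), r_C = div(cl), r_B = div(b))
    }
  )
  out <- data.frame(
    node = network$nodes,
    strength_raw = unname(s),
    closeness_raw = unname(cl),
    betweenness_raw = unname(b),
    r_S = unname(std$r_S),
    r_C = unname(std$r_C),
    r_B = unname(std$r_B),
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- mode
  class(out) <- c("centrality_report", "data.frame")
  out
}

#' Rank nodes by centrality
#'
#' Per-index descending rankings (rank 1 = most central; ties share their
#' average rank) and a consensus ordering by mean rank across the three
#' indices, ties broken lexicographically by node ID.
#'
#' @param report A `centrality_report` from [centrality()].
#' @return data.frame with columns `node`, `rank_strength`,
#'   `rank_closeness`, `rank_betweenness`, `consensus_rank` (mean of the
#'   three), sorted by consensus.
#' @export
rank_nodes <- function(report) {
  rk <- function(v) rank(-v, ties.method = "average")
  out <- data.frame(
    node = report$node,
    rank_strength = rk(report$r_S),
    rank_closeness = rk(report$r_C),
    rank_betweenness = rk(report$r_B),
    stringsAsFactors = FALSE
  )
  out$consensus_rank <- (out$rank_strength + out$rank_closeness +
                           out$rank_betweenness) / 3
  out <- out[order(out$consensus_rank, out$node), ]
  rownames(out) <- NULL
  out
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("Centrality report (standardization:", attr(x, "mode"), ")\n")
  NextMethod()
}
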