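# Weighted Fruchterman-Reingold force-directed layout, written so that a
# given seed always reproduces the same coordinates. Edge weights |r| scale
# the attractive force linearly, which pulls strongly correlated nodes --
# and hence densely connected hubs -- toward the center of the drawing.

#' Fruchterman-Reingold layout of a symptom network
#'
#' Seeded force-directed placement. With `k = sqrt(area/n)` the repulsive
#' force between every node pair is `k^2/d` and the attractive force along
#' an edge of weight `w = |r|` is `w * d^2 / k`; displacements are capped by
#' a linearly cooling temperature. Coordinates are centered and rescaled to
#' fit the `[-1, 1]^2` box (isotropically, so the shape is preserved).
#'
#' @param network A `symptom_network`.
#' @param seed Integer seed for the initial uniform placement.
#' @param iterations Number of force iterations (default 500).
#' @param initial_temp Starting temperature as a fraction of the frame
#'   (default 0.1); cools linearly to zero.
#' @param init Optional n x 2 matrix of starting positions, overriding the
#'   seeded uniform initialization.
#' @return Object of class `network_layout`: data.frame with columns
#'   `node`, `x`, `y`; attributes `seed` and `iterations`.
#' @export
#' @examples
#' spec <- calibrate_spec(n_participants = 120, seed = 5)
#' net <- symptom_network(generate_responses(spec), mh_instrument(),
#'                        level = "cluster")
#' head(fruchterman_reingold(net, seed = 1))
fruchterman_reingold <- function(network, seed = 1, iterations = 500,
                                 initial_temp = 0.1, init = NULL) {
  w <- abs(network$rho)
  diag(w) <- 0
  n <- ncol(w)
  if (n == 1L) {
    out <- data.frame(node = network$nodes, x = 0, y = 0)
    attr(out, "seed") <- seed
    attr(out, "iterations") <- 0L
    class(out) <- c("network_layout", "data.frame")
    return(out)
  }
  pos <- if (is.null(init)) {
    with_local_seed(seed, matrix(stats::runif(2 * n, -0.5, 0.5), n, 2))
  } else {
    stopifnot(nrow(init) == n, ncol(init) == 2)
    init
  }
  k <- sqrt(1 / n)
  for (it in seq_len(iterations)) {
    temp <- initial_temp * (iterations - it + 1) / iterations
    disp <- matrix(0, n, 2)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    # repulsion k^2/d between all pairs, attraction w*d^2/k along edges;
    # both applied along the unit separation vector
    coef <- k^2 / d^2 - w * d / k
    diag(coef) <- 0
    disp[, 1] <- rowSums(coef * dx)
    disp[, 2] <- rowSums(coef * dy)
    len <- sqrt(rowSums(disp^2))
    len[len < 1e-12] <- 1e-12
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
  }
  pos <- sweep(pos, 2, colMeans(pos))
  radius <- max(sqrt(rowSums(pos^2)))
  if (radius > 0) pos <- pos / radius
  out <- data.frame(node = network$nodes, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  class(out) <- c("network_layout", "data.frame")
  out
}

#' Plot a symptom network
#'
#' Figure-style rendering: nodes on a Fruchterman-Reingold layout, edge
#' width proportional to `|r|` (solid for positive, dashed for negative
#' correlations), and node size proportional to standardized strength when a
#' centrality report is supplied.
#'
#' @param x A `symptom_network`.
#' @param centrality_report Optional [centrality()] output; node area then
#'   scales with `r_S`.
#' @param seed,iterations Passed to [fruchterman_reingold()].
#' @param display_threshold Edges with `|r|` below this are not drawn
#'   (display only; the network itself is unchanged). Default 0.
#' @param labels Draw node labels (default: node IDs for up to 15 nodes,
#'   node numbers otherwise).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return The layout, invisibly.
#' @export
plot.symptom_network <- function(x, centrality_report = NULL, seed = 1,
                                 iterations = 500, display_threshold = 0,
                                 labels = NULL, ...) {
  lay <- fruchterman_reingold(x, seed = seed, iterations = iterations)
  graphics::plot(lay$x, lay$y, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15), asp = 1, ...)
  rho <- x$rho
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  for (e in seq_len(nrow(ut))) {
    r <- rho[ut[e, 1], ut[e, 2]]
    if (abs(r) <= display_threshold || r == 0) next
    graphics::segments(lay$x[ut[e, 1]], lay$y[ut[e, 1]],
                       lay$x[ut[e, 2]], lay$y[ut[e, 2]],
                       lwd = 0.5 + 3 * abs(r),
                       lty = if (r > 0) 1 else 2,
                       col = grDevices::adjustcolor(
                         if (r > 0) "darkgreen" else "firebrick",
                         alpha.f = min(1, 0.15 + abs(r))))
  }
  size <- if (!is.null(centrality_report)) {
    0.5 + 2.5 * centrality_report$r_S[match(x$nodes, centrality_report$node)]
  } else rep(1.5, length(x$nodes))
  graphics::points(lay$x, lay$y, pch = 21, bg = "steelblue1", cex = size)
  if (is.null(labels)) labels <- length(x$nodes) <= 15
  txt <- if (labels) x$nodes else seq_along(x$nodes)
  graphics::text(lay$x, lay$y, txt, pos = 3, cex = 0.7)
  invisible(lay)
}
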