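# File I/O and pipeline orchestration: responses CSV in, full analysis
# (exclusion -> scoring -> both networks -> centrality -> layout) out, with
# seed and configuration provenance embedded in every artifact.
#
# CSV dialect: UTF-8, comma separated, header row, "." decimal. Numeric
# cells are written with 17 significant digits so a written-then-reread
# weight matrix is bit-identical.

#' Read a response CSV
#'
#' Expects a header of item IDs and integer cells 0-3; empty cells are
#' missing responses (kept as `NA` for [exclude_incomplete()] to handle).
#'
#' @param path CSV file path.
#' @param instrument Optional [instrument_config()]; if given, the file's
#'   columns must match the instrument's item set exactly (any order).
#' @return Numeric matrix with `NA` for missing cells.
#' @export
read_responses <- function(path, instrument = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (!is.null(instrument)) {
    extra <- setdiff(names(df), instrument$items$id)
    missing <- setdiff(instrument$items$id, names(df))
    if (length(extra) || length(missing)) {
      stop_symptomnet(
        sprintf("response columns do not match instrument (unknown: %s; absent: %s)",
                paste(extra, collapse = ","), paste(missing, collapse = ",")),
        "schema_error"
      )
    }
    df <- df[, instrument$items$id, drop = FALSE]
  }
  m <- as.matrix(df)
  bad <- which(matrix(!is.na(m) & !(m %in% 0:3), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_symptomnet(
      sprintf("invalid score %s at row %d, column '%s'",
              m[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(m)[bad[1, 2]]),
      "validation_error"
    )
  }
  m
}

#' Write responses to CSV
#'
#' @param responses Integer response matrix with item-ID column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

provenance_header <- function(provenance) {
  sprintf("# seed=%s config=%s symptomnet=%s",
          provenance$seed, provenance$config_hash, provenance$version)
}

write_csv_prov <- function(df, path, provenance = NULL, digits17 = character()) {
  for (col in digits17) df[[col]] <- sprintf("%.17g", df[[col]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance_header(provenance), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read network edge lists
#'
#' Edge CSV columns: `node_a`, `node_b`, `r` (signed Spearman weight,
#' written at full precision so the weight matrix round-trips exactly).
#'
#' @param network A `symptom_network`.
#' @param path CSV path.
#' @param provenance Optional provenance list (internal use).
#' @return `write_edges()` returns `path` invisibly; `read_edges()` returns
#'   the edge data.frame.
#' @export
write_edges <- function(network, path, provenance = NULL) {
  rho <- network$rho
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(rho)[ut[, 1]],
    node_b = colnames(rho)[ut[, 2]],
    r = rho[ut],
    stringsAsFactors = FALSE
  )
  write_csv_prov(edges, path, provenance, digits17 = "r")
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Rebuild a weight matrix from an edge list
#'
#' @param edges data.frame from [read_edges()].
#' @return Symmetric matrix with unit diagonal.
#' @export
edges_to_matrix <- function(edges) {
  nodes <- unique(c(edges$node_a, edges$node_b))  # first-appearance order
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  m[cbind(edges$node_a, edges$node_b)] <- edges$r
  m[cbind(edges$node_b, edges$node_a)] <- edges$r
  diag(m) <- 1
  m
}

#' Export a network as GraphML
#'
#' Minimal GraphML with a `weight` edge attribute (signed Spearman rho,
#' full precision) and a `label` node attribute, readable by igraph and by
#' standard graph tools.
#'
#' @param network A `symptom_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  rho <- network$rho
  nodes <- network$nodes
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"><data key="label">%s</data></node>',
            nodes, xml_escape(network$labels)),
    {
      keep <- rho[ut] != 0
      sprintf('    <edge source="%s" target="%s"><data key="weight">%.17g</data></edge>',
              nodes[ut[keep, 1]], nodes[ut[keep, 2]], rho[ut][keep])
    },
    '  </graph>',
    '</graphml>'
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Read a GraphML network back as a weight matrix
#'
#' @param path GraphML file written by [write_graphml()] (or any GraphML
#'   with a numeric `weight` edge attribute).
#' @return Symmetric weight matrix with unit diagonal.
#' @export
read_graphml_matrix <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  m <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  diag(m) <- 1
  dimnames(m) <- list(igraph::V(g)$id %||% igraph::V(g)$name,
                      igraph::V(g)$id %||% igraph::V(g)$name)
  m
}

#' Run the full analysis pipeline
#'
#' Exclusion of incomplete records, prevalence/severity/alpha scoring, the
#' symptom-level and cluster-level Spearman networks, centrality reports,
#' layouts, and all file artifacts: `summary.csv`, `*_edges.csv`,
#' `*_network.graphml`, `*_centrality.csv`, `*_layout.csv` and
#' `report.json`. Every artifact embeds the seed and a hash of the run
#' configuration; rerunning with identical inputs and seed reproduces every
#' file byte-for-byte.
#'
#' @param responses Raw response matrix (may contain `NA`) or a path to a
#'   responses CSV.
#' @param instrument An [instrument_config()] (default [mh_instrument()]).
#' @param out_dir Output directory, created if needed; `NULL` to skip
#'   writing files.
#' @param mode Centrality standardization mode.
#' @param seed Seed recorded in provenance and used for layouts.
#' @param top_k Number of strongest edges reported per network.
#' @param min_abs_weight Edge threshold passed to [symptom_network()].
#' @return An `analysis_report` list: `summary`, `networks`, `centrality`,
#'   `top_edges`, `rankings`, `exclusion`, `provenance`.
#' @export
run_pipeline <- function(responses, instrument = mh_instrument(),
                         out_dir = NULL,
                         mode = c("theoretical-max", "observed-max"),
                         seed = 1, top_k = 3, min_abs_weight = 0) {
  mode <- match.arg(mode)
  if (is.character(responses)) {
    responses <- read_responses(responses, instrument)
  }
  config <- list(mode = mode, seed = seed, top_k = top_k,
                 min_abs_weight = min_abs_weight,
                 items = instrument$items$id)
  provenance <- list(
    seed = seed,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("symptomnet"))
  )
  excl <- exclude_incomplete(responses)
  summary_tab <- score_responses(excl$responses, instrument)
  nets <- list(
    symptom = symptom_network(excl$responses, instrument, level = "symptom",
                              min_abs_weight = min_abs_weight),
    cluster = symptom_network(excl$responses, instrument, level = "cluster",
                              min_abs_weight = min_abs_weight)
  )
  cents <- lapply(nets, centrality, mode = mode)
  ranks <- lapply(cents, rank_nodes)
  edges <- lapply(nets, top_edges, k = top_k)
  layouts <- lapply(nets, fruchterman_reingold, seed = seed)
  report <- structure(
    list(summary = summary_tab, networks = nets, centrality = cents,
         top_edges = edges, rankings = ranks,
         exclusion = excl[c("n_excluded", "pct_excluded")],
         provenance = provenance),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_prov(summary_tab, file.path(out_dir, "summary.csv"), provenance)
    for (lev in names(nets)) {
      write_edges(nets[[lev]], file.path(out_dir, paste0(lev, "_edges.csv")),
                  provenance)
      write_graphml(nets[[lev]], file.path(out_dir, paste0(lev, "_network.graphml")))
      write_csv_prov(cents[[lev]], file.path(out_dir, paste0(lev, "_centrality.csv")),
                     provenance)
      write_csv_prov(layouts[[lev]], file.path(out_dir, paste0(lev, "_layout.csv")),
                     provenance)
    }
    json <- list(
      provenance = provenance,
      exclusion = report$exclusion,
      mode = mode,
      top_edges = edges,
      rankings = lapply(ranks, utils::head, 5),
      summary = summary_tab
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Symptom network analysis report\n")
  cat(sprintf("  retained participants: %d (excluded %d, %.1f%%)\n",
              x$networks$symptom$n, x$exclusion$n_excluded,
              x$exclusion$pct_excluded))
  cat(sprintf("  networks: %d-node symptom, %d-node cluster (mode: %s)\n",
              length(x$networks$symptom$nodes),
              length(x$networks$cluster$nodes),
              attr(x$centrality$symptom, "mode")))
  cat("  top consensus nodes (symptom):",
      paste(utils::head(x$rankings$symptom$node, 3), collapse = ", "), "\n")
  cat("  top consensus nodes (cluster):",
      paste(utils::head(x$rankings$cluster$node, 3), collapse = ", "), "\n")
  invisible(x)
}
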