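#' Multilayer period network container
#'
#' An `elin_graph` holds one period's heterogeneous network: a node table
#' (canonical id, display label, layer, human-gene flag) and a
#' provenance-tagged edge table. Edges are stored once per unordered node
#' pair and provenance; mixed directedness is carried as an edge attribute
#' because the assembled product is an association network.
#'
#' @param period One of [period_codes()].
#' @return An empty `elin_graph`.
#' @export
new_graph <- function(period) {
  period <- match.arg(period, PERIOD_CODES)
  structure(
    list(
      period = period,
      nodes = tibble::tibble(id = character(), label = character(),
                             layer = character(), is_human_gene = logical()),
      edges = empty_edges(),
      build_log = list()
    ),
    class = "elin_graph"
  )
}

empty_edges <- function() {
  tibble::tibble(from = character(), to = character(), directed = logical(),
                 provenance = character(), weight = double(),
                 evidence_count = integer())
}

EDGE_PROVENANCES <- c("LITERATURE", "REFERENCE_CONFIRMED", "GO_ENRICHMENT",
                      "GOSLIM_ENRICHMENT", "DISEASE_ENRICHMENT",
                      "ENDPOINT_MAPPING", "INFERRED")

#' @export
print.elin_graph <- function(x, ...) {
  cat(sprintf("<elin_graph> period %s: %d nodes, %d edges\n",
              x$period, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    print(table(x$nodes$layer))
  }
  invisible(x)
}

# unordered pair key used for edge identity
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

log_stage <- function(graph, stage, ...) {
  graph$build_log[[length(graph$build_log) + 1L]] <-
    c(list(stage = stage), list(...))
  graph
}

#' Add nodes to a graph
#'
#' Nodes already present (same canonical id) are left untouched; the first
#' registration of an id fixes its label, layer and human-gene flag.
#'
#' @param graph An `elin_graph`.
#' @param nodes Tibble with columns `id`, `label`, `layer`, `is_human_gene`.
#' @return The updated graph.
#' @export
add_nodes <- function(graph, nodes) {
  stopifnot(inherits(graph, "elin_graph"))
  stopifnot(all(c("id", "label", "layer", "is_human_gene") %in% names(nodes)))
  bad <- setdiff(unique(nodes$layer), LAYER_CODES)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[!(nodes$id %in% graph$nodes$id), , drop = FALSE]
  graph$nodes <- dplyr::bind_rows(
    graph$nodes,
    tibble::as_tibble(nodes[, c("id", "label", "layer", "is_human_gene")])
  )
  graph
}

#' Add edges to a graph
#'
#' Enforces the edge invariants: endpoints must exist, no self-loops,
#' positive weight, and at most one edge per unordered node pair and
#' provenance (later duplicates are dropped silently; merging policy is the
#' caller's job, e.g. [assemble_network()] sums evidence before adding).
#'
#' @param graph An `elin_graph`.
#' @param edges Tibble with columns `from`, `to`, `directed`, `provenance`,
#'   `weight`, `evidence_count`.
#' @return The updated graph.
#' @export
add_edges <- function(graph, edges) {
  stopifnot(inherits(graph, "elin_graph"))
  if (!nrow(edges)) return(graph)
  stopifnot(all(c("from", "to", "directed", "provenance", "weight",
                  "evidence_count") %in% names(edges)))
  bad <- setdiff(unique(edges$provenance), EDGE_PROVENANCES)
  if (length(bad)) stop("unknown provenance(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(unique(c(edges$from, edges$to)), graph$nodes$id)
  if (length(missing)) {
    stop("edge endpoint(s) not in node set: ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
  if (any(edges$weight <= 0)) stop("edge weight must be > 0")
  if (any(edges$provenance == "LITERATURE" & edges$evidence_count < 1)) {
    stop("LITERATURE edges need evidence_count >= 1")
  }
  key <- paste(pair_key(edges$from, edges$to), edges$provenance)
  edges <- edges[!duplicated(key), , drop = FALSE]
  have <- paste(pair_key(graph$edges$from, graph$edges$to),
                graph$edges$provenance)
  edges <- edges[!(paste(pair_key(edges$from, edges$to), edges$provenance)
                   %in% have), , drop = FALSE]
  graph$edges <- dplyr::bind_rows(graph$edges, tibble::as_tibble(edges))
  graph
}

#' Per-layer node counts
#'
#' Summarizes a period network in the shape of the enriched-network node
#' table: one row per layer with its node count (layers with no nodes
#' report 0).
#'
#' @param graph An `elin_graph`.
#' @return Tibble with columns `layer` and `n_nodes`.
#' @export
layer_counts <- function(graph) {
  stopifnot(inherits(graph, "elin_graph"))
  counts <- table(factor(graph$nodes$layer, levels = LAYER_CODES))
  tibble::tibble(layer = LAYER_CODES, n_nodes = as.integer(counts))
}

#' Convert to igraph
#'
#' Returns an undirected igraph representation (the association-network
#' view used for centrality); node attributes `label`, `layer`,
#' `is_human_gene` and edge attributes `provenance`, `weight`,
#' `evidence_count`, `edge_directed` are carried along.
#'
#' @param graph An `elin_graph`.
#' @return An `igraph` object whose vertex `name` is the canonical node id.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "elin_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(
    g, nrow(graph$nodes),
    name = graph$nodes$id, label = graph$nodes$label,
    layer = graph$nodes$layer, is_human_gene = graph$nodes$is_human_gene
  )
  if (nrow(graph$edges)) {
    idx <- match(c(rbind(graph$edges$from, graph$edges$to)), graph$nodes$id)
    g <- igraph::add_edges(
      g, idx,
      provenance = graph$edges$provenance, weight = graph$edges$weight,
      evidence_count = graph$edges$evidence_count,
      edge_directed = graph$edges$directed
    )
  }
  igraph::graph_attr(g, "period") <- graph$period
  g
}

#' Serialize a period network
#'
#' Writes the graph as GraphML (via igraph) and/or as a paired
#' `nodes.tsv` / `edges.tsv` with identical content. Either output can be
#' read back with [read_network()] without loss of node ids, layers, edge
#' sets or provenances.
#'
#' @param graph An `elin_graph`.
#' @param graphml,nodes_tsv,edges_tsv Output paths; `NULL` skips a format.
#'   `nodes_tsv` and `edges_tsv` must be given together.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(graph, graphml = NULL, nodes_tsv = NULL,
                          edges_tsv = NULL) {
  stopifnot(inherits(graph, "elin_graph"))
  if (xor(is.null(nodes_tsv), is.null(edges_tsv))) {
    stop("nodes_tsv and edges_tsv must be given together")
  }
  written <- character()
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(graph), graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(nodes_tsv)) {
    nd <- graph$nodes
    nd$period <- graph$period
    write_tsv_plain(nd, nodes_tsv)
    write_tsv_plain(graph$edges, edges_tsv)
    written <- c(written, nodes_tsv, edges_tsv)
  }
  invisible(written)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Read a period network back from disk
#'
#' Counterpart of [write_network()]; accepts either a GraphML path or the
#' nodes/edges TSV pair.
#'
#' @param graphml,nodes_tsv,edges_tsv Paths as written by [write_network()].
#' @param period Period code; required for the TSV route only if the nodes
#'   file lacks a `period` column.
#' @return An `elin_graph`.
#' @export
read_network <- function(graphml = NULL, nodes_tsv = NULL, edges_tsv = NULL,
                         period = NULL) {
  if (!is.null(graphml)) {
    ig <- igraph::read_graph(graphml, format = "graphml")
    period <- igraph::graph_attr(ig, "period")
    graph <- new_graph(period)
    graph <- add_nodes(graph, tibble::tibble(
      id = igraph::V(ig)$name, label = igraph::V(ig)$label,
      layer = igraph::V(ig)$layer,
      is_human_gene = as.logical(igraph::V(ig)$is_human_gene)
    ))
    if (igraph::ecount(ig)) {
      ends <- igraph::as_edgelist(ig, names = TRUE)
      graph <- add_edges(graph, tibble::tibble(
        from = ends[, 1], to = ends[, 2],
        directed = as.logical(igraph::E(ig)$edge_directed),
        provenance = igraph::E(ig)$provenance,
        weight = as.double(igraph::E(ig)$weight),
        evidence_count = as.integer(igraph::E(ig)$evidence_count)
      ))
    }
    return(graph)
  }
  if (is.null(nodes_tsv) || is.null(edges_tsv)) {
    stop("give either graphml or the nodes_tsv/edges_tsv pair")
  }
  nd <- read.delim(nodes_tsv, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", encoding = "UTF-8")
  ed <- read.delim(edges_tsv, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", encoding = "UTF-8")
  if (is.null(period)) period <- nd$period[1]
  graph <- new_graph(period)
  graph <- add_nodes(graph, tibble::as_tibble(nd))
  if (nrow(ed)) {
    ed$directed <- as.logical(ed$directed)
    ed$weight <- as.double(ed$weight)
    ed$evidence_count <- as.integer(ed$evidence_count)
    graph <- add_edges(graph, tibble::as_tibble(ed))
  }
  graph
}
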