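ANNOT_LAYER <- c(GO = "GO_PROCESS", GOSLIM = "GOSLIM_PROCESS",
                 DISEASE = "DISEASE")
ANNOT_PROVENANCE <- c(GO = "GO_ENRICHMENT", GOSLIM = "GOSLIM_ENRICHMENT",
                      DISEASE = "DISEASE_ENRICHMENT")
ANNOT_NS <- c(GO = "GO", GOSLIM = "GOSLIM", DISEASE = "UMLS")

#' Enrich a period network with annotation edges
#'
#' Joins gene-term annotation tables onto the graph: for every annotation
#' row whose gene symbol matches a GENE_PROTEIN node already in the
#' network, the term node (GO_PROCESS / GOSLIM_PROCESS / DISEASE by table
#' source) is added if absent together with an undirected enrichment edge
#' of weight 1. Genes absent from the network contribute nothing — only
#' genes the period literature mentions are annotated. ENDPOINT_MAP tables
#' are applied last: the four immune endpoint nodes are added and each
#' mapped term that made it into the network gains a term-to-endpoint
#' ENDPOINT_MAPPING edge, so no endpoint hangs off a term without gene
#' support. Enrichment only ever grows the graph and is independent of
#' table row order.
#'
#' @param graph A denoised `elin_graph`.
#' @param annotations A list of tables from [read_annotations()] (any mix
#'   of sources; ENDPOINT_MAP tables are processed after the rest).
#' @param min_score Optional lower bound passed through to DISEASE tables
#'   that carry a `score` column; default `NULL` applies no cutoff.
#' @return A list with `graph` (enriched) and `summary`, a tibble with one
#'   row per source: `source`, `n_nodes_added`, `n_edges_added`.
#' @export
enrich_graph <- function(graph, annotations, min_score = NULL) {
  stopifnot(inherits(graph, "elin_graph"))
  if (inherits(annotations, "elin_annotation")) annotations <- list(annotations)
  sources <- vapply(annotations, function(a) attr(a, "source") %||% "",
                    character(1))
  bad <- setdiff(sources, c("GO", "GOSLIM", "DISEASE", "ENDPOINT_MAP"))
  if (length(bad %||% character()) || any(!nzchar(sources))) {
    stop("annotation table with unknown source label")
  }
  ord <- order(sources == "ENDPOINT_MAP")  # endpoint mapping last
  summary <- list()
  for (i in ord) {
    src <- sources[i]
    tab <- annotations[[i]]
    before_n <- nrow(graph$nodes)
    before_e <- nrow(graph$edges)
    graph <- if (src == "ENDPOINT_MAP") {
      apply_endpoint_map(graph, tab)
    } else {
      apply_gene_annotation(graph, tab, src, min_score)
    }
    summary[[length(summary) + 1L]] <- tibble::tibble(
      source = src,
      n_nodes_added = nrow(graph$nodes) - before_n,
      n_edges_added = nrow(graph$edges) - before_e
    )
  }
  summary <- dplyr::bind_rows(summary)
  graph <- log_stage(graph, "enrich",
                     n_edges_added = sum(summary$n_edges_added))
  list(graph = graph, summary = summary)
}

term_node_id <- function(term_id, source) {
  ns <- ANNOT_NS[[source]]
  ifelse(grepl(":", term_id) & source != "GOSLIM",
         term_id, paste0(ns, ":", sub("^[A-Za-z]+:", "", term_id)))
}

apply_gene_annotation <- function(graph, tab, src, min_score) {
  if (!nrow(tab)) return(graph)
  if (!is.null(min_score) && src == "DISEASE" && "score" %in% names(tab)) {
    tab <- tab[tab$score >= min_score, , drop = FALSE]
  }
  genes <- graph$nodes[graph$nodes$layer == "GENE_PROTEIN", , drop = FALSE]
  sym2id <- setNames(genes$id, toupper(genes$label))
  hit <- tab[tab$gene %in% names(sym2id), , drop = FALSE]
  if (!nrow(hit)) return(graph)
  hit$term_node <- term_node_id(hit$term_id, src)
  terms <- hit[!duplicated(hit$term_node), , drop = FALSE]
  terms <- terms[order(terms$term_node), , drop = FALSE]
  graph <- add_nodes(graph, tibble::tibble(
    id = terms$term_node, label = terms$term_name,
    layer = ANNOT_LAYER[[src]], is_human_gene = FALSE
  ))
  hit <- hit[order(hit$term_node, hit$gene), , drop = FALSE]
  add_edges(graph, tibble::tibble(
    from = unname(sym2id[hit$gene]), to = hit$term_node,
    directed = FALSE, provenance = ANNOT_PROVENANCE[[src]],
    weight = 1, evidence_count = 0L
  ))
}

endpoint_node_id <- function(endpoint) paste0("TEXT:", toupper(endpoint))

apply_endpoint_map <- function(graph, tab) {
  graph <- add_nodes(graph, tibble::tibble(
    id = endpoint_node_id(IMMUNE_ENDPOINTS), label = IMMUNE_ENDPOINTS,
    layer = "IMMUNE_ENDPOINT", is_human_gene = FALSE
  ))
  if (!nrow(tab)) return(graph)
  # the mapping references GO/GO-slim/text-mined process terms; accept a
  # term if any of those canonical forms is already a node
  candidates <- cbind(tab$term_id,
                      term_node_id(tab$term_id, "GO"),
                      term_node_id(tab$term_id, "GOSLIM"),
                      paste0("TEXT:", toupper(tab$term_id)))
  present <- matrix(candidates %in% graph$nodes$id, nrow = nrow(tab))
  first <- apply(present, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  ok <- !is.na(first)
  if (!any(ok)) return(graph)
  hit <- tibble::tibble(
    from = candidates[cbind(which(ok), first[ok])],
    to = endpoint_node_id(tab$endpoint[ok])
  )
  hit <- hit[order(hit$from, hit$to), , drop = FALSE]
  add_edges(graph, tibble::tibble(
    from = hit$from, to = hit$to, directed = FALSE,
    provenance = "ENDPOINT_MAPPING", weight = 1, evidence_count = 0L
  ))
}
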