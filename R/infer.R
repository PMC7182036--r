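#' Gene profile of a network node
#'
#' The set of GENE_PROTEIN neighbors of a node over any edge provenance
#' (literature, reference-confirmed or enrichment). For an IMMUNE_ENDPOINT
#' node the profile is the union of the profiles of the bioprocess terms
#' mapped onto it, since endpoints have no direct gene edges.
#'
#' @param graph An `elin_graph`.
#' @param node_id Canonical node id.
#' @return Character vector of gene node ids (possibly empty).
#' @export
gene_profile <- function(graph, node_id) {
  stopifnot(inherits(graph, "elin_graph"))
  if (!(node_id %in% graph$nodes$id)) stop("unknown node: ", node_id)
  profiles <- gene_profiles(graph, node_id)
  profiles[[node_id]]
}

# batch profile computation; ids = nodes to profile
gene_profiles <- function(graph, ids) {
  ed <- graph$edges
  layer_of <- setNames(graph$nodes$layer, graph$nodes$id)
  gene_ids <- graph$nodes$id[graph$nodes$layer == "GENE_PROTEIN"]
  # neighbor pairs in both orientations
  nb <- tibble::tibble(node = c(ed$from, ed$to), other = c(ed$to, ed$from))
  gene_nb <- nb[nb$other %in% gene_ids, , drop = FALSE]
  prof <- split(gene_nb$other, gene_nb$node)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    if (identical(layer_of[[id]], "IMMUNE_ENDPOINT")) {
      terms <- nb$other[nb$node == id]
      terms <- terms[layer_of[terms] != "GENE_PROTEIN"]
      out[[id]] <- sort(unique(unlist(prof[terms], use.names = FALSE)))
    } else {
      out[[id]] <- sort(unique(prof[[id]] %||% character()))
    }
  }
  out
}

#' Infer cross-layer edges from gene-set overlap
#'
#' For every node pair (a, b) with a in `layer_a` and b in `layer_b` whose
#' gene profiles share at least `min_overlap` genes, tests the overlap
#' against a hypergeometric null: drawing `|genes(b)|` genes from a
#' background population of `background_n` containing `|genes(a)|`
#' successes, the p-value is the upper tail P(X >= k). p-values are
#' Benjamini-Hochberg adjusted across all tested pairs of the layer pair,
#' and pairs with q <= `alpha` become undirected INFERRED edges whose
#' weight is the Jaccard similarity of the two profiles.
#'
#' @param graph An enriched `elin_graph`.
#' @param layer_a,layer_b Two distinct codes from [layer_codes()].
#' @param background_n Background population size (number of genes the
#'   annotation universe could have drawn from); must be at least the size
#'   of every tested profile union.
#' @param alpha BH false-discovery level in (0, 1); default 0.05.
#' @param min_overlap Minimum shared-gene count for a pair to be tested;
#'   default 2.
#' @return A list with `graph` (edges added) and `edges`, a tibble of the
#'   significant pairs: `a_id`, `b_id`, `shared_genes` (list-column), `k`,
#'   `jaccard`, `p_value`, `q_value`. The tibble carries the full tested
#'   set (before the q cutoff) in attribute `tested`.
#' @export
infer_edges <- function(graph, layer_a, layer_b, background_n,
                        alpha = 0.05, min_overlap = 2) {
  stopifnot(inherits(graph, "elin_graph"))
  layer_a <- match.arg(layer_a, LAYER_CODES)
  layer_b <- match.arg(layer_b, LAYER_CODES)
  if (layer_a == layer_b) stop("layer_a and layer_b must differ")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (min_overlap < 1) stop("min_overlap must be >= 1")

  a_ids <- graph$nodes$id[graph$nodes$layer == layer_a]
  b_ids <- graph$nodes$id[graph$nodes$layer == layer_b]
  empty <- tibble::tibble(
    a_id = character(), b_id = character(), shared_genes = list(),
    k = integer(), jaccard = double(), p_value = double(), q_value = double()
  )
  if (!length(a_ids) || !length(b_ids)) {
    attr(empty, "tested") <- empty
    return(list(graph = graph, edges = empty))
  }
  prof <- gene_profiles(graph, c(a_ids, b_ids))
  rows <- list()
  for (a in a_ids) {
    pa <- prof[[a]]
    if (length(pa) < min_overlap) next
    for (b in b_ids) {
      pb <- prof[[b]]
      shared <- intersect(pa, pb)
      k <- length(shared)
      if (k < min_overlap) next
      un <- length(union(pa, pb))
      if (un > background_n) {
        stop(sprintf(
          "background_n (%d) smaller than a profile union (%d genes)",
          background_n, un))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        a_id = a, b_id = b, shared_genes = list(shared), k = k,
        jaccard = k / un,
        p_value = hyper_tail(k, length(pa), length(pb), background_n)
      )
    }
  }
  if (!length(rows)) {
    attr(empty, "tested") <- empty
    return(list(graph = graph, edges = empty))
  }
  tested <- dplyr::bind_rows(rows)
  tested$q_value <- p.adjust(tested$p_value, method = "BH")
  tested <- tested[order(tested$p_value, tested$a_id, tested$b_id), ,
                   drop = FALSE]
  sig <- tested[tested$q_value <= alpha, , drop = FALSE]
  if (nrow(sig)) {
    graph <- add_edges(graph, tibble::tibble(
      from = sig$a_id, to = sig$b_id, directed = FALSE,
      provenance = "INFERRED", weight = sig$jaccard, evidence_count = 0L
    ))
  }
  graph <- log_stage(graph, "infer", layer_a = layer_a, layer_b = layer_b,
                     n_tested = nrow(tested), n_inferred = nrow(sig))
  attr(sig, "tested") <- tested
  list(graph = graph, edges = sig)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for the overlap of a fixed success set of size `n_a` with a
#' uniform draw of `n_b` items from a population of `background_n`.
#'
#' @param k Observed overlap.
#' @param n_a,n_b Sizes of the two gene profiles.
#' @param background_n Population size.
#' @return Probability in \[0, 1\].
#' @export
hyper_tail <- function(k, n_a, n_b, background_n) {
  stopifnot(k >= 0, n_a >= 0, n_b >= 0, background_n >= max(n_a, n_b))
  if (k == 0) return(1)
  phyper(k - 1, n_a, background_n - n_a, n_b, lower.tail = FALSE)
}
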