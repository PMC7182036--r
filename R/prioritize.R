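#' PageRank parameters
#'
#' @param damping Probability of following an edge rather than teleporting;
#'   default 0.85 (the classical choice).
#' @param tol Convergence threshold on the L1 change between successive
#'   score vectors; default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @return A list of class `elin_pagerank_params`.
#' @export
pagerank_params <- function(damping = 0.85, tol = 1e-10, max_iter = 1000) {
  stopifnot(damping > 0, damping < 1, tol > 0, max_iter >= 1)
  structure(list(damping = damping, tol = tol, max_iter = max_iter),
            class = "elin_pagerank_params")
}

#' PageRank over the full heterogeneous topology
#'
#' Power iteration on the symmetrized, by default unweighted adjacency
#' with uniform teleportation: important nodes are those receiving
#' associations from other important genes/bioprocesses/diseases, over the
#' whole multilayer topology rather than a local neighborhood. Isolated
#' nodes (e.g. non-human genes whose gene-gene edges were denoised away
#' and that gained no enrichment edges) receive teleport-only mass, giving
#' every node the floor (1 - damping)/N. Deterministic.
#'
#' @param graph A non-empty `elin_graph`.
#' @param params A [pagerank_params()] list.
#' @param use_weights If `TRUE`, transition probabilities are proportional
#'   to edge weights; default `FALSE` (edge strengths are not taken into
#'   account).
#' @return Named numeric vector of scores summing to 1, in node-table order.
#' @export
pagerank <- function(graph, params = pagerank_params(), use_weights = FALSE) {
  stopifnot(inherits(graph, "elin_graph"))
  n <- nrow(graph$nodes)
  if (n == 0) stop("cannot rank an empty graph")
  ids <- graph$nodes$id
  d <- params$damping

  w <- if (use_weights) graph$edges$weight else rep(1, nrow(graph$edges))
  i <- match(graph$edges$from, ids)
  j <- match(graph$edges$to, ids)
  # symmetrized adjacency; parallel provenances between a pair accumulate
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  if (!use_weights && length(A@x)) A@x[] <- 1  # binarize parallel provenances
  deg <- Matrix::colSums(A)
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)

  x <- rep(1 / n, n)
  for (iter in seq_len(params$max_iter)) {
    spread <- as.numeric(A %*% (x * inv_deg))
    x_new <- (1 - d) / n + d * (spread + sum(x[dangling]) / n)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < params$tol) {
      return(setNames(x / sum(x), ids))
    }
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %.3g)",
               params$max_iter, delta))
}

#' Rank all nodes by PageRank score
#'
#' @param graph An `elin_graph`.
#' @param scores Output of [pagerank()]; computed if missing.
#' @param params Passed to [pagerank()] when `scores` is missing.
#' @return Tibble with `node_id`, `label`, `layer`, `score`,
#'   `overall_rank` and `layer_rank` (both dense, ties broken
#'   lexicographically by node id).
#' @export
rank_nodes <- function(graph, scores = NULL, params = pagerank_params()) {
  stopifnot(inherits(graph, "elin_graph"))
  if (is.null(scores)) scores <- pagerank(graph, params)
  df <- tibble::tibble(
    node_id = graph$nodes$id,
    label = graph$nodes$label,
    layer = graph$nodes$layer,
    score = unname(scores[graph$nodes$id])
  )
  df <- df[order(-df$score, df$node_id), , drop = FALSE]
  df$overall_rank <- seq_len(nrow(df))
  df <- df |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(layer_rank = dplyr::row_number()) |>
    dplyr::ungroup()
  df
}

#' Top-ranked genes of a period network
#'
#' Ranks globally over all nodes, then restricts to the GENE_PROTEIN layer
#' and returns the `k` highest-scoring genes (score descending, ties by
#' node id ascending); fewer if the layer is smaller.
#'
#' @param scores Output of [pagerank()].
#' @param graph The ranked `elin_graph`.
#' @param k List length; default 50.
#' @return Tibble with `rank`, `node_id`, `label`, `score`, `layer`.
#' @export
top_genes <- function(scores, graph, k = 50) {
  stopifnot(k >= 1)
  ranked <- rank_nodes(graph, scores)
  genes <- ranked[ranked$layer == "GENE_PROTEIN", , drop = FALSE]
  genes <- head(genes, k)
  tibble::tibble(
    rank = seq_len(nrow(genes)),
    node_id = genes$node_id,
    label = genes$label,
    score = genes$score,
    layer = genes$layer
  )
}
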