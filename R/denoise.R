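#' Denoise literature gene-gene edges against a reference interactome
#'
#' Every LITERATURE edge joining two GENE_PROTEIN nodes is kept only if its
#' unordered gene-symbol pair occurs in the reference human association
#' table (any network type; direction and reference weight are ignored).
#' Retained edges are re-tagged REFERENCE_CONFIRMED. Gene-gene edges
#' touching a non-human gene node (no HGNC grounding) can never be
#' confirmed and are always removed. Edges with at least one non-gene
#' endpoint are untouched. Nodes are never removed: unsupported genes stay
#' in the network as disconnected nodes so later enrichment can reconnect
#' them.
#'
#' @param graph An assembled `elin_graph`.
#' @param ref A reference table from [read_reference_edges()].
#' @return A list with `graph` (denoised) and `report`, a one-row tibble
#'   with `period`, `n_genes`, `n_literature_gene_edges`, `n_confirmed` and
#'   `pct_confirmed` (integer percent, rounded half-up, 0 when there are no
#'   gene-gene literature edges).
#' @export
denoise_graph <- function(graph, ref) {
  stopifnot(inherits(graph, "elin_graph"))
  stopifnot(inherits(ref, "elin_reference") || is.data.frame(ref))
  if (!nrow(ref)) warning("empty reference table: removing all gene-gene edges")

  gene_ids <- graph$nodes$id[graph$nodes$layer == "GENE_PROTEIN"]
  human <- graph$nodes$id[graph$nodes$layer == "GENE_PROTEIN" &
                            graph$nodes$is_human_gene]
  symbol_of <- setNames(toupper(graph$nodes$label), graph$nodes$id)

  ed <- graph$edges
  is_gg <- ed$provenance == "LITERATURE" &
    ed$from %in% gene_ids & ed$to %in% gene_ids
  ref_keys <- if (nrow(ref)) pair_key(ref$gene_a, ref$gene_b) else character()
  confirmed <- is_gg & ed$from %in% human & ed$to %in% human &
    pair_key(symbol_of[ed$from], symbol_of[ed$to]) %in% ref_keys

  ed$provenance[confirmed] <- "REFERENCE_CONFIRMED"
  keep <- !is_gg | confirmed
  out <- graph
  out$edges <- ed[keep, , drop = FALSE]

  n_gg <- sum(is_gg)
  n_conf <- sum(confirmed)
  report <- tibble::tibble(
    period = graph$period,
    n_genes = length(gene_ids),
    n_literature_gene_edges = n_gg,
    n_confirmed = n_conf,
    pct_confirmed = pct_round(n_conf, n_gg)
  )
  out <- log_stage(out, "denoise", n_gene_edges = n_gg, n_confirmed = n_conf,
                   n_removed = n_gg - n_conf)
  list(graph = out, report = report)
}

# integer percent, half-up, 0/0 -> 0
pct_round <- function(num, den) {
  if (den <= 0) return(0L)
  as.integer(floor(100 * num / den + 0.5))
}

#' Render per-period confirmation statistics
#'
#' Collates one denoising report per period into the conventional
#' confirmation table: gene count, literature gene-gene edge count, and
#' `"confirmed (pct%)"` in one column.
#'
#' @param reports A list of (or single row-bound tibble of) reports from
#'   [denoise_graph()]; at most one per period.
#' @param path Optional TSV output path.
#' @return Tibble with columns `period`, `n_genes`, `n_edges`, `confirmed`.
#' @export
confirmation_table <- function(reports, path = NULL) {
  df <- if (is.data.frame(reports)) reports else dplyr::bind_rows(reports)
  if (any(duplicated(df$period))) stop("duplicate period in reports")
  df <- df[order(match(df$period, PERIOD_CODES)), , drop = FALSE]
  out <- tibble::tibble(
    period = df$period,
    n_genes = df$n_genes,
    n_edges = df$n_literature_gene_edges,
    confirmed = sprintf("%d (%d%%)", df$n_confirmed, df$pct_confirmed)
  )
  if (!is.null(path)) write_tsv_plain(out, path)
  out
}
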