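STMT_TYPES <- c("Activation", "Inhibition", "IncreaseAmount",
                "DecreaseAmount", "Complex", "Association")
DIRECTIONAL_TYPES <- c("Activation", "Inhibition", "IncreaseAmount",
                       "DecreaseAmount")

#' Parse a causal-statement file
#'
#' Reads a JSON array of text-mined causal statements (one record per
#' relationship: `type`, `subj`/`obj` entities with `name` and `db_refs`
#' groundings, `evidence_count`, `pmids`, `period`; the schema ships at
#' `system.file("extdata", "statement-schema.json", package = "elin")`).
#' Records with an unknown statement type, a missing entity, or a subject
#' equal to the object after canonicalization are counted and skipped, not
#' fatal; more than 50% invalid records aborts with a malformed-input
#' error. Order of valid records is preserved.
#'
#' @param path Path to the statement JSON file.
#' @return A tibble with one row per valid statement: list-columns `subj`
#'   and `obj` (entities), `stmt_type`, `evidence_count`, `pmids`
#'   (list-column), `period`, plus attributes `n_invalid` (unparseable or
#'   unknown-type records) and `n_self` (self-statements dropped).
#' @export
parse_statements <- function(path) {
  if (!file.exists(path)) stop("cannot read statement file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw)) stop("malformed statement file (expected a JSON array)")
  n_invalid <- 0L
  n_self <- 0L
  rows <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    rec <- raw[[i]]
    parsed <- tryCatch(parse_statement_record(rec), error = function(e) NULL)
    if (is.null(parsed)) {
      n_invalid <- n_invalid + 1L
      next
    }
    if (canonical_id(parsed$subj) == canonical_id(parsed$obj)) {
      n_self <- n_self + 1L
      next
    }
    rows[[i]] <- parsed
  }
  if (length(raw) > 0 && n_invalid > length(raw) / 2) {
    stop(sprintf("malformed input: %d of %d statement records invalid",
                 n_invalid, length(raw)))
  }
  if (n_invalid > 0) {
    warning(sprintf("%d invalid statement record(s) skipped", n_invalid))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- tibble::tibble(
    subj = lapply(rows, `[[`, "subj"),
    obj = lapply(rows, `[[`, "obj"),
    stmt_type = vapply(rows, `[[`, character(1), "stmt_type"),
    evidence_count = vapply(rows, `[[`, integer(1), "evidence_count"),
    pmids = lapply(rows, `[[`, "pmids"),
    period = vapply(rows, `[[`, character(1), "period")
  )
  attr(out, "n_invalid") <- n_invalid
  attr(out, "n_self") <- n_self
  out
}

parse_statement_record <- function(rec) {
  if (!is.list(rec) || is.null(rec$type) || is.null(rec$subj) ||
      is.null(rec$obj)) {
    stop("incomplete record")
  }
  if (!(rec$type %in% STMT_TYPES)) stop("unknown statement type: ", rec$type)
  if (is.null(rec$period) || !(rec$period %in% PERIOD_CODES)) {
    stop("missing or unknown period tag")
  }
  period <- rec$period
  ev <- as.integer(rec$evidence_count %||% 1L)
  if (is.na(ev) || ev < 1L) stop("evidence_count must be >= 1")
  list(
    subj = record_entity(rec$subj),
    obj = record_entity(rec$obj),
    stmt_type = rec$type,
    evidence_count = ev,
    pmids = as.character(unlist(rec$pmids %||% character())),
    period = period
  )
}

record_entity <- function(x) {
  if (!is.list(x) || is.null(x$name)) stop("entity without a name")
  entity(x$name, groundings = x$db_refs %||% character(),
         hint = x$kind %||% "none")
}

#' Assemble a period literature network
#'
#' De-duplicates parsed statements into one multilayer graph: one node per
#' canonical entity id, and one LITERATURE edge per unordered node pair.
#' Statements collapsing onto the same pair merge with summed evidence
#' counts (weight stays 1); the merged edge is directed only if every
#' contributing statement type is directional and they all point the same
#' way. The result is order-invariant in the statement list.
#'
#' @param statements Tibble from [parse_statements()].
#' @param period Period code; all statements must carry this period tag.
#' @return An `elin_graph` whose `build_log` records input/output counts.
#' @export
assemble_network <- function(statements, period) {
  period <- match.arg(period, PERIOD_CODES)
  graph <- new_graph(period)
  if (!nrow(statements)) {
    warning("no statements: returning an empty ", period, " network")
    return(log_stage(graph, "assemble", n_statements = 0L, n_nodes = 0L,
                     n_edges = 0L))
  }
  if (!all(statements$period == period)) {
    stop("statements tagged with a different period than ", period)
  }
  ents <- c(statements$subj, statements$obj)
  ids <- vapply(ents, canonical_id, character(1))
  nodes <- tibble::tibble(
    id = ids,
    label = vapply(ents, `[[`, character(1), "name"),
    layer = vapply(ents, `[[`, character(1), "layer"),
    is_human_gene = vapply(ents, `[[`, logical(1), "is_human_gene")
  )
  # deterministic node table regardless of statement order
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  graph <- add_nodes(graph, nodes)

  n <- nrow(statements)
  subj_id <- ids[seq_len(n)]
  obj_id <- ids[n + seq_len(n)]
  df <- tibble::tibble(
    a = pmin(subj_id, obj_id), b = pmax(subj_id, obj_id),
    # direction recorded on the canonical (a, b) orientation
    dir = ifelse(statements$stmt_type %in% DIRECTIONAL_TYPES,
                 ifelse(subj_id <= obj_id, "ab", "ba"), "undir"),
    evidence_count = statements$evidence_count
  )
  merged <- df |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(
      evidence_count = sum(.data$evidence_count),
      one_dir = dplyr::n_distinct(.data$dir) == 1 && .data$dir[1] != "undir",
      dir = .data$dir[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$a, .data$b)
  edges <- tibble::tibble(
    from = ifelse(merged$one_dir & merged$dir == "ba", merged$b, merged$a),
    to = ifelse(merged$one_dir & merged$dir == "ba", merged$a, merged$b),
    directed = merged$one_dir,
    provenance = "LITERATURE",
    weight = 1,
    evidence_count = as.integer(merged$evidence_count)
  )
  graph <- add_edges(graph, edges)
  log_stage(graph, "assemble",
            n_statements = n,
            n_invalid = attr(statements, "n_invalid") %||% 0L,
            n_self = attr(statements, "n_self") %||% 0L,
            n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges))
}

#' Read a reference gene-gene association table
#'
#' Tab-separated with header `gene_a`, `gene_b`, `network_type`, `weight`
#' (weights in (0, 1]); `#` comment lines allowed. Symbols are uppercased;
#' duplicate unordered pairs within a network type are collapsed (count
#' logged as a warning); self-pairs are dropped.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `elin_reference` with the four columns.
#' @export
read_reference_edges <- function(path) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b", "network_type", "weight"))
  if (!nrow(df)) {
    warning("reference edge table is empty")
    out <- tibble::as_tibble(df)
    class(out) <- c("elin_reference", class(out))
    return(out)
  }
  df$gene_a <- toupper(trimws(df$gene_a))
  df$gene_b <- toupper(trimws(df$gene_b))
  df$weight <- as.double(df$weight)
  if (any(!is.finite(df$weight) | df$weight <= 0 | df$weight > 1)) {
    stop("reference weights must lie in (0, 1]")
  }
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  key <- paste(pair_key(df$gene_a, df$gene_b), df$network_type)
  ndup <- sum(duplicated(key))
  if (ndup > 0) warning(ndup, " duplicate reference row(s) collapsed")
  out <- tibble::as_tibble(df[!duplicated(key), , drop = FALSE])
  class(out) <- c("elin_reference", class(out))
  out
}

#' Read a gene annotation table
#'
#' For sources `GO`, `GOSLIM` and `DISEASE` the TSV has header `gene`,
#' `term_id`, `term_name`; gene symbols are uppercased and duplicate
#' (gene, term) rows merged. For source `ENDPOINT_MAP` the header is
#' `term_id`, `endpoint`: a curated mapping from bioprocess terms to the
#' four immune health endpoints.
#'
#' @param path Path to the TSV.
#' @param source One of `"GO"`, `"GOSLIM"`, `"DISEASE"`, `"ENDPOINT_MAP"`.
#' @return A tibble of class `elin_annotation` with attribute `source`.
#' @export
read_annotations <- function(path, source) {
  source <- match.arg(source, c("GO", "GOSLIM", "DISEASE", "ENDPOINT_MAP"))
  if (source == "ENDPOINT_MAP") {
    df <- read_tsv_checked(path, c("term_id", "endpoint"))
    if (nrow(df)) {
      df$endpoint <- tolower(trimws(df$endpoint))
      bad <- setdiff(unique(df$endpoint), IMMUNE_ENDPOINTS)
      if (length(bad)) {
        stop("unknown immune endpoint(s): ", paste(bad, collapse = ", "))
      }
      key <- paste(df$term_id, df$endpoint)
      df <- df[!duplicated(key), , drop = FALSE]
    } else {
      warning("annotation table is empty: ", path)
    }
  } else {
    df <- read_tsv_checked(path, c("gene", "term_id", "term_name"),
                           keep = "score")
    if (nrow(df)) {
      df$gene <- toupper(trimws(df$gene))
      key <- paste(df$gene, df$term_id)
      ndup <- sum(duplicated(key))
      if (ndup > 0) warning(ndup, " duplicate annotation row(s) collapsed")
      df <- df[!duplicated(key), , drop = FALSE]
    } else {
      warning("annotation table is empty: ", path)
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "source") <- source
  class(out) <- c("elin_annotation", class(out))
  out
}

read_tsv_checked <- function(path, required, keep = character()) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  df[, c(required, intersect(keep, names(df))), drop = FALSE]
}
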