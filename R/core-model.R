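#' Early-life period vocabulary
#'
#' The six human early-life periods used throughout the package, in
#' developmental order: the three gestational trimesters (`EG`, `MG`, `LG`),
#' `BIRTH`, `NEWBORN` (0--28 days) and `INFANT` (1--23 months).
#'
#' @return `periods()` returns a tibble with columns `code` (ordered factor)
#'   and `human_window` (free-text span label); `period_codes()` returns the
#'   six codes as a character vector in developmental order.
#' @examples
#' periods()
#' @export
periods <- function() {
  tibble::tibble(
    code = factor(PERIOD_CODES, levels = PERIOD_CODES, ordered = TRUE),
    human_window = c("GD0\u2013GW12", "GW13\u201328", "GW29\u201340",
                     "", "0\u201328 days", "1\u201323 months")
  )
}

PERIOD_CODES <- c("EG", "MG", "LG", "BIRTH", "NEWBORN", "INFANT")

#' @rdname periods
#' @export
period_codes <- function() PERIOD_CODES

#' Node-layer taxonomy
#'
#' The eight node layers of the multilayer immune network: genes/proteins
#' (conflated into one node type because literature often uses the same
#' name for both), protein families, chemicals, text-mining bioprocesses,
#' GO processes, GO-slim processes, diseases, and the four immune health
#' endpoints.
#'
#' @return Character vector of the eight layer codes.
#' @export
layer_codes <- function() LAYER_CODES

LAYER_CODES <- c("GENE_PROTEIN", "PROTEIN_FAMILY", "CHEMICAL",
                 "INDRA_BIOPROCESS", "GO_PROCESS", "GOSLIM_PROCESS",
                 "DISEASE", "IMMUNE_ENDPOINT")

#' Immune health endpoints
#'
#' The four fixed top-layer outcomes every period network is mapped onto:
#' autoimmunity, hypersensitivity, resistance to neoplasms and resistance
#' to infections. These are a closed enumeration, not user input.
#'
#' @return Character vector of length four.
#' @export
immune_endpoints <- function() IMMUNE_ENDPOINTS

IMMUNE_ENDPOINTS <- c("autoimmunity", "hypersensitivity",
                      "resistance to neoplasms", "resistance to infections")

# Grounding namespaces in precedence order for canonical ids. HGNC wins so
# that surface-form variants of the same human gene merge into one node.
NS_PRECEDENCE <- c("HGNC", "FPLX", "CHEBI", "GO", "GOSLIM",
                   "MESH", "DOID", "UMLS")
DISEASE_NS <- c("MESH", "DOID", "UMLS")

#' Construct a grounded entity
#'
#' An entity is one biological node candidate: a display name, a (possibly
#' empty) map of namespace -> identifier groundings, and an optional kind
#' hint carried by the statement source for ungrounded entities
#' (`"bioprocess"` for terms the text-mining ontology tagged as processes,
#' `"gene"` for gene-like symbols such as non-human contaminants).
#'
#' @param name Display label (non-empty string).
#' @param groundings Named character vector mapping namespaces (HGNC, FPLX,
#'   CHEBI, GO, GOSLIM, MESH, DOID, UMLS) to identifiers. A `TEXT` entry, as
#'   emitted by text-mining groundings, is dropped.
#' @param hint One of `"none"`, `"bioprocess"`, `"gene"`.
#' @return An object of class `elin_entity` with fields `name`, `groundings`,
#'   `hint`, plus the derived `layer` and `is_human_gene`.
#' @examples
#' entity("TNF", c(HGNC = "11892"))
#' entity("lacZ", hint = "gene")
#' @export
entity <- function(name, groundings = character(), hint = "none") {
  if (is.list(groundings)) groundings <- unlist(groundings)
  if (is.null(groundings)) groundings <- character()
  groundings <- groundings[names(groundings) != "TEXT"]
  if ((is.null(name) || !nzchar(trimws(name %||% ""))) && !length(groundings)) {
    stop("invalid entity: empty name and empty groundings", call. = FALSE)
  }
  hint <- match.arg(hint, c("none", "bioprocess", "gene"))
  e <- structure(
    list(name = as.character(name), groundings = groundings, hint = hint),
    class = "elin_entity"
  )
  e$layer <- assign_layer(e)
  e$is_human_gene <- "HGNC" %in% names(groundings)
  e
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.elin_entity <- function(x, ...) {
  cat(sprintf("<entity> %s [%s] %s\n", x$name, x$layer, canonical_id(x)))
  invisible(x)
}

#' Canonical node identifier
#'
#' Deterministic id of the form `"NAMESPACE:identifier"` taken from the
#' highest-precedence grounding (HGNC > FPLX > CHEBI > GO > GOSLIM > disease
#' namespaces); ungrounded entities fall back to `"TEXT:<UPPERCASED NAME>"`
#' so case variants of the same text-mined symbol merge. Two entities with
#' the same HGNC id map to the same node id regardless of surface name.
#'
#' @param x An `elin_entity`.
#' @return A single string.
#' @examples
#' canonical_id(entity("tumor necrosis factor", c(HGNC = "11892")))
#' canonical_id(entity("lacZ", hint = "gene"))
#' @export
canonical_id <- function(x) {
  stopifnot(inherits(x, "elin_entity"))
  gr <- x$groundings
  for (ns in NS_PRECEDENCE) {
    if (ns %in% names(gr)) {
      id <- sub(paste0("^", ns, ":"), "", gr[[ns]])
      return(paste0(ns, ":", id))
    }
  }
  if (!nzchar(trimws(x$name))) {
    stop("invalid entity: empty name and empty groundings", call. = FALSE)
  }
  paste0("TEXT:", toupper(trimws(x$name)))
}

#' Assign an entity to its network layer
#'
#' Layer is a pure function of the groundings (and, for ungrounded
#' entities, the statement-source kind hint): HGNC -> GENE_PROTEIN;
#' FPLX -> PROTEIN_FAMILY; CHEBI -> CHEMICAL; GO -> GO_PROCESS;
#' GOSLIM -> GOSLIM_PROCESS; MESH/DOID/UMLS -> DISEASE. The four immune
#' endpoint names (matched case-insensitively) always map to
#' IMMUNE_ENDPOINT. Ungrounded entities hinted as bioprocesses become
#' INDRA_BIOPROCESS; ungrounded gene-like symbols (hinted `"gene"`, or
#' short single tokens) become GENE_PROTEIN with `is_human_gene = FALSE`
#' so non-human contaminants such as lacZ or env stay in the network;
#' any other ungrounded multi-word name is treated as a text-mined
#' bioprocess. Total function: never errors on a well-formed entity.
#'
#' @param x An `elin_entity`.
#' @return One of [layer_codes()].
#' @export
assign_layer <- function(x) {
  stopifnot(inherits(x, "elin_entity"))
  if (tolower(trimws(x$name)) %in% IMMUNE_ENDPOINTS) return("IMMUNE_ENDPOINT")
  ns <- names(x$groundings)
  if ("HGNC" %in% ns) return("GENE_PROTEIN")
  if ("FPLX" %in% ns) return("PROTEIN_FAMILY")
  if ("CHEBI" %in% ns) return("CHEMICAL")
  if ("GO" %in% ns) return("GO_PROCESS")
  if ("GOSLIM" %in% ns) return("GOSLIM_PROCESS")
  if (any(DISEASE_NS %in% ns)) return("DISEASE")
  if (x$hint == "bioprocess") return("INDRA_BIOPROCESS")
  if (x$hint == "gene") return("GENE_PROTEIN")
  # no grounding, no hint: short single-token symbols look like genes,
  # longer free text looks like a text-mined process description
  nm <- trimws(x$name)
  if (!grepl("\\s", nm) && nchar(nm) <= 10) "GENE_PROTEIN" else "INDRA_BIOPROCESS"
}
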