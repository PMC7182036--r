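test_that("period and layer vocabularies are closed and ordered", {
  p <- periods()
  expect_equal(as.character(p$code), c("EG", "MG", "LG", "BIRTH", "NEWBORN",
                                       "INFANT"))
  expect_true(is.ordered(p$code))
  expect_equal(p$human_window,
               c("GD0\u2013GW12", "GW13\u201328", "GW29\u201340", "",
                 "0\u201328 days", "1\u201323 months"))
  expect_length(layer_codes(), 8)
  expect_length(immune_endpoints(), 4)
})

test_that("canonical ids follow the grounding precedence rule", {
  expect_equal(canonical_id(entity("tumor necrosis factor",
                                   c(HGNC = "11892"))), "HGNC:11892")
  expect_equal(canonical_id(entity("lacZ", hint = "gene")), "TEXT:LACZ")
  # merge-by-grounding: surface form is irrelevant once HGNC is present
  expect_equal(canonical_id(entity("TNF", c(HGNC = "11892"))),
               canonical_id(entity("TNF-alpha", c(HGNC = "11892"))))
  # HGNC outranks every other namespace
  expect_equal(canonical_id(entity("x", c(GO = "GO:1", HGNC = "5"))),
               "HGNC:5")
  # namespace-prefixed identifiers are not doubled
  expect_equal(canonical_id(entity("immune response",
                                   c(GO = "GO:0006955"))), "GO:0006955")
  # case variants of ungrounded names merge
  expect_equal(canonical_id(entity("Env", hint = "gene")),
               canonical_id(entity("env", hint = "gene")))
})

test_that("canonical_id is idempotent and injective within a namespace", {
  es <- list(entity("a", c(HGNC = "1")), entity("b", c(HGNC = "2")),
             entity("c", c(CHEBI = "1")), entity("d"))
  ids <- vapply(es, canonical_id, character(1))
  expect_equal(ids, vapply(es, canonical_id, character(1)))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("entity construction rejects the empty entity", {
  expect_error(entity("", character()), "invalid entity")
  expect_error(entity(NULL, NULL), "invalid entity")
})

test_that("layer assignment follows grounding, endpoints and hints", {
  expect_equal(assign_layer(entity("x", c(GO = "GO:0006955"))), "GO_PROCESS")
  expect_equal(assign_layer(entity("TNF", c(HGNC = "11892"))), "GENE_PROTEIN")
  expect_equal(assign_layer(entity("TGFB", c(FPLX = "TGFB"))),
               "PROTEIN_FAMILY")
  expect_equal(assign_layer(entity("retinol", c(CHEBI = "17336"))), "CHEMICAL")
  expect_equal(assign_layer(entity("asthma", c(MESH = "D001249"))), "DISEASE")
  expect_equal(assign_layer(entity("Autoimmunity")), "IMMUNE_ENDPOINT")
  e <- entity("env", hint = "gene")
  expect_equal(e$layer, "GENE_PROTEIN")
  expect_false(e$is_human_gene)
  expect_equal(assign_layer(entity("inflammatory response of the gut",
                                   hint = "bioprocess")), "INDRA_BIOPROCESS")
  # is_human_gene true iff HGNC grounding exists
  expect_true(entity("TNF", c(HGNC = "11892"))$is_human_gene)
  expect_false(entity("immune response", c(GO = "GO:0006955"))$is_human_gene)
})

test_that("layer assignment is deterministic under shuffling", {
  set.seed(7)
  ents <- lapply(1:40, function(i) {
    switch(sample(4, 1),
           entity(paste0("G", i), c(HGNC = as.character(i))),
           entity(paste0("chem", i), c(CHEBI = as.character(i))),
           entity(paste0("process number ", i), hint = "bioprocess"),
           entity(paste0("sym", i), hint = "gene"))
  })
  layers1 <- vapply(ents, assign_layer, character(1))
  perm <- sample(seq_along(ents))
  layers2 <- vapply(ents[perm], assign_layer, character(1))
  expect_equal(layers2, layers1[perm])
})

test_that("graphs round-trip through GraphML and TSV without loss", {
  g <- toy_enriched_graph()
  g <- add_nodes(g, tibble::tibble(id = "TEXT:LACZ", label = "lacZ",
                                   layer = "GENE_PROTEIN",
                                   is_human_gene = FALSE))
  gml <- withr::local_tempfile(fileext = ".graphml")
  nt <- withr::local_tempfile(fileext = ".tsv")
  et <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, graphml = gml, nodes_tsv = nt, edges_tsv = et)
  for (g2 in list(read_network(graphml = gml),
                  read_network(nodes_tsv = nt, edges_tsv = et))) {
    expect_equal(g2$period, g$period)
    expect_equal(dplyr::arrange(g2$nodes, id), dplyr::arrange(g$nodes, id))
    key <- function(gr) sort(paste(pmin(gr$edges$from, gr$edges$to),
                                   pmax(gr$edges$from, gr$edges$to),
                                   gr$edges$provenance))
    expect_equal(key(g2), key(g))
  }
})

test_that("edge invariants are enforced", {
  g <- new_graph("EG")
  g <- add_nodes(g, gene_nodes(c("A", "B")))
  expect_error(add_edges(g, tibble::tibble(
    from = "HGNC:5001", to = "HGNC:5001", directed = FALSE,
    provenance = "LITERATURE", weight = 1, evidence_count = 1L
  )), "self-loop")
  expect_error(add_edges(g, tibble::tibble(
    from = "HGNC:5001", to = "HGNC:9999", directed = FALSE,
    provenance = "LITERATURE", weight = 1, evidence_count = 1L
  )), "not in node set")
  expect_error(add_edges(g, tibble::tibble(
    from = "HGNC:5001", to = "HGNC:5002", directed = FALSE,
    provenance = "LITERATURE", weight = 0, evidence_count = 1L
  )), "weight")
  # one edge per unordered pair and provenance
  e <- tibble::tibble(from = c("HGNC:5001", "HGNC:5002"),
                      to = c("HGNC:5002", "HGNC:5001"), directed = FALSE,
                      provenance = "LITERATURE", weight = 1,
                      evidence_count = 1L)
  expect_equal(nrow(add_edges(g, e)$edges), 1)
})
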