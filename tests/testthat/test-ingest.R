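test_that("parse_statements filters invalid records and logs counts", {
  recs <- list(
    stmt_record("IL6", "STAT3", subj_refs = list(HGNC = "6018"),
                obj_refs = list(HGNC = "11364")),
    stmt_record("TNF", "IL10", subj_refs = list(HGNC = "11892"),
                obj_refs = list(HGNC = "5962")),
    stmt_record("CD4", "FOXP3", subj_refs = list(HGNC = "1678"),
                obj_refs = list(HGNC = "6106")),
    stmt_record("A", "B", type = "Translocation")  # unknown type
  )
  path <- write_statement_file(recs)
  expect_warning(st <- parse_statements(path), "1 invalid")
  expect_equal(nrow(st), 3)
  expect_equal(attr(st, "n_invalid"), 1L)
  # order preserved
  expect_equal(vapply(st$subj, `[[`, character(1), "name"),
               c("IL6", "TNF", "CD4"))
})

test_that("parse_statements handles empty files and self-statements", {
  empty <- write_statement_file(list())
  expect_equal(nrow(parse_statements(empty)), 0)

  selfy <- write_statement_file(list(
    stmt_record("TNF", "TNF-alpha", subj_refs = list(HGNC = "11892"),
                obj_refs = list(HGNC = "11892")),
    stmt_record("IL6", "STAT3", subj_refs = list(HGNC = "6018"),
                obj_refs = list(HGNC = "11364"))
  ))
  st <- parse_statements(selfy)
  expect_equal(nrow(st), 1)
  expect_equal(attr(st, "n_self"), 1L)
})

test_that("parse_statements aborts when most records are invalid", {
  path <- write_statement_file(list(
    stmt_record("A", "B", type = "Nope"),
    stmt_record("C", "D", type = "AlsoNope"),
    stmt_record("IL6", "STAT3", subj_refs = list(HGNC = "6018"),
                obj_refs = list(HGNC = "11364"))
  ))
  expect_error(parse_statements(path), "malformed input")
  expect_error(parse_statements(tempfile()), "cannot read")
})

test_that("assembly merges duplicate pairs and sums evidence", {
  path <- write_statement_file(list(
    stmt_record("IL6", "STAT3", type = "Activation", evidence = 2L,
                subj_refs = list(HGNC = "6018"),
                obj_refs = list(HGNC = "11364")),
    stmt_record("STAT3", "IL6", type = "Association", evidence = 1L,
                subj_refs = list(HGNC = "11364"),
                obj_refs = list(HGNC = "6018"))
  ))
  g <- assemble_network(parse_statements(path), "NEWBORN")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$evidence_count, 3L)
  expect_equal(g$edges$provenance, "LITERATURE")
  expect_false(g$edges$directed)  # Association joined in -> undirected
})

test_that("five statements over four distinct pairs give four edges", {
  # brute-force expectation: pair keys {A-B, A-C, B-C, C-D}
  mk <- function(s, o, ev = 1L) {
    stmt_record(s, o, evidence = ev, subj_refs = list(HGNC = s),
                obj_refs = list(HGNC = o))
  }
  recs <- list(mk("1", "2"), mk("1", "3"), mk("2", "3", 2L), mk("3", "4"),
               mk("2", "1"))
  st <- parse_statements(write_statement_file(recs))
  pairs <- unique(vapply(seq_len(nrow(st)), function(i) {
    a <- canonical_id(st$subj[[i]]); b <- canonical_id(st$obj[[i]])
    paste(pmin(a, b), pmax(a, b))
  }, character(1)))
  g <- assemble_network(st, "NEWBORN")
  expect_equal(nrow(g$edges), length(pairs))
  expect_equal(nrow(g$edges), 4)
})

test_that("assembly is order-invariant and conserves evidence mass", {
  set.seed(11)
  syms <- sprintf("G%02d", 1:15)
  recs <- lapply(1:60, function(i) {
    pair <- sample(syms, 2)
    stmt_record(pair[1], pair[2],
                type = sample(c("Activation", "Inhibition", "Association"), 1),
                evidence = sample(1:3, 1),
                subj_refs = list(HGNC = substring(pair[1], 2)),
                obj_refs = list(HGNC = substring(pair[2], 2)))
  })
  st <- parse_statements(write_statement_file(recs))
  g1 <- assemble_network(st, "NEWBORN")
  shuffled <- st[sample(nrow(st)), ]
  attr(shuffled, "n_invalid") <- 0L; attr(shuffled, "n_self") <- 0L
  g2 <- assemble_network(shuffled, "NEWBORN")
  expect_equal(g2$nodes, g1$nodes)
  expect_equal(dplyr::arrange(g2$edges, from, to),
               dplyr::arrange(g1$edges, from, to))
  expect_equal(sum(g1$edges$evidence_count), sum(st$evidence_count))
})

test_that("directed edges survive only when all merged statements agree", {
  mk <- function(s, o, type) {
    stmt_record(s, o, type = type, period = "EG",
                subj_refs = list(HGNC = s), obj_refs = list(HGNC = o))
  }
  st <- parse_statements(write_statement_file(list(
    mk("1", "2", "Activation"), mk("1", "2", "Inhibition"),  # same direction
    mk("3", "4", "Activation"), mk("4", "3", "Activation")   # opposing
  )))
  g <- assemble_network(st, "EG")
  ed <- dplyr::arrange(g$edges, from)
  expect_true(ed$directed[ed$from == "HGNC:1"])
  expect_false(ed$directed[ed$from %in% c("HGNC:3", "HGNC:4")])
})

test_that("empty statement set assembles to an empty graph with a warning", {
  st <- parse_statements(write_statement_file(list()))
  expect_warning(g <- assemble_network(st, "BIRTH"), "no statements")
  expect_equal(nrow(g$nodes), 0)
  expect_equal(g$period, "BIRTH")
})

test_that("reference table reading collapses duplicates and uppercases", {
  df <- data.frame(gene_a = c("tnf", "IL6", "TNF", "CD4"),
                   gene_b = c("IL6", "tnf", "il6", "FOXP3"),
                   network_type = "physical", weight = 0.4)
  expect_warning(ref <- read_reference_edges(write_ref_tsv(df)), "duplicate")
  expect_equal(nrow(ref), 2)
  expect_true(all(ref$gene_a == toupper(ref$gene_a)))
  # missing column -> schema error naming it
  bad <- write_ref_tsv(df[, -4])
  expect_error(read_reference_edges(bad), "weight")
  # empty-but-headered -> empty table with warning
  empty <- write_ref_tsv(df[0, ])
  expect_warning(r0 <- read_reference_edges(empty), "empty")
  expect_equal(nrow(r0), 0)
})

test_that("annotation reading enforces source labels and merges case variants", {
  df <- data.frame(gene = c("il6", "IL6", "Tnf"), term_id = "GO:0006955",
                   term_name = "immune response")
  expect_warning(ann <- read_annotations(write_ref_tsv(df), "GO"),
                 "duplicate")
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$gene, c("IL6", "TNF"))
  expect_error(read_annotations(write_ref_tsv(df), "GWAS"))
  emap <- data.frame(term_id = "GO:0002376",
                     endpoint = "Resistance to infections")
  em <- read_annotations(write_ref_tsv(emap), "ENDPOINT_MAP")
  expect_equal(em$endpoint, "resistance to infections")
  bad <- data.frame(term_id = "GO:1", endpoint = "longevity")
  expect_error(read_annotations(write_ref_tsv(bad), "ENDPOINT_MAP"),
               "unknown immune endpoint")
})
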