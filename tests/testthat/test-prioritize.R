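two_node_graph <- function() {
  g <- new_graph("EG")
  g <- add_nodes(g, gene_nodes(c("A", "B")))
  add_edges(g, tibble::tibble(from = "HGNC:5001", to = "HGNC:5002",
                              directed = FALSE, provenance = "LITERATURE",
                              weight = 1, evidence_count = 1L))
}

star_graph <- function() {
  g <- new_graph("EG")
  g <- add_nodes(g, gene_nodes(c("C", "L1", "L2", "L3")))
  add_edges(g, tibble::tibble(
    from = "HGNC:5001", to = paste0("HGNC:", 5002:5004), directed = FALSE,
    provenance = "LITERATURE", weight = 1, evidence_count = 1L
  ))
}

test_that("two symmetric nodes split the score evenly", {
  s <- pagerank(two_node_graph())
  expect_equal(unname(s), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("star scores match the dense eigen solution", {
  g <- star_graph()
  s <- pagerank(g)
  # closed form for a 3-leaf star at damping 0.85:
  # center = (0.0375 + 0.85) / 1.85, each leaf = (1 - center) / 3
  expect_equal(unname(s["HGNC:5001"]), 0.8875 / 1.85, tolerance = 1e-8)
  expect_equal(unname(s["HGNC:5002"]), (1 - 0.8875 / 1.85) / 3,
               tolerance = 1e-8)
  oracle <- oracle_pagerank_eigen(g)
  expect_equal(s, oracle[names(s)], tolerance = 1e-8)
})

test_that("scores sum to one and respect the teleport floor", {
  set.seed(91)
  for (i in 1:20) {
    g <- random_graph(sample(2:50, 1), runif(1, 0.02, 0.3))
    s <- pagerank(g)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    n <- nrow(g$nodes)
    expect_true(all(s >= (1 - 0.85) / n - 1e-12))
  }
})

test_that("power iteration matches the eigen oracle on random graphs", {
  set.seed(17)
  for (i in 1:40) {
    g <- random_graph(sample(2:50, 1), runif(1, 0.01, 0.4))
    s <- pagerank(g)
    o <- oracle_pagerank_eigen(g)
    expect_lt(max(abs(s - o[names(s)])), 1e-8)
  }
})

test_that("scores agree with igraph's implementation", {
  set.seed(43)
  for (i in 1:5) {
    g <- random_graph(30, 0.1)
    # keep the comparison on a graph with no isolated vertices: dangling
    # conventions differ between implementations
    ig <- as_igraph(g)
    deg <- igraph::degree(ig)
    if (any(deg == 0)) {
      keep <- names(deg[deg > 0])
      g$nodes <- g$nodes[g$nodes$id %in% keep, , drop = FALSE]
    }
    if (nrow(g$nodes) < 2) next
    s <- pagerank(g)
    ref <- igraph::page_rank(as_igraph(g), damping = 0.85,
                             weights = NA)$vector
    expect_equal(s[names(ref)], ref, tolerance = 1e-6)
  }
})

test_that("isolated nodes keep teleport-only mass", {
  g <- two_node_graph()
  g <- add_nodes(g, tibble::tibble(id = "TEXT:ENV", label = "env",
                                   layer = "GENE_PROTEIN",
                                   is_human_gene = FALSE))
  s <- pagerank(g)
  expect_equal(unname(s["TEXT:ENV"]), (1 - 0.85) / 3 +
                 0.85 * sum(s["TEXT:ENV"]) / 3, tolerance = 1e-6)
  expect_lt(s["TEXT:ENV"], min(s[c("HGNC:5001", "HGNC:5002")]))
  expect_equal(sum(s), 1, tolerance = 1e-9)
})

test_that("adding an incident edge never hurts a node's score", {
  set.seed(59)
  for (i in 1:10) {
    g <- random_graph(12, 0.2)
    ids <- g$nodes$id
    existing <- pair_keys <- paste(pmin(g$edges$from, g$edges$to),
                                   pmax(g$edges$from, g$edges$to))
    cand <- t(utils::combn(ids, 2))
    cand <- cand[!(paste(pmin(cand[, 1], cand[, 2]),
                         pmax(cand[, 1], cand[, 2])) %in% existing), ,
                 drop = FALSE]
    if (!nrow(cand)) next
    pick <- cand[sample(nrow(cand), 1), ]
    v <- pick[1]
    g2 <- add_edges(g, tibble::tibble(
      from = pick[1], to = pick[2], directed = FALSE,
      provenance = "INFERRED", weight = 1, evidence_count = 0L
    ))
    expect_gte(oracle_pagerank_eigen(g2)[v] - oracle_pagerank_eigen(g)[v],
               -1e-9)
    expect_gte(pagerank(g2)[v] - pagerank(g)[v], -1e-9)
  }
})

test_that("top_genes filters to the gene layer and breaks ties by id", {
  g <- toy_enriched_graph()
  s <- pagerank(g)
  tk <- top_genes(s, g, k = 3)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$layer == "GENE_PROTEIN"))
  expect_true(all(diff(tk$score) <= 1e-15))
  # forced exact tie: two isolated genes share the teleport floor
  g2 <- new_graph("EG")
  g2 <- add_nodes(g2, gene_nodes(c("B", "A")))
  s2 <- pagerank(g2)
  tk2 <- top_genes(s2, g2, k = 2)
  expect_equal(tk2$node_id, sort(tk2$node_id))
  # k larger than the layer
  expect_equal(nrow(top_genes(s2, g2, k = 10)), 2)
})

test_that("rank_nodes produces dense global and per-layer ranks", {
  g <- toy_enriched_graph()
  r <- rank_nodes(g)
  expect_equal(r$overall_rank, seq_len(nrow(r)))
  gp <- r[r$layer == "GO_PROCESS", ]
  expect_equal(sort(gp$layer_rank), seq_len(nrow(gp)))
})

test_that("non-convergence is reported as an error", {
  g <- star_graph()  # asymmetric, so the iteration cannot land in one step
  expect_error(pagerank(g, pagerank_params(tol = 1e-16, max_iter = 2)),
               "did not converge")
})
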