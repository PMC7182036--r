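#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]: input paths
#' (per-period statement files and the four resource tables) and stage
#' parameter blocks. Can be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param statements Named character vector/list of statement-file paths,
#'   one per period code.
#' @param reference Path to the reference gene-gene association TSV.
#' @param go,goslim,disease Paths to the annotation TSVs.
#' @param endpoints Path to the bioprocess-endpoint mapping TSV.
#' @param out_dir Output directory for per-stage artifacts.
#' @param top_k Length of the per-period top-gene list; default 50.
#' @param alpha,min_overlap Inference parameters (see [infer_edges()]).
#' @param background Inference background size, or `"auto"` (default) for
#'   the number of distinct genes across the loaded annotation tables.
#' @param infer_pairs List of layer pairs to infer over; default
#'   bioprocess-to-disease (GO and GO-slim layers) and disease-to-endpoint.
#' @param pagerank A [pagerank_params()] block.
#' @param min_score Optional disease-annotation score cutoff.
#' @return A list of class `elin_pipeline_config`, validated.
#' @export
pipeline_config <- function(statements, reference, go, goslim, disease,
                            endpoints, out_dir, top_k = 50,
                            alpha = 0.05, min_overlap = 2,
                            background = "auto",
                            infer_pairs = list(
                              c("GO_PROCESS", "DISEASE"),
                              c("GOSLIM_PROCESS", "DISEASE"),
                              c("DISEASE", "IMMUNE_ENDPOINT")
                            ),
                            pagerank = pagerank_params(),
                            min_score = NULL) {
  statements <- as.list(statements)
  if (!all(PERIOD_CODES %in% names(statements))) {
    stop("statements must name one file per period: ",
         paste(PERIOD_CODES, collapse = ", "))
  }
  cfg <- list(statements = statements[PERIOD_CODES], reference = reference,
              go = go, goslim = goslim, disease = disease,
              endpoints = endpoints, out_dir = out_dir, top_k = top_k,
              alpha = alpha, min_overlap = min_overlap,
              background = background, infer_pairs = infer_pairs,
              pagerank = pagerank, min_score = min_score)
  inputs <- c(unlist(cfg$statements), reference, go, goslim, disease,
              endpoints)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(top_k >= 1, alpha > 0, alpha < 1, min_overlap >= 1)
  structure(cfg, class = "elin_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]: a `statements`
#' map (period code to path), the five resource/output paths, and optional
#' `params` blocks (`top_k`, `alpha`, `min_overlap`, `background`,
#' `pagerank: {damping, tol, max_iter}`).
#'
#' @param path YAML file path.
#' @return An `elin_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- do.call(pagerank_params, y$params$pagerank %||% list())
  pipeline_config(
    statements = y$statements, reference = y$reference, go = y$go,
    goslim = y$goslim, disease = y$disease, endpoints = y$endpoints,
    out_dir = y$out_dir,
    top_k = y$params$top_k %||% 50,
    alpha = y$params$alpha %||% 0.05,
    min_overlap = y$params$min_overlap %||% 2,
    background = y$params$background %||% "auto",
    pagerank = pr,
    min_score = y$params$min_score
  )
}

#' Run the full early-life network pipeline
#'
#' Per period: parse statements, assemble the literature network, denoise
#' gene-gene edges against the reference table, enrich with GO / GO-slim /
#' disease / endpoint annotations, infer cross-layer edges, compute
#' PageRank and extract the top-gene list. Across periods: merge the three
#' gestation lists and write the four-set Venn partition with the
#' all-period core. Every stage writes its artifact under
#' `config$out_dir`, and a machine-readable `manifest.json` records
#' parameters, artifact paths and their md5 digests so reruns can be
#' audited for determinism.
#'
#' @param config An `elin_pipeline_config` or path to a YAML file.
#' @return Invisibly, a list with `reports` (denoising), `summaries`
#'   (enrichment), `top` (per-period top-gene tibbles), `venn`, `ranked`
#'   (per-period full rankings) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "elin_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ref <- read_reference_edges(config$reference)
  annots <- list(
    read_annotations(config$go, "GO"),
    read_annotations(config$goslim, "GOSLIM"),
    read_annotations(config$disease, "DISEASE"),
    read_annotations(config$endpoints, "ENDPOINT_MAP")
  )
  background <- if (identical(config$background, "auto")) {
    length(unique(unlist(lapply(annots[1:3], function(a) a$gene))))
  } else {
    as.integer(config$background)
  }

  reports <- list()
  summaries <- list()
  top <- list()
  ranked <- list()
  for (period in PERIOD_CODES) {
    res <- tryCatch(
      run_period(period, config, ref, annots, background),
      error = function(e) {
        stop(sprintf("stage failure in period %s: %s", period,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    reports[[period]] <- res$report
    summaries[[period]] <- res$summary
    top[[period]] <- res$top
    ranked[[period]] <- res$ranked
  }
  confirmation_table(reports, file.path(config$out_dir, "confirmation.tsv"))

  gestation <- combine_gestation(top$EG$node_id, top$MG$node_id,
                                 top$LG$node_id)
  venn <- venn_partition(
    gestation, top$BIRTH$node_id, top$NEWBORN$node_id, top$INFANT$node_id,
    per_period_lists = lapply(top, `[[`, "node_id")
  )
  write_venn(venn, file.path(config$out_dir, "venn.tsv"))

  manifest <- write_manifest(config, background)
  invisible(list(reports = dplyr::bind_rows(reports), summaries = summaries,
                 top = top, venn = venn, ranked = ranked,
                 manifest = manifest))
}

run_period <- function(period, config, ref, annots, background) {
  statements <- parse_statements(config$statements[[period]])
  graph <- assemble_network(statements, period)
  den <- denoise_graph(graph, ref)
  enr <- enrich_graph(den$graph, annots, min_score = config$min_score)
  graph <- enr$graph
  inferred <- list()
  for (pair in config$infer_pairs) {
    res <- infer_edges(graph, pair[1], pair[2], background_n = background,
                       alpha = config$alpha,
                       min_overlap = config$min_overlap)
    graph <- res$graph
    inferred[[paste(pair, collapse = "-")]] <- res$edges
  }
  scores <- pagerank(graph, config$pagerank)
  ranked <- rank_nodes(graph, scores)
  topk <- top_genes(scores, graph, k = config$top_k)

  out <- config$out_dir
  write_network(graph,
                graphml = file.path(out, sprintf("network_%s.graphml", period)),
                nodes_tsv = file.path(out, sprintf("nodes_%s.tsv", period)),
                edges_tsv = file.path(out, sprintf("edges_%s.tsv", period)))
  write_tsv_plain(topk, file.path(out, sprintf("top_genes_%s.tsv", period)))
  inf_flat <- dplyr::bind_rows(lapply(names(inferred), function(nm) {
    e <- inferred[[nm]]
    if (!nrow(e)) return(NULL)
    tibble::tibble(layer_pair = nm, a_id = e$a_id, b_id = e$b_id, k = e$k,
                   jaccard = e$jaccard, p = e$p_value, q = e$q_value)
  }))
  if (!nrow(inf_flat)) {
    inf_flat <- tibble::tibble(layer_pair = character(), a_id = character(),
                               b_id = character(), k = integer(),
                               jaccard = double(), p = double(), q = double())
  }
  write_tsv_plain(inf_flat, file.path(out, sprintf("inferred_%s.tsv", period)))
  list(report = den$report, summary = enr$summary, top = topk,
       ranked = ranked, graph = graph)
}

write_manifest <- function(config, background) {
  out <- config$out_dir
  artifacts <- list.files(out, pattern = "\\.(tsv|graphml)$",
                          full.names = TRUE)
  digests <- tools::md5sum(sort(artifacts))
  manifest <- list(
    package_version = as.character(utils::packageVersion("elin")),
    periods = PERIOD_CODES,
    parameters = list(
      top_k = config$top_k, alpha = config$alpha,
      min_overlap = config$min_overlap, background = background,
      damping = config$pagerank$damping, tol = config$pagerank$tol,
      max_iter = config$pagerank$max_iter
    ),
    inputs = lapply(c(config$statements,
                      list(reference = config$reference, go = config$go,
                           goslim = config$goslim, disease = config$disease,
                           endpoints = config$endpoints)),
                    function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = mapply(function(p, d) list(path = p, md5 = unname(d)),
                       names(digests), digests, SIMPLIFY = FALSE,
                       USE.NAMES = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
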