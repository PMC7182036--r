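NONHUMAN_POOL <- c("lacZ", "env", "rpoD", "dop", "cscK", "ptc", "lanA1",
                   "AtJ1", "lectin")

#' Synthetic-bundle configuration
#'
#' Parameters of the synthetic input generator. Defaults emulate one
#' desk-scale study condition: a 300-gene universe with 10 planted hub
#' genes whose appearance probability in statements and annotations is
#' multiplied by `hub_degree_multiplier`; 500 statements per period of
#' which `noise_edge_fraction` of the gene-gene pairs are random noise
#' absent from the reference table; and a reference table covering
#' `reference_coverage` of the generated gene-gene pairs, mirroring the
#' ~27-32% confirmation rates seen when literature networks are screened
#' against a human association database.
#'
#' @param n_genes Size of the human gene universe.
#' @param n_hubs Number of planted hub genes.
#' @param n_processes Number of GO process terms.
#' @param n_diseases Number of disease terms.
#' @param statements_per_period Statements written per period file.
#' @param hub_degree_multiplier Sampling-weight multiplier for hub genes.
#' @param reference_coverage Fraction of generated gene-gene pairs present
#'   in the reference table.
#' @param noise_edge_fraction Fraction of gene-gene statement pairs drawn
#'   at random (never copied into the reference table).
#' @param n_nonhuman Number of non-human contaminant gene entities
#'   (ungrounded, e.g. lacZ, env) appearing in statements.
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   configuration.
#' @return A validated list of class `elin_synth_config`.
#' @export
synth_config <- function(n_genes = 300, n_hubs = 10, n_processes = 60,
                         n_diseases = 40, statements_per_period = 500,
                         hub_degree_multiplier = 8,
                         reference_coverage = 0.3,
                         noise_edge_fraction = 0.3,
                         n_nonhuman = 5, seed = 42) {
  cfg <- list(n_genes = n_genes, n_hubs = n_hubs, n_processes = n_processes,
              n_diseases = n_diseases,
              statements_per_period = statements_per_period,
              hub_degree_multiplier = hub_degree_multiplier,
              reference_coverage = reference_coverage,
              noise_edge_fraction = noise_edge_fraction,
              n_nonhuman = n_nonhuman, seed = as.integer(seed))
  counts <- cfg[c("n_genes", "n_hubs", "n_processes", "n_diseases",
                  "statements_per_period", "hub_degree_multiplier")]
  if (any(vapply(counts, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all synthetic counts must be positive")
  }
  if (reference_coverage < 0 || reference_coverage > 1 ||
      noise_edge_fraction < 0 || noise_edge_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (noise_edge_fraction < 1 &&
      reference_coverage / (1 - noise_edge_fraction) > 1) {
    stop("reference_coverage cannot exceed the non-noise pair fraction")
  }
  if (n_hubs > n_genes) stop("n_hubs cannot exceed n_genes")
  if (n_nonhuman < 0) stop("n_nonhuman must be >= 0")
  structure(cfg, class = "elin_synth_config")
}

#' Generate a complete synthetic input bundle
#'
#' Writes six period statement files, a reference gene-gene association
#' table, GO / GO-slim / disease annotation tables, a bioprocess-endpoint
#' mapping, and a `ground_truth.json` with the generator's bookkeeping
#' (planted hubs, per-period distinct gene-gene pairs and their expected
#' reference confirmation), all deterministic in `config$seed`.
#'
#' Mechanics: gene-gene statements are drawn from a fixed backbone of
#' hub-weighted "true" pairs, except a `noise_edge_fraction` share drawn
#' uniformly at random; the reference table contains each backbone pair
#' with probability `reference_coverage / (1 - noise_edge_fraction)` plus
#' distractor pairs never seen in statements, so the confirmed share of a
#' period's gene-gene edges is approximately `reference_coverage`.
#' Non-human contaminants enter statements ungrounded and are never
#' annotated or referenced.
#'
#' @param config An [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`
#'   (the ground-truth list, identical to the JSON on disk).
#' @export
generate_bundle <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "elin_synth_config"))
  if (missing(out_dir)) stop("out_dir is required")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- sprintf("ELG%03d", seq_len(config$n_genes))
  hgnc <- setNames(as.character(20000 + seq_len(config$n_genes)), genes)
  hubs <- sort(sample(genes, config$n_hubs))
  w <- setNames(rep(1, config$n_genes), genes)
  w[hubs] <- config$hub_degree_multiplier
  nonhuman <- rep_len(NONHUMAN_POOL, config$n_nonhuman)
  if (config$n_nonhuman > length(NONHUMAN_POOL)) {
    nonhuman <- make.unique(nonhuman, sep = "")
  }

  # hub-weighted backbone of "true" gene-gene pairs
  n_backbone <- max(50L, round(1.2 * config$statements_per_period))
  backbone <- draw_pairs(genes, w, n_backbone)
  q_ref <- if (config$noise_edge_fraction < 1) {
    min(1, config$reference_coverage / (1 - config$noise_edge_fraction))
  } else 0
  in_ref <- runif(nrow(backbone)) < q_ref
  ref_pairs <- backbone[in_ref, , drop = FALSE]

  # distractor reference rows: pairs never emitted in statements
  n_extra <- round(0.4 * nrow(backbone))
  extra <- draw_pairs(genes, setNames(rep(1, length(genes)), genes),
                      nrow(backbone) + n_extra)
  extra <- extra[!(pair_key(extra$a, extra$b) %in%
                     pair_key(backbone$a, backbone$b)), , drop = FALSE]
  extra <- head(extra, n_extra)
  ref_tab <- rbind(ref_pairs, extra)
  net_types <- c("co-expression", "physical", "pathway",
                 "co-localization", "domain")
  reference <- tibble::tibble(
    gene_a = ref_tab$a, gene_b = ref_tab$b,
    network_type = sample(net_types, nrow(ref_tab), replace = TRUE),
    weight = round(runif(nrow(ref_tab), 0.05, 1), 4)
  )

  # companion entity pools for the other layers
  bioproc <- sprintf("synthetic immune process %02d", seq_len(25))
  chems <- tibble::tibble(name = sprintf("chem%02d", seq_len(30)),
                          id = sprintf("CHEBI:%05d", 90000 + seq_len(30)))
  fams <- tibble::tibble(name = sprintf("FAM_%02d", seq_len(15)),
                         id = sprintf("FPLX:SYN%02d", seq_len(15)))
  mesh_dis <- tibble::tibble(name = sprintf("statement disease %02d",
                                            seq_len(20)),
                             id = sprintf("D05%04d", seq_len(20)))

  ref_keys <- pair_key(reference$gene_a, reference$gene_b)
  backbone_keys <- pair_key(backbone$a, backbone$b)
  forbidden <- unique(c(ref_keys, backbone_keys))

  truth_periods <- list()
  stmt_paths <- character()
  for (period in PERIOD_CODES) {
    per <- generate_period_statements(
      period, config, genes, hgnc, w, backbone, forbidden, nonhuman,
      bioproc, chems, fams, mesh_dis
    )
    path <- file.path(out_dir, sprintf("statements_%s.json", period))
    jsonlite::write_json(per$records, path, auto_unbox = TRUE, digits = NA)
    stmt_paths[period] <- path
    gg_keys <- unique(per$gg_keys)
    human_keys <- unique(per$gg_keys[per$gg_human])
    truth_periods[[period]] <- list(
      n_statements = length(per$records),
      n_gene_gene_statements = per$n_gg,
      n_distinct_gene_pairs = length(gg_keys),
      n_expected_confirmed = sum(human_keys %in% ref_keys),
      expected_pct_confirmed = pct_round(sum(human_keys %in% ref_keys),
                                         length(gg_keys))
    )
  }

  annotations <- generate_annotations(config, genes, w, mesh_dis)
  paths <- c(
    stmt_paths,
    reference = file.path(out_dir, "reference_edges.tsv"),
    go = file.path(out_dir, "go_annotations.tsv"),
    goslim = file.path(out_dir, "goslim_annotations.tsv"),
    disease = file.path(out_dir, "disease_associations.tsv"),
    endpoints = file.path(out_dir, "endpoint_map.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_tsv_plain(reference, paths[["reference"]])
  write_tsv_plain(annotations$go, paths[["go"]])
  write_tsv_plain(annotations$goslim, paths[["goslim"]])
  write_tsv_plain(annotations$disease, paths[["disease"]])
  write_tsv_plain(annotations$endpoints, paths[["endpoints"]])

  truth <- list(
    seed = config$seed,
    hub_genes = hubs,
    hub_node_ids = unname(paste0("HGNC:", hgnc[hubs])),
    n_genes = config$n_genes,
    nonhuman_genes = nonhuman,
    n_reference_rows = nrow(reference),
    n_annotation_genes = length(unique(c(annotations$go$gene,
                                         annotations$goslim$gene,
                                         annotations$disease$gene))),
    periods = truth_periods
  )
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = as.list(paths), truth = truth))
}

# weighted endpoint sampling of n distinct unordered gene pairs
draw_pairs <- function(genes, w, n) {
  seen <- character()
  out_a <- character(n)
  out_b <- character(n)
  got <- 0L
  while (got < n) {
    take <- (n - got) * 2L + 10L
    a <- sample(genes, take, replace = TRUE, prob = w)
    b <- sample(genes, take, replace = TRUE, prob = w)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    key <- pair_key(a, b)
    fresh <- !duplicated(key) & !(key %in% seen)
    a <- a[fresh]; b <- b[fresh]; key <- key[fresh]
    m <- min(length(a), n - got)
    if (m > 0) {
      idx <- seq_len(m)
      out_a[got + idx] <- pmin(a[idx], b[idx])
      out_b[got + idx] <- pmax(a[idx], b[idx])
      seen <- c(seen, key[idx])
      got <- got + m
    }
  }
  tibble::tibble(a = out_a, b = out_b)
}

generate_period_statements <- function(period, config, genes, hgnc, w,
                                       backbone, forbidden, nonhuman,
                                       bioproc, chems, fams, mesh_dis) {
  spp <- config$statements_per_period
  n_nonhuman_stmts <- if (config$n_nonhuman > 0) {
    max(config$n_nonhuman, round(0.015 * spp))
  } else 0L
  n_gg <- max(0L, round(0.68 * spp))
  n_noise <- round(config$noise_edge_fraction * n_gg)
  n_true <- n_gg - n_noise
  n_gp <- round(0.10 * spp)
  n_gc <- round(0.08 * spp)
  n_gf <- round(0.05 * spp)
  n_gd <- max(0L, spp - n_gg - n_gp - n_gc - n_gf - n_nonhuman_stmts)

  gene_ent <- function(sym) {
    list(name = sym, db_refs = list(HGNC = unname(hgnc[sym])))
  }
  gg_types <- c("Activation", "Inhibition", "Complex", "Association",
                "IncreaseAmount", "DecreaseAmount")
  records <- list()
  gg_keys <- character()
  gg_human <- logical()
  emit <- function(subj, obj, type) {
    records[[length(records) + 1L]] <<- list(
      type = type, subj = subj, obj = obj,
      evidence_count = sample(1:3, 1, prob = c(0.7, 0.2, 0.1)),
      pmids = list(sprintf("PMID%07d", sample.int(9999999, 1))),
      period = period
    )
  }

  if (n_true > 0) {
    # distinct backbone pairs per period, so the confirmed share of this
    # period's gene-gene edges tracks reference_coverage
    rows <- backbone[sample.int(nrow(backbone), min(n_true, nrow(backbone))), ]
    n_true <- nrow(rows)
    for (i in seq_len(n_true)) {
      emit(gene_ent(rows$a[i]), gene_ent(rows$b[i]),
           sample(gg_types, 1, prob = c(0.3, 0.15, 0.2, 0.25, 0.05, 0.05)))
      gg_keys <- c(gg_keys, pair_key(rows$a[i], rows$b[i]))
      gg_human <- c(gg_human, TRUE)
    }
  }
  made <- 0L
  period_noise <- character()
  while (made < n_noise) {
    a <- sample(genes, 1)
    b <- sample(genes, 1)
    if (a == b) next
    key <- pair_key(a, b)
    # noise pairs are never reference-backed, and distinct within a period
    if (key %in% forbidden || key %in% period_noise) next
    period_noise <- c(period_noise, key)
    emit(gene_ent(a), gene_ent(b), sample(gg_types, 1))
    gg_keys <- c(gg_keys, key)
    gg_human <- c(gg_human, TRUE)
    made <- made + 1L
  }
  for (i in seq_len(n_nonhuman_stmts)) {
    nh <- sample(nonhuman, 1)
    g <- sample(genes, 1, prob = w)
    emit(list(name = nh, db_refs = list(), kind = "gene"), gene_ent(g),
         sample(c("Activation", "Association"), 1))
    gg_keys <- c(gg_keys, pair_key(paste0("NH_", toupper(nh)), g))
    gg_human <- c(gg_human, FALSE)
  }
  for (i in seq_len(n_gp)) {
    emit(gene_ent(sample(genes, 1, prob = w)),
         list(name = sample(bioproc, 1), db_refs = list(),
              kind = "bioprocess"),
         "Activation")
  }
  for (i in seq_len(n_gc)) {
    j <- sample.int(nrow(chems), 1)
    emit(list(name = chems$name[j], db_refs = list(CHEBI = chems$id[j])),
         gene_ent(sample(genes, 1, prob = w)), "IncreaseAmount")
  }
  for (i in seq_len(n_gf)) {
    j <- sample.int(nrow(fams), 1)
    emit(gene_ent(sample(genes, 1, prob = w)),
         list(name = fams$name[j], db_refs = list(FPLX = fams$id[j])),
         "Complex")
  }
  for (i in seq_len(n_gd)) {
    j <- sample.int(nrow(mesh_dis), 1)
    emit(gene_ent(sample(genes, 1, prob = w)),
         list(name = mesh_dis$name[j], db_refs = list(MESH = mesh_dis$id[j])),
         "Association")
  }
  list(records = records, gg_keys = gg_keys, gg_human = gg_human,
       n_gg = n_gg + n_nonhuman_stmts)
}

generate_annotations <- function(config, genes, w, mesh_dis) {
  mult <- config$hub_degree_multiplier
  bern_rows <- function(terms, p_base) {
    p <- pmin(0.9, p_base * ifelse(w[genes] > 1, mult, 1))
    hits <- which(matrix(runif(length(genes) * length(terms)),
                         nrow = length(genes)) < p)
    gi <- ((hits - 1) %% length(genes)) + 1
    ti <- ((hits - 1) %/% length(genes)) + 1
    ord <- order(gi, ti)
    list(gene = genes[gi][ord], term = ti[ord])
  }
  go_terms <- tibble::tibble(
    id = sprintf("GO:07%05d", seq_len(config$n_processes)),
    name = sprintf("synthetic process %03d", seq_len(config$n_processes))
  )
  hit <- bern_rows(go_terms$id, 0.035)
  go <- tibble::tibble(gene = hit$gene, term_id = go_terms$id[hit$term],
                       term_name = go_terms$name[hit$term])
  slim_terms <- tibble::tibble(
    id = sprintf("GO:0081%03d", seq_len(15)),
    name = sprintf("synthetic slim process %02d", seq_len(15))
  )
  hit <- bern_rows(slim_terms$id, 0.08)
  goslim <- tibble::tibble(gene = hit$gene, term_id = slim_terms$id[hit$term],
                           term_name = slim_terms$name[hit$term])
  dis_terms <- tibble::tibble(
    id = sprintf("C10%05d", seq_len(config$n_diseases)),
    name = sprintf("synthetic disease %03d", seq_len(config$n_diseases))
  )
  hit <- bern_rows(dis_terms$id, 0.03)
  disease <- tibble::tibble(gene = hit$gene, term_id = dis_terms$id[hit$term],
                            term_name = dis_terms$name[hit$term])
  mapped_go <- sample(go_terms$id, max(1, round(0.3 * nrow(go_terms))))
  mapped_slim <- sample(slim_terms$id, max(1, round(0.5 * nrow(slim_terms))))
  endpoints <- tibble::tibble(
    term_id = c(mapped_go, mapped_slim),
    endpoint = sample(IMMUNE_ENDPOINTS, length(mapped_go) + length(mapped_slim),
                      replace = TRUE)
  )
  list(go = go, goslim = goslim, disease = disease, endpoints = endpoints)
}
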