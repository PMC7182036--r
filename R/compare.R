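#' Merge the three gestation top-gene lists
#'
#' The early, mid and late gestation top-50 lists are combined into one
#' de-duplicated gestation gene set for the four-way cross-period
#' comparison.
#'
#' @param eg,mg,lg Character vectors of gene ids (top-list order ignored).
#' @return Sorted character vector of the union.
#' @export
combine_gestation <- function(eg, mg, lg) {
  stopifnot(length(eg) > 0, length(mg) > 0, length(lg) > 0)
  sort(unique(c(eg, mg, lg)))
}

VENN_SETS <- c("GESTATION", "BIRTH", "NEWBORN", "INFANT")

#' Four-set Venn partition of top-gene lists
#'
#' Assigns every gene in the union of the four sets (gestation = merged
#' EG/MG/LG, birth, newborn, infant) to exactly one of the 15 regions
#' given by its membership signature; region labels are the member sets
#' joined with `+` in the fixed order GESTATION, BIRTH, NEWBORN, INFANT.
#' The all-period core is computed separately as the intersection of the
#' six un-merged per-period lists, so a core gene must be top-ranked in
#' every single gestational trimester, not merely somewhere in gestation.
#'
#' @param gestation,birth,newborn,infant Character vectors of gene ids.
#' @param per_period_lists Optional named list of the six un-merged lists
#'   (`EG`, `MG`, `LG`, `BIRTH`, `NEWBORN`, `INFANT`) used for the core;
#'   when `NULL` the core is the intersection of the four inputs.
#' @return A list of class `elin_venn` with `regions` (named list of gene
#'   vectors, one per non-empty signature), `sizes` (named integer vector
#'   over all 15 regions) and `core_all_periods`.
#' @export
venn_partition <- function(gestation, birth, newborn, infant,
                           per_period_lists = NULL) {
  sets <- list(GESTATION = unique(gestation), BIRTH = unique(birth),
               NEWBORN = unique(newborn), INFANT = unique(infant))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  signature <- apply(membership, 1, function(m) {
    paste(VENN_SETS[m], collapse = "+")
  })
  all_labels <- unlist(lapply(seq_along(VENN_SETS), function(sz) {
    combn(VENN_SETS, sz, paste, collapse = "+")
  }))
  regions <- split(universe, factor(signature, levels = all_labels))
  sizes <- vapply(regions, length, integer(1))

  core <- if (is.null(per_period_lists)) {
    Reduce(intersect, sets)
  } else {
    stopifnot(all(PERIOD_CODES %in% names(per_period_lists)))
    Reduce(intersect, lapply(per_period_lists[PERIOD_CODES], unique))
  }
  structure(
    list(regions = regions[sizes > 0], sizes = sizes,
         core_all_periods = sort(core)),
    class = "elin_venn"
  )
}

#' @export
print.elin_venn <- function(x, ...) {
  cat("<elin_venn> 4-set partition of", sum(x$sizes), "genes;",
      length(x$core_all_periods), "core genes across all periods\n")
  nz <- x$sizes[x$sizes > 0]
  for (i in seq_along(nz)) {
    cat(sprintf("  %-32s %d\n", names(nz)[i], nz[i]))
  }
  invisible(x)
}

#' Write a Venn partition as TSV
#'
#' One row per region (all 15, empty included) with the gene ids
#' semicolon-joined, plus a final `CORE_ALL_PERIODS` row.
#'
#' @param venn An `elin_venn`.
#' @param path Output TSV path.
#' @return The table, invisibly.
#' @export
write_venn <- function(venn, path) {
  stopifnot(inherits(venn, "elin_venn"))
  genes <- vapply(names(venn$sizes), function(lbl) {
    paste(venn$regions[[lbl]] %||% character(), collapse = ";")
  }, character(1))
  out <- tibble::tibble(
    region = c(names(venn$sizes), "CORE_ALL_PERIODS"),
    n_genes = c(unname(venn$sizes), length(venn$core_all_periods)),
    genes = c(unname(genes), paste(venn$core_all_periods, collapse = ";"))
  )
  write_tsv_plain(out, path)
  invisible(out)
}
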