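---
title: "Assembling and prioritizing early-life immune networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and prioritizing early-life immune networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elin)
```

## The problem

The molecular drivers of immune development differ between early-life
periods: what matters in the first trimester of gestation is not what
matters in a newborn. The literature describing those drivers is scattered
across thousands of papers, each focused on a narrow topic, so no single
source gives a period-resolved picture. `elin` implements a network
workflow over that literature: text-mined causal statements are assembled
into one heterogeneous network per period — three gestational trimesters
(`EG`, `MG`, `LG`), `BIRTH`, `NEWBORN` (0–28 days) and `INFANT`
(1–23 months) — cleaned against a reference human interactome, enriched
from annotation databases, completed by statistical edge inference, and
finally ranked with PageRank to nominate the period's key immune marker
genes.

The package starts at the *statement* level: it consumes the output format
of a text-mining/assembly system (typed causal relationships between
grounded entities, with evidence counts), not PDFs, and all database
lookups are file-based tables, so every run is offline and reproducible.

## The multilayer model

Nodes are typed into eight layers: genes/proteins (one node per name —
literature rarely distinguishes a gene from its product, so neither do
we), protein families, chemicals, text-mined bioprocesses, GO processes,
GO-slim processes, diseases, and four fixed immune health endpoints
(autoimmunity, hypersensitivity, resistance to neoplasms, resistance to
infections). The layer of an entity is a pure function of its groundings:
HGNC → gene, FPLX → family, CHEBI → chemical, GO/GO-slim → process,
MESH/DOID/UMLS → disease. The canonical node id is taken from the
highest-precedence grounding (HGNC first); ungrounded names fall back to
an uppercased `TEXT:` id so case variants of the same surface form merge.
The precedence order is a package choice — the statement format does not
say how to resolve conflicting groundings — and HGNC-first reflects that a
human gene id is the most specific claim an extractor can make.

Ungrounded gene-like symbols (for example viral `env` or bacterial `lacZ`)
stay in the network as gene nodes flagged `is_human_gene = FALSE`. This
matters downstream: their gene–gene edges can never be confirmed against a
human reference and are always removed, but the nodes themselves persist
and can be re-connected by annotation edges.

GO-slim terms are canonicalized in their own `GOSLIM:` namespace even when
their identifiers look like plain GO ids. The slim vocabulary plays a
different structural role (a small parent layer above the full GO layer),
and keeping the two node sets disjoint preserves per-layer node counts.

## Pipeline stages

**Assembly** (`parse_statements()`, `assemble_network()`). Statements
collapsing onto the same unordered node pair merge into one literature
edge whose evidence count is the *sum* of the merged statements (summing,
rather than taking the maximum, preserves the total literature support for
reporting). A merged edge stays directed only if every contributing
statement is directional and they agree; any mixture collapses to an
undirected association, and all downstream analysis treats the network as
an association network. Self-statements ("TNF activates TNF") are dropped
and counted; a file in which more than half the records are invalid is
rejected outright.

**Denoising** (`denoise_graph()`). Every literature gene–gene edge is kept
only if its unordered symbol pair occurs anywhere in the reference human
association table; retained edges are re-tagged `REFERENCE_CONFIRMED`,
the rest are deleted — *but no node is ever removed*. The match is pure
membership: reference network type and weight are ignored, because the
screen is a presence/absence plausibility filter, not a re-weighting. The
confirmation report rounds percentages half-up to integers, matching how
such tables are conventionally printed.

**Enrichment** (`enrich_graph()`). Annotation tables are *joined*, not
tested: each (gene, term) row whose gene is already in the period network
contributes the term node and an undirected edge of weight 1. Genes absent
from the period literature contribute nothing — only genes observed in
that period are annotated, which is what makes the six networks
period-specific. Statistical testing is deliberately deferred to the
inference stage. Endpoint mapping runs last and only attaches endpoints to
terms that actually made it into the network, so an endpoint is never
reachable except through gene-supported terms. An optional `min_score`
cutoff can be applied to disease tables that carry association scores;
the default applies none.

**Inference** (`infer_edges()`). Cross-layer edges (bioprocess → disease,
disease → endpoint) are created from the genes the two nodes share. For
profiles of sizes $K$ and $n$ sharing $k$ genes out of a background of $N$,
the p-value is the hypergeometric upper tail
$P(X \ge k) = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$,
Benjamini–Hochberg adjusted across all candidate pairs of the layer pair;
pairs with $q \le \alpha$ become undirected edges weighted by the Jaccard
similarity $k/|A \cup B|$. Defaults: $\alpha = 0.05$, minimum overlap 2,
and background $N$ = the number of distinct genes across the loaded
annotation tables (the universe the annotations could have drawn from).
These are configuration choices, not a reconstruction: "number and
similarity of shared genes" pins the sufficient statistics (overlap count
and Jaccard) but not the test, and BH is the standard control when the
candidate-pair count is large. An endpoint node's gene profile is the
union of the profiles of the terms mapped onto it.

**Prioritization** (`pagerank()`, `top_genes()`). PageRank is computed by
power iteration over the *symmetrized, unweighted* adjacency with uniform
teleportation: important genes are those receiving associations from other
important genes/bioprocesses/diseases, over the full topology rather than
a local neighborhood. Unweighted, because edge strengths are heterogeneous
provenances (evidence counts, unit annotation weights, Jaccard values)
that are not commensurable; a `use_weights` switch exists for sensitivity
analysis. Undirected, because the final product is an association network.
Damping is the classical 0.85. Nodes are ranked globally and the gene
layer is then filtered out to form the per-period top-50 list, so a gene's
rank reflects competition with every node type. Dangling (isolated) nodes
redistribute their mass uniformly, giving every node the teleport floor
$(1-d)/N$ — disconnected non-human genes rank low but are never lost,
and can rise if enrichment reconnects them.

**Comparison** (`combine_gestation()`, `venn_partition()`). The three
gestation top-50 lists are merged by union, and each gene in the union of
{gestation, birth, newborn, infant} is assigned to exactly one of the 15
membership regions. The all-period core is computed from the six
*un-merged* lists: a core gene must be top-ranked in every single
trimester, not merely somewhere in gestation.

## Numerical choices

- PageRank convergence is declared when the L1 change falls below `tol`
  (default `1e-10`, cap 1000 iterations; non-convergence is an error, not
  a silent result). At damping 0.85 this leaves the score vector within
  about `tol · d/(1-d)` of the fixed point, comfortably inside the 1e-8
  agreement the test suite demands against a dense eigen-decomposition
  oracle on graphs up to 50 nodes.
- Ties in rankings are broken lexicographically by node id, making every
  ranked artifact byte-reproducible.
- Percent rounding in confirmation reports is half-up (`floor(x + 0.5)`);
  0/0 reports 0.
- Parallel edges between the same pair (different provenances) are
  binarized before PageRank so a pair of nodes never counts twice in the
  unweighted walk.
- `hyper_tail()` delegates to `stats::phyper`; the exhaustive-enumeration
  cross-check in the test suite covers every configuration with background
  ≤ 12 at 1e-12.

## The synthetic study condition

No public statement corpus exists for this workflow, so the package ships
a generator (`synth_config()`, `generate_bundle()`) that emulates all five
inputs with planted ground truth. The default configuration is the study
condition used throughout the tests: 300 human genes, 10 hub genes whose
probability of appearing in statements and annotations is multiplied by 8,
500 statements per period (68% gene–gene, the rest spread over
gene–bioprocess, gene–chemical, gene–family and gene–disease statements
plus a few ungrounded non-human contaminants drawn from names like `lacZ`
and `env`), 60 GO terms, 15 GO-slim terms, 40 diseases, and a curated-style
term→endpoint mapping covering a subset of process terms.

Gene–gene statements are drawn from a fixed hub-weighted backbone of
"true" pairs, except a `noise_edge_fraction` (default 0.3) of uniformly
random pairs. The reference table contains each backbone pair with
probability `reference_coverage / (1 − noise_edge_fraction)` plus
distractor pairs never emitted in statements, so the confirmed share of a
period's gene–gene edges tracks `reference_coverage` (default 0.3,
mirroring the ~27–32% confirmation range reported when literature networks
are screened against a human association database). Per-period true pairs
are drawn *without* replacement: sampling with replacement collapses
duplicates at assembly and silently shrinks the confirmed share below the
design value. Noise and non-human pairs are never reference-backed.

Hubs are planted by degree multiplication rather than block structure
because the prioritization claim being tested is exactly "more
associations from more important neighbors"; recovery of all 10 hubs in
each period's top-50 is the headline end-to-end check. The generator also
writes `ground_truth.json` with its own bookkeeping (distinct pairs,
expected confirmation counts), and the suite re-parses the written files
to verify the bookkeeping matches — the generator audits itself.

What the generator does **not** emulate: real grounding ambiguity (each
synthetic symbol grounds cleanly), correlated annotation structure (terms
are drawn independently per gene, so there is no ontology-like nesting),
citation bias, or the long-tailed degree distributions of real literature
networks. Passing tests therefore demonstrate that the machinery is
correct and that degree/annotation signal is recovered — not that any
particular biological list is right.

The null-calibration check for the overlap test uses independently drawn
profiles spanning 25–35% of a 10,000-gene background. The sizes are chosen
so the discrete hypergeometric tail has fine support: with small profiles
the test is *conservative* (the p ≤ 0.05 mass falls detectably short of
0.05 purely by discreteness), which is a property of the statistic, not a
bug, and would defeat a calibration check designed for a near-uniform
null.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the default 300-gene bundle for end-to-end checks, 80–150-gene bundles for
stage tests, 200 random graphs of ≤ 50 nodes for the PageRank oracle, and
4,000 candidate pairs for the null calibration. These sizes were chosen as
the smallest at which each property is cleanly expressed.

## Limitations

- Layer assignment of ungrounded entities uses a token heuristic (short
  single tokens look like genes); a real corpus would carry extractor
  hints, which the statement dialect supports via an optional `kind`
  field.
- Enrichment is a join, so the networks inherit whatever biases the
  annotation tables carry; no ontology propagation is performed — terms
  are flat labels.
- The inference background defaults to the annotation-table gene universe;
  if the supplied tables cover only a small gene panel, the hypergeometric
  test will be anti-conservative and `background` should be set explicitly.
- PageRank parameters are not period-specific; damping 0.85 is a
  convention, and rank lists should be read as robust orderings, not
  calibrated scores.
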