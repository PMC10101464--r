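---
title: "Methods: cataloging prophages with gene-sharing networks, clustering and host-range reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cataloging prophages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagenet)
```

This vignette documents the models and procedures behind `prophagenet`,
the assumptions they make, the parameters that matter, and the design
choices taken where more than one reasonable convention exists.

## The analysis problem

Given a collection of predicted prophage sequences — each with a source
genome, a nucleotide sequence and gene annotations — the package answers
four questions: which genes are homologs of one another (gene families);
how are the prophages related through shared gene content (the
gene-sharing network); which prophages are the "same phage" at the species
level (sequence clusters); and what do similarity screens and spot-assay
data say about taxonomy, cargo genes and host range.

## Gene families: alignment scores, minbit, MCL

Homologous genes are found by all-vs-all pairwise alignment of the
nucleotide gene sequences. `pair_score()` computes a Smith–Waterman local
alignment score with match +5, mismatch −4 and affine gaps (a gap of
length $L$ costs $8 + 2L$), so the self-score of a length-$L$ gene is
$5L$ and the score floor is 0. Each pairwise score is normalized by the
smaller of the two self-scores:

$$\mathrm{minbit}(a,b) = \frac{\mathrm{score}(a,b)}
{\min(\mathrm{score}(a,a),\ \mathrm{score}(b,b))} \in [0,1],$$

and edges with minbit < 0.35 are discarded. This normalized similarity is
robust to length differences and puts a dimensionless threshold on what
counts as candidate homology. An exact all-vs-all scan is quadratic, so a
shared-word prescreen (one common 8-mer required) skips hopeless pairs; at
the divergence levels where minbit ≥ 0.35 could hold, homologous pairs
always share 8-mers, so the prescreen cannot lose true edges.

The retained similarity graph is clustered with a from-scratch **Markov
Clustering** implementation (`mcl_cluster()`). The column-stochastic
transition matrix (self-loops set to each node's maximum incident weight)
is alternately *expanded* (squared) and *inflated* (elementwise power
2, then renormalized), pruning entries below $10^{-5}$, until the maximum
absolute change falls below $10^{-6}$ or 100 iterations. Inflation 2 is
the package default, a standard mid-granularity setting. Clusters are
read off the attractor rows' supports; a node claimed by several
attractors goes to the one holding the largest mass, ties to the lowest
index, so the output is a deterministic partition. Because expansion
cannot move mass between disconnected components, clusters never span
graph components. Genes left without any retained edge become singleton
clusters — the clustering is total over the input, and singletons simply
occupy their own presence/absence column downstream.

Two conventions here were genuinely open. First, pan-genome pipelines
often score translated (amino-acid) sequences; this package scores
nucleotide sequences directly, keeping the stack self-contained while
preserving the minbit semantics. Second, the treatment of unclustered
genes as singletons (rather than discarding them) was chosen so that the
presence/absence matrix retains every gene.

## The gene-sharing network

Gene-cluster membership is summarized in the binary presence/absence
matrix $P$: $P_{ij}=1$ iff genome $i$ carries at least one gene of
cluster $j$ (multiplicity collapses to 1; all-zero columns are dropped).
$P$ is the adjacency matrix of the bipartite genome–gene network, and

$$A_\mathrm{genome} = \mathrm{sign}(P P^T), \qquad
  A_\mathrm{gene} = \mathrm{sign}(P^T P)$$

are the genome- and gene-level projections: two genomes are connected iff
they share any gene cluster, and $S = P P^T$ counts shared clusters.
Edges are weighted

$$w = \frac{s}{l_1 \, l_2},$$

where $l_i$ is the *size* of genome $i$. The package defines $l_i$ as the
number of distinct gene clusters in genome $i$ (the row sum of $P$), not
its bp length: this keeps $w$ dimensionless and implies the bound
$w \le 1/\max(l_1, l_2)$ since $s \le \min(l_1, l_2)$.

Edge filtering supports two rules, because two natural phrasings of
"sharing enough genes" are not equivalent:

* the default weight rule retains an edge iff $w > minw$ (strict
  inequality), and
* a fraction rule retains an edge iff $s/\min(l_1,l_2) \ge f$ (inclusive;
  default $f = 0.30$), i.e. the pair shares at least that fraction of the
  smaller genome's genic content.

Both are exposed in `filter_edges()` / `build_network()` rather than
guessing a single interpretation. Connected components are labeled via
igraph and canonicalized by each component's smallest member id, making
labels invariant to edge-list order. Edge lists export as TSV and SIF for
Cytoscape; no layout or community detection beyond components is
attempted.

## Species-level sequence clustering

`greedy_cluster()` collapses near-identical prophages in the style of
greedy incremental est-clustering: sort sequences by length descending
(ties by id), scan in order, and join the first existing cluster whose
representative passes (a) length ratio shorter/longer ≥ 0.8, (b) at least
one shared 4-mer, and (c) identity ≥ 0.8; otherwise found a new cluster.
Representatives are therefore always the longest members, any two
representatives fail at least one join criterion, and the canonical sort
makes output independent of input order.

Identity is defined as *matches divided by the length of the shorter
sequence*, computed by aligning the shorter sequence globally against the
best-matching region of the longer (glocal alignment, match +2,
mismatch −3, gap open 5, gap extend 2). The identity denominator is a
real choice — alignment-length and longer-sequence denominators exist in
the wild — and the shorter-sequence convention was picked as the common
est-clustering semantics; it is documented rather than asserted as
universal. "Length-difference cutoff 0.8" is likewise interpreted as
shorter/longer ≥ 0.8, its standard meaning. The `cluster_config()`
`band_width` field is retained for interface stability, but alignments
run unbanded: at the sequence lengths the package targets the C-level
full dynamic programming in Biostrings is fast enough that a banded
heuristic would add risk without measurable benefit.

Output mirrors `.clstr` conventions (`write_clstr()` / `read_clstr()`),
with member identities printed to two decimals and representatives marked
`*`; `cluster_summary()` reports cluster counts, singleton fraction,
largest size and a representative-length table for size–length
association checks.

## Annotation screens

All screens are monotone threshold filters over similarity hit tables in
the BLAST tabular (outfmt 6) convention, with query-coverage and
subject-coverage columns appended.

* **Taxonomy** (`assign_taxonomy()`): among hits with query coverage
  strictly > 50% and identity strictly > 70%, the best hit by bitscore
  (ties: identity, then subject id) donates its taxonomy label; no
  qualifying hit gives "Unknown". Best-hit rather than consensus labeling
  was chosen as the standard convention with deterministic tie-breaks.
* **Virulence factors** (`vf_screen()`): hits are retained at identity
  ≥ 90% and subject coverage ≥ 90% — the aligned region must span ≥ 90% of
  the virulence gene, whose length is the natural denominator for that
  filter.
* **Gut-phageome tiers** (`gut_compare()`): `identical` (full query
  coverage, 100% identity) ⊂ `full_coverage` (full coverage, ≥ 96%
  identity) ⊂ `match` (coverage ≥ 50%, identity ≥ 70%); each prophage
  gets exactly one tier, the strongest it satisfies. The match tier's
  identity floor is set at 70% (the screening threshold), not at the
  higher identities matches may empirically show.
* **Integrase** (`flag_integrase()`): case-insensitive substring match of
  "integrase" in gene product descriptions — deliberately simple, since
  annotation dialects vary and recall matters more than precision here.
* **Resistance genes** (`arg_tabulate()`): tabulation only; the package
  consumes a caller's tabular output and never re-implements the caller.

## Host range and cocktails

Spot assays score complete lysis of a bacterial lawn. Technical
replicates are collapsed by `aggregate_replicates()`; the default rule
scores a (phage, strain) pair as lysed only when *every* replicate shows
complete lysis, the conservative reading of a binary "completely lysed"
call, with an "any" rule selectable since the aggregation convention for
replicated spot assays is rarely stated. Downstream reductions are exact
counting: `host_count()`, `pair_table()` (four mutually exclusive
categories that must sum to the panel size), `cocktail_coverage()`
(strains lysed by ≥ 1 member), and `best_cocktail()` (exhaustive search
over size-$k$ subsets, ties lexicographic). Published worked examples — a
19 × 13 lysis table and two-phage category counts over 103 strains — ship
as plain-CSV fixtures and are reduced by these same functions in the
tests and the acceptance script. The phylotype column of the bundled
strain metadata reflects a best reading of the source table's layout and
is not used in any computed statistic.

## The synthetic-data generator

`simulate_prophages()` plants a known family structure: each of
`n_families` families owns a disjoint pool of gene modules; module 1 is
core (always present) and the rest are accessory, dropped per genome with
probability `mosaicism_rate`; every gene copy is its family ancestor
mutated i.i.d. per site at `mutation_rate`; genomes are concatenations of
their genes in module order, on the + strand, with 0-based half-open
coordinates. A single seeded RNG stream drives all draws, and the
generator never touches the caller's RNG state, so one configuration
yields byte-identical artifacts.

Defaults are chosen as a desk-scale caricature of a prophage catalog
with clearly separated families: 3 families × 5 genomes, 2 modules of 3
genes per family, 500 bp genes, 3% per-site divergence (comfortably
inside a 80%-identity species cluster), 25% accessory-module dropout.
The end-to-end fixtures in the tests and the acceptance script use these
sizes with mosaicism 0 — every genome then carries its family's full
module complement, making "one species cluster per family" the planted
truth — which keeps the full pipeline run to seconds.

What the generator deliberately does **not** emulate: real gene-length
variation, GC composition, horizontal transfer *between* families,
sequencing error, prophage boundary/integration-site ambiguity, or the
scoring of any prophage predictor. Passing recovery tests therefore show
that the algorithms are implemented correctly and recover planted
structure under clean separation — not that they would resolve the far
messier homology structure of a real catalog, where families share
mosaic modules and divergence is heterogeneous.

## Numerical conventions

* Alignment scoring: gaps cost open + extend per gap position
  (a length-$L$ gap costs $\mathrm{open} + L\cdot\mathrm{extend}$);
  local scores are floored at 0.
* MCL: prune threshold $10^{-5}$, tolerance $10^{-6}$, max 100
  iterations; non-convergence warns and uses the last iterate; column
  sums are restored to 1 after every inflation.
* Percentages: `percent()` rounds half away from zero at the printed
  precision (the convention of published tables; base R's `round()`
  rounds half to even).
* Tie-breaks are always deterministic: lowest node index (MCL), id order
  (greedy clustering and representative selection), lexicographic subject
  id (taxonomy), lexicographic phage sets (cocktail search).
* Degenerate inputs: empty hit tables give "Unknown"/empty results, an
  edgeless network gives all-singleton components, a single-replicate
  spot assay is rule-invariant, and an empty catalog summarizes to zeros
  without division.

## Known limitations

* Gene-family clustering scores nucleotide sequences; deeply diverged
  homologs detectable only in protein space will be missed.
* The all-vs-all stage is quadratic in gene count; it is sized for
  catalogs of hundreds of genes per run, not for hundreds of thousands.
* `best_cocktail()` is exhaustive and intended for small phage panels
  (tens of phages); it makes no attempt at submodular approximation.
* Taxonomy roll-up to morphology groups is a regex mapping over label
  text and inherits whatever dialect the hit table's labels use.
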