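---
title: "Methods: pan-genome islands, homeocassettes, and the supporting analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome islands, homeocassettes, and the supporting analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panisles)
```

`panisles` implements a pan-genome-graph view of gene content variation
in a set of closely related prokaryotic genomes (same species, typically
ANI ≥ 98.5%). This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic tests
do and do not establish about real data.

## The pan-genome data model

Gene calls are a tibble of records `(genome_id, contig_id, index, strand,
family_id, annotation, nt_seq)` with 0-based, contiguous gene-order
indices per contig. Families can be supplied (e.g. from Panaroo) or
computed by `cluster_families()`, a greedy single-linkage clustering at a
global nucleotide identity threshold (default 0.98). This deliberately
simplified clustering — plus `build_pangraph()` — substitutes for
Panaroo's multi-stage graph correction; real Panaroo graphs can be
imported instead (`read_panaroo()`), and the bespoke computation of this
package begins *after* graph construction.

The pan-genome graph has families as nodes and observed gene adjacencies
as edges, each edge carrying the set of supporting genomes. Edges are
unordered (strand-agnostic, since islands occur in either orientation),
never cross contig boundaries, and a genome supports an edge once
regardless of copy number (multi-copy handling is not specified by the
graph model; counting each genome once is this package's choice).

Divisions: a family is **core** when its representation reaches the core
threshold — 44 of 47 genomes (~94%) by default, `ceiling(0.94 * n)`
otherwise — **cloud** when found in exactly one genome, **shell** in
between.

## Island discovery

An island is a maximal run of non-core families bounded on both sides by
core families. The published graph-based search expands ±20 genes around
each family and looks for the coverage pattern high–low–high; because
every accepted island must be a traceable linear path between its two
core flanks, an equivalent formulation is a per-genome linear scan with
locus-level merging, which is what `find_islands()` implements. The two
give identical output on linearizable loci, and the scan needs no ±20
length window — `max_len` defaults to 40 genes, comfortably above the
largest island the approach is expected to report (~22 genes).

Numerical/merging choices, all at the locus (= unordered core-flank
pair) level:

- identical, reverse-ordered, or set-equal member sets are one island;
- a proper subset merges as a *partial carrier* of the superset island;
- member sets with Jaccard < 0.5 against every island at the locus found
  a new island;
- the remaining case (Jaccard ≥ 0.5, neither subset nor equal) merges
  into the highest-Jaccard island, takes the union of members, and flags
  the island `merged_variants` — the spec of the search leaves this case
  open, and the union keeps partial rearrangements visible rather than
  multiplying island variants;
- loci with more than `max_variants_per_locus` (default 3) islands are
  discarded as over-multifurcated and reported; 3 is the largest count
  the approach is meant to retain at one locus;
- single-gene runs are kept only when their locus hosts at least two
  islands (the "size one, same core genes as another island" rule);
- runs truncated by a contig end lack a flank and are skipped, but
  counted in the report.

The low-representation band is "anything below the core threshold": an
island by definition cannot contain a core gene, and no tighter numeric
band is imposed.

The mobilome neighborhood scan (`neighborhood_scan()`) checks annotation
labels at gene offsets 1..5 beyond each flank (configurable radius) for
transposase/insertion-sequence, integrase/recombinase and tRNA
vocabularies; island-member families are never counted, so a tRNA on the
island itself does not inflate the neighborhood tally. G+C content is
`(G+C)/(A+C+G+T)` with N excluded from both counts. Cross-carrier
identity compares the concatenated member-gene sequence per carrier after
orientation normalization (canonical form = lexicographic minimum of the
sequence and its reverse complement).

## Homeocassettes

All unordered island pairs at one locus are *conflicting pairs*; genomes
carrying both islands are reported as mutual-exclusivity violations, not
errors. For each cross-island gene pair, amino-acid local alignment
(BLOSUM62, affine gaps 11/1) provides the score; nucleotide identity
(match/mismatch +2/−3, gaps 5/2) is recorded when sequences exist.
Significance uses a shuffle-permutation test in place of an external
PRSS-style program: the observed score is ranked against `n_shuffles`
(default 200) alignments to residue shuffles of the partner gene, with
the pseudocount estimator `perm_p = (1 + #null ≥ obs) / (1 + n_shuffles)`.

One inconsistency had to be resolved: the nominal significance level
(`alpha = 0.001`) lies below the estimator's attainable floor
`1/(1+200) ≈ 0.005`, yet identical genes (which always sit exactly at
the floor) must clearly count as homologous. The package therefore treats
`perm_p ≤ max(alpha, 1/(1+n_shuffles))` as significant — the floor is
significant by construction, and raising `n_shuffles` to ≥ 999 restores
the literal 0.001 threshold. Lowering `alpha` still never increases the
number of calls. A pair must additionally align over ≥ 50% of the
shorter gene.

Significant hits resolve greedily by descending score (ties broken
lexicographically) into one-to-one **homeoalleles**; leftover significant
hits attached to an already-matched gene become **unbalanced
duplications**; unmatched genes are **iORFans**. Greedy best-hit matching
mirrors reciprocal-best-hit practice; an optimal bipartite matching was
deliberately not used. A pair is a **homeocassette** when at least 50%
(inclusive) of the gene content of *each* island participates in
homeoallele or duplication matches — the published rule says "their gene
content" without naming an island, and requiring both is the stricter,
symmetric reading (flagged as an open interpretation).

## tANI distances and the phylogeny

`tani_distance(ani, af) = −ln(ani × af)`. The product form is used
because only it reproduces the printed correspondence between the
species-boundary distance 0.315 and ANI 73% at AF = 1 (−ln 0.73 =
0.3147); a "+" that appears in one prose statement of the formula is
treated as a typographical artifact. Undefined products (AF = 0) are
capped (default 10) and flagged.

ANI/AF follow the fragment convention of the underlying jANI-style
method: the query is cut into consecutive 1020-nt windows (a trailing
window ≥ 100 nt is kept so that a genome against itself yields AF exactly
1), each fragment is located in the subject by exact 14-mer seeds spaced
~80 nt (both strands; at 5% divergence the chance that all seeds miss is
~10⁻⁴) and evaluated ungapped on the seeded diagonal, falling back to
gapped local alignment when the diagonal identity drops below 0.9 (i.e.
when indels are plausible). Hits with identity ≥ 0.7 over ≥ 0.7 of the
fragment are retained; ANI is the mean retained identity, AF the
retained aligned length over the fragmented query length; pairs are
symmetrized by averaging both directions. Trees are neighbor-joining
(`ape::nj`) with negative branch lengths clamped to 0; an all-zero
matrix yields a star tree by construction. Bootstrap supports resample
each query's fragments with replacement, reusing cached per-fragment
statistics, and report bipartition frequencies ×100.

## Neutral-core population structure

Tajima's D is computed from the 1989 formulas (coefficients a1, a2, b1,
b2, c1, c2, e1, e2) per core-gene alignment after removing columns with
gaps or N (a conventional choice; the source text does not state one).
Families with |D| < 0.2 — strictly; |D| = 0.2 is non-neutral — are taken
as near-neutral, concatenated, and reduced to polymorphic columns to form
the SNP matrix; genomes missing a family contribute N and drop out of
the affected pairwise denominators.

Population assignment is a silhouette-guided stand-in for model-based
nested clustering (rhierBAPS-style): average-linkage hierarchical
clustering on N-aware SNP Hamming distances, the cut chosen by maximal
mean silhouette over k ∈ [2, 10], then the same procedure within each
level-1 cluster for level 2 (clusters smaller than 3, or with all-zero
internal distances, stay whole). Two levels are the default — the
nesting depth is not prescribed anywhere, and two levels already express
the clade/sub-clade structure the analysis is after. Refinement of
level-1 labels by level-2 labels holds by construction. The procedure is
deterministic; the `seed` argument exists only for interface stability.

## DTL reconciliation

Gene trees are uncorrected NJ "proto-phylogenies" on Jukes–Cantor
distances (reconciliation-aware tree correction is an external concern
and out of scope); trees require ≥ 3 taxa and non-identical sequences,
and genes failing that are skipped and reported. Rooting evaluates every
edge and keeps the minimum-reconciliation-cost position, ties broken by
the smallest postorder edge index.

The reconciliation itself is an undated DTL parsimony dynamic program
(duplication, transfer, loss; transfers allowed between any two
non-ancestrally-related species edges, no time-consistency constraint —
matching the default behavior of the standard reconciliation tools).
The minimum cost is exact. "300 independent runs" is realized as 300
uniform samples of optimal backtraces — the DP counts optimal solutions
per cell, so sampling is exactly uniform over cost-minimal
reconciliations — and event counts are aggregated by arithmetic mean.
Rates are `count / (n_internal_nodes × total branch length)` of the gene
tree; genes with zero total branch length are excluded and flagged. All
three cost schemes (2,3,1), (3,3,1), (2,4,1) are reported, with (2,3,1)
as the headline default. Island trees are built from the concatenated
member genes of each carrier. The island-vs-core comparison is a Welch
two-sided t-test per event class.

## The synthetic pan-genome generator

The generator's defaults are the conditions the downstream checks run
under: 47 genomes, a 2,000-family core backbone with the 44-of-47 core
threshold, and ten planted islands of 2–22 genes when the default island
layout is requested. Shell and cloud counts default to 400 and 200 — a
desk-scale rendering of the several-thousand-family accessory genomes
typical of such datasets. No generative model is prescribed by the
analysis itself, so the remaining choices are the package's own, made
once:

- gene sequences are i.i.d. per position at a target G+C, then ORF-ized
  (start/stop codons, no interior stops) — composition is the only
  sequence property the downstream stages consume;
- each shell/cloud family occupies its own inter-core locus (at most one
  accessory family per locus, placed away from island neighborhoods), so
  an islands-free configuration contains no multi-gene accessory runs
  and "zero false islands" is a well-defined control;
- homeoalleles on a partner island are built by replacing whole codons
  with codons of a different amino acid, so the amino-acid identity to
  the source gene is `1 − k/n` exactly at the planted target;
- core-gene SNPs are placed on a two-level planted genealogy (clade,
  sub-clade, private sites at 2×, 1×, and 0.5× `core_snp_rate`), so
  population clustering has recoverable nested structure;
- genomes are one contig by default; a `fragmentation` option introduces
  contig breaks away from islands to exercise contig-end handling;
- flanking mobilome elements (transposase/integrase/tRNA) are inserted
  at configurable gene-order offsets from the island flanks, at most one
  per side in the default layout so they remain rejected singleton runs
  rather than unintended islands.

What passing the synthetic tests shows — and what it does not: the
generator produces substitution-only divergence, clean ORFs, perfectly
consistent family assignments, and islands with exact core flanks.
Recovery there establishes the correctness of the search, merging,
classification and reconciliation logic, not robustness to annotation
error, assembly fragmentation beyond the modeled breaks, paralog
confusion, or within-island recombination in real draft genomes.

## Problem sizes used by the shipped checks

The test suite exercises: island recovery on twenty 47-genome × 2,000
core-family pan-genomes (plus islands-free controls); homeocassette
classification across twenty seeds with planted homeoallele fractions
0.2/0.4/0.6/0.8 on 16-genome pan-genomes; DP-vs-enumeration equality for
reconciliation on random tree pairs up to six leaves under all three
cost schemes; Tajima's D against an independent implementation on 100
random alignments (n = 4..20, S = 1..50) at 10⁻¹⁰ relative tolerance;
NJ recovery of additive 4- and 5-taxon matrices plus full bootstrap
support on planted two-clade genome quartets (8 kb) over ten seeds; and
byte-level reproducibility of the full pipeline on an 8-genome
configuration. These sizes are the package's chosen test conditions;
larger runs use the same code paths.

## Known limitations

- `cluster_families()` is O(n²) in unique sequences and intended for
  small inputs; use Panaroo-scale tools for large datasets and import
  their output.
- Island discovery requires both core flanks; islands at contig ends or
  next to non-core flanks are out of scope by definition.
- The homology stage compares one representative sequence per member
  family (the first carrier's copy).
- The Panaroo import consumes presence/absence and the GML graph; it
  does not reconstruct per-genome gene orders, so only the graph stage
  runs in that mode.
- Remote homology below local-alignment sensitivity (profile/HMM
  territory) is not detected, so homeoallele counts are conservative.
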