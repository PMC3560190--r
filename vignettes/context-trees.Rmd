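---
title: "Context trees: comparing gene neighborhoods across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context trees: comparing gene neighborhoods across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contexttrees)
```

## The problem and the model

A gene's genomic context — which genes surround it, on which strand, at
what spacing — often carries functional signal that sequence homology
misses. The motivating case is a pair of highly homologous genes with
different roles, one occurring alone and the other inside a conserved
multi-gene operon: automated annotation confuses them, their contexts do
not. `contexttrees` turns this observation into a pipeline: extract the
context of every query match across a set of genomes, score all contexts
pairwise with a dissimilarity metric, and agglomerate them into a
*context tree* whose major branches group species by context type.

The tree is a **multidendrogram**, built by variable-group agglomerative
clustering: at every step the algorithm finds the global minimum
inter-cluster distance $d^\*$, connects all cluster pairs whose linkage
distance ties $d^\*$, and merges each connected component of that tie
graph in a single step. A merged node records the agglomeration band
$[h_{\min}, h_{\max}]$ — the minimum and maximum pairwise linkage
distance among the fused clusters (a point when there is no tie). The
payoff is exactness under ties: pairwise agglomeration breaks ties by
input order and can return different trees for permuted inputs, whereas
the multidendrogram is permutation-invariant (a property the test suite
fuzzes directly).

## Grouping schemes and their parameters

All schemes operate on features sorted by (contig, start). The
intergenic gap between consecutive genes is
$\mathrm{gap} = \mathrm{start}_{i+1} - \mathrm{end}_i - 1$, the count of
nucleotides strictly between them: gap 0 means abutting, overlapping
genes have negative gap and always chain. Runs break at contig
boundaries and strand flips, never wrap around (GFF carries no reliable
topology flag, so circular contigs are treated as linear).

| scheme | parameter | default | meaning |
|---|---|---|---|
| `single_gene` | — | — | each query match is its own context |
| `operon` | `threshold` (nt) | 20 | operon prediction by intergenic distance |
| `strand_distance` | `distance` (nt) | 75 | same kernel; "D75" = distance 75 |
| `gene_window` | `k` (genes) | 1 | match ± k genes on its contig |
| `nt_window` | `window` (nt) | 0 | genes overlapping the match ± window |
| `custom` | file | — | groupings listed explicitly |

`operon` and `strand_distance` share one kernel, differing only in the
conventional threshold; the suite asserts their equivalence as a
property. Thresholded grouping is deliberately naive — no probabilistic
operon model — because the comparison downstream, not the grouping, is
where the signal is extracted; the threshold is monotone (larger
thresholds only coarsen the partition), which the tests also check.

Leaves are named `species-serial`, the serial counting query matches
within a species in genomic order from 1, restarting per build. A
grouping containing several matches becomes one leaf (one context is one
leaf), keeping the serial of its first match. The `-` delimiter keeps
names Newick-safe; whitespace in species names becomes `_`.

## Dissimilarity metrics

Set metrics reduce a context to the *set* of identity keys of its genes
— homology cluster IDs, or annotation strings normalized by lowercasing
and whitespace collapsing (annotations differ in case and spacing across
genomes). Duplicated keys within one context count once. Genes with no
homology cluster contribute no key under the cluster key. Dice
$1 - 2|a \cap b|/(|a|+|b|)$ and Jaccard $1 - |a \cap b|/|a \cup b|$ are
both offered; Jaccard ≥ Dice always, with equality exactly at 0 and 1,
which the suite verifies on random sets.

**Moving distances** targets contexts with similar gene content but
different spacing. Its definition here: restrict both ordered gene lists
to the keys they share (repeated keys matched in positional order); for
each consecutive pair of the shared subsequence compute the intergenic
gap within each context; return the mean absolute gap difference, plus a
per-unshared-gene penalty (default 0 nt). Contexts sharing fewer than
two genes get a configured sentinel (default 10 000 nt, far above any
plausible within-operon spacing difference) — comparing spacing needs at
least one shared adjacency. Each ingredient was chosen so the measure is
order-sensitive, spacing-sensitive, and exactly zero on identical
contexts; the implementation is checked against a brute-force gap-list
oracle. By default a context whose genes are mostly minus-strand is
mirrored before comparison (reversing gene order preserves all pairwise
gaps, so only the order flips), paralleling the viewer's strand
normalization; ties in strand count do not mirror.

**Total length** is $|\,\mathrm{span}(A) - \mathrm{span}(B)\,|$ with
span the envelope length `span_end − span_start + 1` — the plain reading
of "length of the region". A switch (`mode = "gene_sum"`) compares
summed gene lengths instead, preserving the alternative reading.

## Linkages and numerical choices

Five linkages: single (min), complete (max), unweighted average (UPGMA,
size-weighted so it equals the mean over leaf pairs), weighted average
(WPGMA, plain mean over member clusters), and **joint between-within**,
defined here as the root mean square dissimilarity over *all* leaf pairs
of the merged union — between-cluster and within-cluster pairs alike:
$d(U, K) = \sqrt{\tfrac{1}{\binom{|U|+|K|}{2}} \sum_{\{i,j\} \subset U \cup K} d_{ij}^2}$.
The name suggests a measure pooling between- and within-group
dispersion, and this is the simplest such pooling that is zero on
identical clusters and reduces sensibly for singletons; it is isolated
behind the linkage interface so an alternative definition can be
swapped without touching the engine. Unlike the monotone linkages it can
in principle produce non-monotone merge heights (like centroid
linkage), in which case Newick branch lengths may be negative.

Tie detection uses a relative epsilon (default $10^{-9}$, scaled by
$\max(|d^\*|, 1)$): tie semantics must not depend on floating-point
summation order, while exact ties in rational inputs are always caught.
Node heights default to `band_low` — the agglomeration threshold, the
natural ultrametric height; band midpoints are available
(`height_mode = "band_mid"`). Children are ordered by smallest leaf
name and branch lengths printed with fixed decimal formatting, so
Newick output is byte-reproducible.

On tie-free matrices the engine reduces to standard pair-group
agglomeration; the suite checks topology and merge heights against
`hclust` on 200 random matrices and single-linkage heights against
minimum-spanning-tree edge weights (`vegan::spantree`).

## Rendering

Contexts render as SVG panels: one panel per leaf, genes as rectangles
above (+) or below (−) a centerline, horizontal extent linear in
nucleotide coordinates, panel midpoint at the context span's center, one
shared nt-per-pixel scale across panels. Colors come from a
deterministic HSV wheel over sorted identity keys, so identical keys
match across species and across reruns; gray is reserved for flanking
genes (shown within `flank_nt` of the span when requested). Strand
normalization mirrors a panel when a strict majority of its context
genes are minus-strand — an involution, asserted as such. SVG replaces
raster export: it is resolution-independent and byte-diffable, which the
round-trip tests exploit. Pixel constants (panel 900×80, gene height
22) are package constants, not tunable science.

## The synthetic-data generator

`generate_scenario()` writes complete working sets — GFF per species,
long-format homology table, species mapping — determined entirely by a
seed. The central scenario, `single_gene_vs_operon`, plants in half the
species a lone query-cluster gene and in the other half the query gene
heading a 4-gene same-strand run with intra-operon gaps of 12, 8, 15 nt
(all ≤ 20, so the run survives both the operon threshold and D75
grouping); this mirrors the lone-gene-versus-operon contrast the method
exists to resolve. Gene lengths are uniform in [300, 1500] nt — a
plausible microbial scale — and background genes carry species-unique
clusters, random strands and gaps of 200–500 nt, keeping them out of
any query context at thresholds ≤ 75 nt. Other scenarios:
`conserved_operon` (identical contexts everywhere: the tree must be one
n-way merge at height 0), `gap_variation` (same content, different
spacing: exercises moving distances), `tie_block` (all pairwise
dissimilarities equal by construction).

What the generator does *not* emulate: annotation noise, missing or
split genes, paralogs inside one context, pseudo-genes, multi-contig
assemblies of real drafts, or any evolutionary model of rearrangement.
Passing the scenario tests therefore demonstrates that the machinery
recovers planted structure exactly, not that real genomes will separate
this cleanly; on real data the interesting cases are precisely the
intermediate contexts.

Test and acceptance problem sizes — 6–12 genes per genome, up to 12
leaves per matrix, 100–200 randomized repetitions — were chosen as the
smallest sizes at which every property (partition laws, tie handling,
oracle agreement) is non-trivially exercised.

## Design decisions on points the interface left open

- **GFF dialect.** Both GFF2 (`key value;`) and GFF3 (`key=value;`)
  attributes are accepted, auto-detected per record, because real
  annotation files mix dialects; strand `.`/`?` is rejected outright
  since every downstream computation needs strandedness. When a `gene`
  and `CDS` record share an ID, the `gene` record wins
  (deterministic deduplication).
- **Homology table layouts.** Two tab-delimited layouts are supported —
  long (species/gene/cluster) and cluster-per-line
  (`cluster<TAB>species|gene...`) — covering the common shapes; the
  dispatch in `parse_homology_table()` is the extension point for more.
- **Custom-scheme leaves** keep serial-based leaf names for consistency
  with every other scheme; the file's labels identify groupings during
  parsing.
- **The command-line layer** is a thin script over exported functions
  (`inst/cli/contexttrees.R`) rather than a compiled entry point: the R
  functions are the primary interface, the script exists for shell
  pipelines.

## Limitations

Contexts never span contigs; operon prediction is purely
distance-based; Dice/Jaccard use set (not multiset) semantics, so
tandem duplications within a context are invisible to them; the moving
distances and total length formulas are this package's own definitions
of the named ideas; and trees carry no support values — the agglomeration
band is a tie record, not a confidence measure.
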