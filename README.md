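# contexttrees

Cross-species comparison of **genomic contexts** — the neighborhoods of
genes on a chromosome, including their order, strand, and intergenic
spacing — for annotated (mostly microbial) genomes.

Two genes can be nearly identical in sequence yet do different jobs; a
classic symptom is a gene that occurs alone in some species but inside a
conserved operon in others. Sequence homology alone then mislabels it,
while the *context* separates the cases cleanly. `contexttrees` makes
that comparison systematic: it collects the genomic context of every
query match across a set of species and organizes the contexts into a
**context tree**, a dendrogram built from context-to-context
dissimilarities rather than sequence differences.

The package is aimed at comparative genomicists who already have
annotated genomes (GFF) and, typically, cross-species homology clusters
from an upstream BLAST + MCL style pipeline.

## Method

1. **Context sets.** A genome's genes are grouped into contexts by a
   named scheme: each query match alone (`single_gene`); operons
   predicted by an intergenic-distance threshold (consecutive same-strand
   genes with gap ≤ *T*, default *T* = 20 nt); the same rule at distance
   *D* (e.g. the "D75" set, *D* = 75 nt); ±*k* genes or ±*w* nt around a
   match; or custom groupings from file. The intergenic gap between
   consecutive genes is `start[i+1] − end[i] − 1` (nucleotides strictly
   between them), so overlapping genes always chain.

2. **Dissimilarity.** For contexts *A*, *B* with identity-key sets
   (homology cluster IDs or normalized annotations) *a*, *b*:

   - Common genes – Dice: `d = 1 − 2|a∩b| / (|a| + |b|)`
   - Common genes – Jaccard: `d = 1 − |a∩b| / |a∪b|`
   - Moving distances: mean |gap difference| over consecutive shared
     genes, sensitive to order and intergenic spacing
   - Total length: |span(A) − span(B)|

3. **Multidendrogram clustering.** Variable-group agglomerative
   hierarchical clustering: at each step *all* cluster pairs tied at the
   minimal linkage distance merge simultaneously, producing nodes with
   possibly more than two children, each carrying an agglomeration band
   `[band_low, band_high]`. The result is invariant to the input order
   of the leaves — the property ordinary pair-group clustering lacks
   under ties. Linkages: single, complete, unweighted/weighted average,
   and joint between-within (root mean square over all leaf pairs of the
   merged union).

4. **Export.** Newick (multifurcating, band-derived heights), PHYLIP or
   TSV distance matrices, JSON tree dumps, and SVG multi-genome browser
   panels (genes as rectangles above/below a centerline by strand,
   colored by homology/annotation, optional gray flanking genes and
   alphabetized legend).

## Worked example

Generate a synthetic working set in which the query gene (homology
cluster 1) is a lone gene in half the species and sits in a 4-gene
operon in the other half, then build the context tree:

```r
library(contexttrees)

sc  <- generate_scenario(scenario_spec("single_gene_vs_operon",
                                       n_species = 6, seed = 5), dir = "fx")
cfg <- run_config(mapping_file = sc$mapping, homology_file = sc$homology_table,
                  query_value = 1,                     # homology cluster ID
                  context_scheme = "strand_distance", distance = 75,  # "D75"
                  metric = "dice", linkage = "joint_between_within",
                  newick_out = "fx/tree.nwk")
res <- run_build_tree(cfg)
cat(to_newick(res$tree), "\n")
```

```
((species_01-1:0,species_03-1:0,species_05-1:0):0.4647580015,
 (species_02-1:0,species_04-1:0,species_06-1:0):0.4647580015);
```

The tree splits into two major out-branches at a joint between-within
height of ≈ 0.465: species 1/3/5 (lone-gene contexts, pairwise Dice 0)
versus species 2/4/6 (operon contexts, also mutually identical). Between
the groups the Dice dissimilarity is `1 − 2·1/(1+4) = 0.6`; within each
it is 0, hence the three-way tie merges at height 0. Leaves are named
`species-serial` (`species_01-1` = first query match in species 1).

The same pipeline runs from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/contexttrees.R", package = "contexttrees"))')
Rscript $CLI build-tree --mapping fx/species_mapping.tsv \
    --homology fx/homology.tsv --query-cluster 1 \
    --scheme strand_distance --distance 75 --metric dice \
    --linkage joint_between_within --newick fx/tree.nwk
Rscript $CLI render --mapping fx/species_mapping.tsv \
    --homology fx/homology.tsv --query-cluster 1 \
    --svg fx/contexts.svg --legend --show-surrounding --flank-nt 2000
Rscript $CLI list-contexts --mapping fx/species_mapping.tsv \
    --homology fx/homology.tsv --query-cluster 1
```

```
species_01-1  species_01  c1:1000-2132  1 genes
species_02-1  species_02  c1:1000-4499  4 genes
...
```

Subcommands: `build-tree`, `render`, `gen-fixtures`, `list-contexts`.
Exit codes distinguish usage (2), input (3), parse (4) and
no-matches (5) failures.

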