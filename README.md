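# setweaver

Functional genomics experiments — differential expression screens, QTL
positional candidate lists, mutant phenotype annotations, literature
mining — all end in the same currency: a set of genes. These sets are noisy,
heterogeneous, and come from different species and platforms, so they rarely
replicate exactly; what they can show is *consilience*, genes and relations
that recur across many independently derived results. `setweaver` is an R
toolkit for exactly that workflow: it harmonizes heterogeneous, cross-species
gene sets into a single bipartite graph and provides the combinatorial
machinery to interrogate it, entirely offline on your own data or on seeded
synthetic fixtures with planted ground truth.

## The model

A collection of gene sets induces a **bipartite graph** G = (S ∪ V, E) with
one vertex class S for gene sets, one class V for genes, and an edge
(s, v) ∈ E whenever gene v is a member of set s. Cross-species sets become
comparable after **harmonization**: each (species, gene) pair is mapped into a
homology **cluster** (HomoloGene-style), with unmapped genes kept as
deterministic singleton clusters. On this structure the package computes:

- **Set similarity.** Jaccard index J(A,B) = |A∩B| / |A∪B|, pairwise or
  against one query set, and the exact one-sided **hypergeometric overlap
  test**: with N universe genes, K in set A and n drawn in set B,
  P(X ≥ k) = Σᵢ₌ₖ C(K,i)·C(N−K,n−i) / C(N,n), with Benjamini–Hochberg
  q-values in matrix mode.
- **Hierarchical similarity DAG.** All **maximal bicliques** of the bipartite
  graph — groups of sets whose common gene intersection can be extended in
  neither direction — arranged as a Hasse diagram with the individual sets at
  the leaves and k-way intersections at level k, with user-chosen *emphasis
  genes* flagged wherever they occur.
- **Guilt-by-association ranking (ABBA-style).** From a query gene list,
  retrieve every set with at least m query genes, then rank all non-query
  genes by *prevalence* — the number of retrieved sets containing them. The
  walk is unweighted: each supporting set counts exactly once.
- **Hub-gene discovery.** Per-gene degree (number of containing sets) tables
  and the minimum-degree bipartite subgraph.
- **Boolean set algebra**, **tier-based filtering** (curation tiers I–V, from
  curated resources down to private uploads), gene/homolog/free-text
  **search**, and a **literature-term set builder** that joins
  gene→publication and publication→term tables, keeping a (gene, term)
  association only when supported by ≥ 2 distinct publications.

## Worked example

```r
library(setweaver)

col <- gene_set_collection(list(
  gene_set("A", c("g1", "g2"), species = "mouse", tier = "I"),
  gene_set("B", c("g2", "g3"), species = "mouse", tier = "III"),
  gene_set("C", c("g1", "g2", "g3"), species = "mouse", tier = "III")
))

jaccard_matrix(col)
#> # A tibble: 3 × 5
#>   set_a set_b intersection_size union_size jaccard
#>   <chr> <chr>             <int>      <int>   <dbl>
#> 1 A     C                     2          3   0.667
#> 2 B     C                     2          3   0.667
#> 3 A     B                     1          3   0.333
```

A and B each share two of three genes with C (J = 2/3) but only g2 with each
other (J = 1/3). The full intersection hierarchy:

```r
build_hisim_dag(col, emphasis = "g2")
#> <hisim_dag> 6 nodes (3 leaves, max level 3), 6 edges
#>   6 node(s) carry emphasis genes
```

Three leaves, the maximal two-way intersections {A,C}·{g1,g2} and
{B,C}·{g2,g3}, and the three-way node {A,B,C}·{g2}; every node contains the
emphasis gene g2. Candidate genes related to a query list:

```r
abba_rank(col, c("g1", "g2"), min_overlap = 2)
#> # A tibble: 1 × 3
#>   gene_id prevalence supporting_sets
#>   <chr>        <int> <list>
#> 1 g3               2 <chr [2]>
```

g3 is the only non-query gene in the two retrieved sets (B and C), supported
by both. Results are tibbles throughout, so they pipe straight into dplyr;
`tidy()`/`glance()` summarize fitted objects and `autoplot()` draws each
result type (DAG layout, bipartite hub view, degree bars, Jaccard heatmap).

A command-line wrapper is installed at `exec/setweaver` with subcommands
`simulate`, `harmonize`, `jaccard`, `hypergeom`, `boolean`, `hisim`, `abba`,
`gsg`, `mesh-build`, and `search`; outputs are TSV with a commented
provenance header (tool version, seed, input MD5 digests) or JSON via
`--json`.

## File formats

- **GMT** (Gene Matrix Transposed): tab-delimited, one set per line —
  `set_id`, description, then member genes (`read_gmt()` / `write_gmt()`).
- **Long-form TSV** (`set_id`, `gene_id`, optional `score`): the carrier for
  per-gene association scores, which GMT cannot hold.
- **Homology TSV** (`cluster_id`, `species`, `gene_id`): one row per cluster
  member (`read_homology_tsv()`).
- **Graph exports**: GraphML, DOT, or JSON with node attributes (level,
  degree, emphasis, labels) via `export_graph()`; deterministic node order,
  byte-stable across runs.

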