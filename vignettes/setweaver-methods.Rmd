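---
title: "Methods: combinatorial gene-set integration in setweaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial gene-set integration in setweaver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setweaver)
```

## The bipartite model

Every analysis in `setweaver` operates on one structure: a collection of
gene sets viewed as a bipartite graph, with set vertices on one side, gene
vertices on the other, and an edge for each membership. The model makes two
assumptions worth stating plainly. First, gene identifiers are *opaque,
case-sensitive tokens*: the package never guesses that `Trp53` and `TP53`
are the same thing. All identifier reconciliation — aliasing, symbol vs.
accession, and cross-species homology — is delegated to an explicit homology
cluster table, because silent normalization is exactly the kind of magic
that makes cross-study analyses irreproducible. Second, membership is
binary. Per-gene association scores (p-values, correlations) are carried and
preserved through I/O, but no current operation weights by them; the
guilt-by-association walk in particular is deliberately unweighted, so one
large noisy set cannot dominate a tally by its size or score profile.

## Harmonization

Cross-species comparability comes from mapping each (species, gene) pair to
a homology *cluster* (the HomoloGene-style many-to-many representation,
rather than pairwise ortholog edges, because clusters give a deterministic
partition to test against). Three design choices were genuinely open:

- **Unmapped genes** become deterministic singleton clusters
  (`u:<species>:<gene>`) rather than being dropped. Mapping is therefore
  total and injective on the unmapped remainder, which yields the property
  that an *empty* index is a pure relabeling: every downstream statistic
  (Jaccard, degree, overlap p-values, biclique structure) is provably
  unchanged. The test suite checks this.
- **Within-species paralogs** that share a cluster collapse to one node by
  default; a mapped set can only shrink. `collapse = FALSE` keeps
  species-qualified nodes for users who need paralog resolution. When scored
  paralogs collapse, the best score survives under a `score_polarity` flag
  (`"min"` for p-value-like scores, the default; `"max"` for magnitudes) —
  a policy choice, made explicit rather than averaged away.
- **Idempotence** is enforced by flagging harmonized sets: re-harmonizing is
  the identity, so pipelines can be re-run safely on partially processed
  inputs.

## Similarity statistics

The Jaccard index is computed from exact integer intersection and union
counts. The overlap test is the one-sided (enrichment) hypergeometric upper
tail, computed exactly via `stats::phyper` — a summation of the probability
mass function, not a normal approximation, which matters at typical gene-set
sizes where tail probabilities are tiny. The background universe defaults to
the collection-wide gene universe (post-harmonization when an index is
loaded), and can be overridden; the choice of background is the single
biggest lever on these p-values, so it is an explicit argument rather than
hidden state. In matrix mode Benjamini–Hochberg q-values are reported
alongside raw p-values; BH was chosen because overlap tests across a
collection are strongly positively dependent, where BH remains a sensible
(if slightly conservative) default.

Whether similarity should be computed before or after homology collapse is
ambiguous in principle; `setweaver` computes it *post*-harmonization
whenever an index is loaded, since that is the space in which cross-species
overlap is meaningful, and documents the behaviour rather than guessing per
call.

## The hierarchical similarity DAG

A *maximal biclique* here is a pair (sets P, genes G) where G is exactly the
full intersection of the sets in P and no further set contains all of G.
These pairs are precisely the closed concepts of the membership relation, so
enumeration proceeds by closing the distinct per-gene *set signatures* (the
set of sets containing each gene) under pairwise intersection; each closed
set-group then pairs with the genes whose signature contains it. This is
complete and duplicate-free without visiting the 2^n lattice of set subsets,
and it is validated in the tests against an exhaustive subset-testing oracle
on hundreds of random collections (up to 8 sets and 20 genes, where the
oracle is cheap).

The DAG places one leaf per input set at level 1 — *always*, even when a
set's genes are wholly contained in another set, because the leaves are the
user's inputs and must stay visible — and each maximal biclique at level
|P|. Edges are the Hasse relation: the transitive reduction of strict
inclusion on set-groups, computed directly (O(n³) in the node count, which
is negligible at these scales). Emphasis genes are intersected with each
node's shared genes and flagged, never used to prune: filtering display is
the caller's decision, and no similarity threshold is applied before
enumeration for the same reason.

## Guilt-by-association ranking

The two-step walk: retrieve all sets with at least `min_overlap` query
genes, then rank non-query genes by the count of retrieved sets containing
them. Ties break lexicographically by gene id for reproducibility. In
homology mode the query and the collection are first moved into one cluster
space, and any homolog of a query gene counts as the query itself — and is
therefore excluded from the ranking — to prevent a gene trivially
"discovering" its own ortholog. Mixed spaces (raw query against harmonized
sets) are not supported within a run; the overlap count would be
meaningless. A `min_prevalence` output filter is exposed (default 1) because
practical use tends to focus on the handful of highly prevalent novel genes;
no significance is attached to prevalence, since no null model for it is
defined here.

## Degree-based hub discovery

`degree_table()` counts containing sets per gene and reports the fraction of
sets alongside; `threshold_subgraph()` keeps genes at or above a minimum
degree, ordering gene nodes ascending by degree so the most connected genes
sit at the end (the conventional orientation for this display). Set nodes
are never dropped: a set contributing nothing above threshold is itself a
finding. The gene-node lists form a monotone filtration in the threshold,
which the tests assert.

## Literature-term set builder

Term sets are built by joining gene→publication to publication→term and
admitting a (gene, term) pair only with at least `min_pubs` *distinct*
supporting publications (default 2, the minimum-evidence convention for
suppressing one-off annotation artifacts). Counting distinct publications —
not rows — means duplicated input never inflates evidence; inputs are
deduplicated before counting and the tests verify row duplication is
inert. Derived sets default to Tier II (data derived from an operation on
resource data). Term hierarchies are out of scope: terms are flat tokens,
and any sub-tree expansion must be applied upstream. The resulting sets
inherit literature bias wholesale — absence from a term set is absence of
evidence, not evidence of absence — and no bias correction is attempted.

## The synthetic-data generator

`fixture_spec()` describes the scenario the package exists for: `n_sets`
independent experiments over a `universe_size` gene universe, where
`n_signal_genes` planted signal genes each join each set independently with
probability `p_signal`, and each set is padded with `background_per_set`
uniform background genes. The defaults — 20 sets, 30 signal genes at
p = 0.9, 200 background genes with 10 drawn per set — model a mid-sized
curated collection around one biological theme: a strong consilient core
with study-specific noise. A signal gene's degree is Binomial(n_sets,
p_signal) (checked empirically against its expectation in the tests), while
a background gene's degree concentrates near n_sets · background_per_set /
pool size ≈ 1, which is what makes degree-based recovery of the planted
signal nearly deterministic at the defaults. `disjoint_background`
partitions the background pool so that p_signal = 0 provably yields no
multi-set intersections at all — the degenerate case for the DAG.

What the generator does *not* emulate: correlated experiments (shared
platforms or labs), heavy-tailed set sizes, per-gene ascertainment bias, or
realistic association scores. Tests passing on these fixtures demonstrate
combinatorial correctness and recovery under the stated noise model, not
performance on real curated corpora.

All randomness flows from one integer seed through `withr::with_seed`, so
generation never perturbs the caller's RNG state and identical seeds give
byte-identical GMT output.

## Numerical and determinism choices

- All orderings are explicit: collections preserve insertion order; derived
  tables sort by the primary statistic with lexicographic (C-locale, radix)
  tie-breaks; graph exports emit nodes in a fixed order. Exporting or
  writing the same object twice is byte-identical.
- Text I/O is UTF-8 with LF newlines, written in binary mode so output is
  platform-independent.
- Degenerate inputs are contracts, not surprises: empty member lists are
  rejected at construction, the Jaccard of two empty sets is an error rather
  than NaN, a universe smaller than either tested set is a domain error, an
  ABBA query smaller than its overlap threshold is rejected, and an empty
  retrieval returns an empty table with a message (a legitimate result, not
  a failure).
- Verification problem sizes were chosen so the brute-force oracles are
  exact and fast: biclique and DAG checks on 200 random collections of ≤ 8
  sets × ≤ 20 genes; overlap tests on 100 instances with N ≤ 30 and draw
  sizes ≤ 6 so *all* C(N, n) draws can be enumerated, plus a 10⁵-draw
  Monte-Carlo agreement check within three standard errors; ranking checks
  on 200 instances of ≤ 10 sets × ≤ 30 genes; recovery on 100 seeded
  replicates at the generator defaults.

## Known limitations

- Biclique enumeration is output-sensitive but worst-case exponential (the
  concept lattice can be large for dense, highly overlapping collections);
  it is intended for the tens-of-sets scale of a curated analysis project,
  not thousands of sets at once.
- No weighted walks, no rank-based (GSEA-style) enrichment, and no
  significance model for prevalence.
- The hypergeometric test assumes exchangeable draws from the declared
  universe; a poorly chosen universe (e.g. whole genome when all sets came
  from one platform) inflates significance, and no correction for that is
  attempted beyond making the universe explicit.
- Homology conflicts (one gene in two clusters) resolve first-occurrence-
  wins at parse time with a warning; there is no probabilistic ortholog
  assignment.
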