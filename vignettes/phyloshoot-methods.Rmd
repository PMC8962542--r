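---
title: "Methods: phylogenetically partitioned search, placement and orthology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetically partitioned search, placement and orthology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the tunable parameters and why their defaults
are what they are, the numerical and design choices made where several
options were defensible, what the simulator does and does not emulate, and
the known limitations. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Database model

The unit of the database is the *homolog group*: a gene family given as
protein sequences, an MSA over exactly those genes (gap character `-` only),
and a rooted gene tree whose leaves are those genes, with integer bootstrap
supports (0–100) stored as bare internal-node labels. Gene ids must be
unique across the whole database, because search results return bare gene
ids. Group inference, alignment and tree inference are upstream concerns:
the builder consumes them, and the simulator generates them.

## Splitting oversized trees

Adding a query to an alignment and tree grows super-linearly in family size,
so families larger than `max_subtree_size` (default **2500 genes**) are
partitioned. The partition rule is a greedy root-to-tip traversal: at any
node whose clade exceeds the limit, recurse into the children; every maximal
clade at or below the limit becomes one subtree. A single leaf stranded at a
split node would otherwise become a one-gene subtree, so it is merged into
its smallest sibling subtree at the same node when the merged set still fits
— only full sibling child-clades are eligible, which keeps every member set
a connected region of the tree and therefore keeps the contraction
well-defined. The *supertree* is that contraction: the original tree with
each member set collapsed to a leaf named by subtree id, branch lengths
inherited from the contracted edges.

Each subtree is stored with one **outgroup** gene so that its tree can be
re-rooted after placement. The outgroup is the non-member leaf with the
smallest branch-length path to the root of the member clade (ties broken by
lexicographically smallest id): a close outgroup adds the least alignment
and rooting distortion. Sub-MSAs are extracted per subtree (members plus
outgroup) and columns that become all-gap are removed to keep placement
alignments compact.

## Representative selection

Per (sub)tree of *N* genes, *k* = ⌈*N*/10⌉ representatives are selected,
floored at min(20, *N*) and capped at *N*. The ceiling keeps *k* ≥ 1;
the floor guarantees that small but diverse families are still covered.
Rows are one-hot encoded per (column, residue) with gaps and `X` as
all-zero blocks — the simplest encoding for which squared Euclidean distance
counts column disagreements — and clustered with k-means (fixed seed,
10 restarts, Hartigan–Wong). Each cluster contributes the member nearest its
centroid (ties lexicographic). If clusters collapse or empty, the
farthest-from-its-centroid unselected sequence is added until *k*
representatives exist. The seed, restart count and empty-cluster policy are
recorded in the database's build-parameter record, so a build is
byte-reproducible.

## Assignment search

The builtin engine computes Smith–Waterman local alignments (BLOSUM62,
gap open 11, extend 1) of the query against the representatives. Raw scores
are converted with the standard gapped Karlin–Altschul constants
(λ = 0.267, K = 0.041):

  S′ = (λS − ln K) / ln 2,  E = m · n · 2^(−S′),

with *m* the query length and *n* the total residue count of the
representative set. Defaults: e-value cutoff **10⁻³**; a secondary
(family, subtree) is also considered when its best hit is within
**10¹⁰ ×** the overall best e-value (when the best e-value underflows to 0,
the threshold is taken from the smallest positive double, a choice the
literature leaves open); candidates are capped at 5 trees to bound placement
cost — the cap is a configurable engineering bound, not a statistical one.
The default pass requires a shared exact 4-mer between query and
representative before aligning, mimicking the heuristic first pass of
practical search engines; when nothing passes the e-value cutoff, the
sensitive retry aligns every representative. Per-tree comparison uses each
tree's *best* hit (whether all hits or best hits should enter the ambiguity
test is ambiguous in the original description; best-per-tree is implemented).
Only the dependency-free builtin engine ships; `search_config(engine=)`
rejects anything else with an actionable error.

## Placement

The query is first aligned into the candidate's MSA by global affine
alignment (open 11 / extend 1) against the per-column residue-frequency
profile, scoring a residue against a column by its expected BLOSUM62 score
under the column's residue frequencies (occupancy kept in the denominator,
so sparse columns attract gaps). Query-only insertion states are discarded:
reference columns are preserved byte-identically (the keep-length
contract), which is what lets the pre-computed tree be reused.

Placement is an exhaustive edge scan. For each edge of the rooted reference
tree the query is attached at the edge midpoint and the attachment scored by
total Fitch parsimony cost over the parsimony-informative columns of the
extended alignment (residues only; gaps and `X` are treated as missing).
The minimum-cost edge wins; ties are resolved by the edge topologically
nearest the best-hit representative's leaf, then by the lexicographically
smallest descendant label — both rules exist purely to make results
deterministic. The pendant branch length is set to the normalized p-distance
between the query row and its nearest leaf row; internal branch lengths are
never re-estimated, and the new node carries no support value. An exhaustive
scan is exact over its own (parsimony) criterion and needs no external
phylogenetic placement binary; the cost is linear in edges × informative
sites, which is cheap at the subtree sizes the splitting stage guarantees.

For split families, the placed subtree is re-rooted on its outgroup's
pendant edge, the outgroup is deleted (its degree-2 parent suppressed with
branch lengths summed), and the subtree is grafted back: each subtree-id
leaf of the supertree is textually replaced by that subtree's member tree,
the queried subtree contributing the placed version. Contracted supertree
edge lengths are restored on the grafted boundary edges, so all lengths of
the original tree are preserved wherever they were defined.

## Orthology

The species-overlap rule labels an internal node a **duplication** iff any
two of its children's species sets intersect (computed as: the children's
set sizes sum to more than their union — equivalent to a pairwise
intersection test, and the natural generalization to polytomies). Orthologs
of the query are the leaves whose LCA with the query is a speciation node.
Genes from the query's own species are therefore always paralogs
("inparalogs" are not distinguished). When the query's species is unknown,
the query is treated as its own private species, which never manufactures
duplications above it; pass `query_species` when it is known (the
leave-one-out harness does).

## The simulator and what "passing" means

`make_fixture()` generates: a Yule species tree (pure birth), rescaled so
the **mean** root-to-tip path equals `tree_height` (default 0.5
substitutions/site — enough divergence that placement is non-trivial, not so
much that alignments lose signal); duplication–loss gene trees by a
birth–death walk of gene lineages down the species tree (rates per unit
branch length; families with fewer than 2 survivors are resampled);
and sequences under a 20-state Poisson/JC-like model — per branch of length
*b*, each site substitutes with probability 1 − e^(−b) to a uniformly random
*different* residue. The per-branch transition kernel
e^(−b)·I + (1 − e^(−b))·(J − I)/19 composes in closed form, which is what
the sequence-identity oracle tests use.

Two deliberate simplifications: **no indels**, so the true MSA is the raw
sequences — alignment inference is a precomputed input to the real pipeline
too, and this isolates placement/orthology correctness from aligner quality;
and **loss-free truth for the accuracy suite** (`loss_rate = 0`), because
losses hide duplications from any species-overlap method — with μ > 0 the
method's recall necessarily drops, which is a property of the rule, not a
bug, and can be explored by setting `loss_rate` yourself. Supports are fixed
at 100 in this noiseless regime. Passing tests on these fixtures therefore
demonstrates correctness of the machinery (splitting, search, placement,
grafting, labeling, metrics) under clean signal; they do not measure
robustness to alignment error, rate heterogeneity, compositional bias or
incomplete databases, all of which real data have.

## Evaluation protocol choices

Cherry test cases are mutual-sister pairs with parent support ≥ 95 from
trees whose median internal support is ≥ 95, at most one case per tree
(highest support, lexicographic tie-break); the lexicographically smaller
gene is the query. Leave-one-out removes the query gene from sequences, MSA,
tree (suppressing its degree-2 parent) and re-selects representatives before
searching. The closest-homolog ranking uses branch-length path distance in
the result tree, ties lexicographic (both in predicted and expected lists,
for determinism). Precision@k is, by default, the literal set-overlap
reading — |top-k(predicted) ∩ top-k(expected)| / min(k, available) — with
classic AP@k available via `map_at_k(method = "average_precision")`.
Normalized Robinson–Foulds distances are computed on unrooted trees
(symmetric difference of non-trivial bipartitions over 2(n−3)); rooted RF
would count the root placement, which placement deliberately does not
re-estimate. The best-hit baseline ranks all database sequences by builtin
e-value, standing in for a BLAST-style search without shelling out.

## Problem sizes

The acceptance-level checks run, as the package's own choice of desk-scale
study conditions: one simulated family of >2500 genes (60-column sequences
— splitting and supertree contraction are sequence-content-free, so short
rows suffice) for the splitting bound; a 200-gene single-copy family for the
representative-count rule; 50 loss-free families (~700 genes, 300 columns,
12 species, duplication rate 0.3) for leave-one-out, MAP@k, ortholog
accuracy and re-placement RF; 10 high-duplication families forced through
splitting (`max_subtree_size = 8`) for the subtree-vs-unsplit comparison;
1000 random trees of up to 500 leaves for the orthology oracle; and repeated
simulate+build runs for byte-level determinism.

## Degenerate inputs and numeric details

Missing Newick branch lengths default to 0; negative lengths are rejected.
Queries shorter than 10 residues are rejected (too short for the statistics
to mean anything). An alignment with no parsimony-informative columns makes
every attachment cost 0 and the tie rules decide. A two-leaf subtree rooted
on its outgroup degenerates to a single-leaf member tree, which grafting
handles as a bare leaf. Empty predicted and truth ortholog sets score
P = R = F = 1 by convention (the prediction is exactly right); an empty
prediction against non-empty truth scores 0. All trees are ape `phylo`
objects; supports round-trip as character node labels.

## Known limitations

* The builtin placer optimizes parsimony, not likelihood; on very divergent
  or rate-heterogeneous families a likelihood placer can disagree.
* E-values use fixed Karlin–Altschul constants rather than per-database
  estimation; they are calibrated for ranking and thresholding, not for
  exact tail probabilities.
* Species-overlap orthology cannot see duplications whose evidence was
  erased by loss.
* The supertree graft preserves the original inter-subtree topology by
  construction, so errors in the original tree are inherited, never
  corrected.
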