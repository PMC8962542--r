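# phyloshoot

Phylogenetic sequence search against partitioned gene-tree databases, with
species-overlap ortholog inference and a built-in evaluation harness.

## The problem

A conventional protein similarity search (BLAST-style) returns a ranked list
of hits, leaving the user to align them and infer a tree before orthology can
be read off. `phyloshoot` takes the opposite route: the phylogenetic
relationships between all database sequences are computed ahead of time, so a
search only has to (i) assign the query to its gene family and (ii) place it
on that family's pre-computed tree. The output is not a hit list but a full
gene tree containing the query, with every other gene labelled as an ortholog
or paralog of it.

The package is aimed at anyone who maintains a set of homolog groups — each a
protein FASTA, a multiple sequence alignment (MSA), and a rooted gene tree
with bootstrap supports — and wants a fast, reproducible "where does this new
sequence belong, and what are its orthologs?" tool, plus the machinery to
benchmark that tool's accuracy on simulated data.

## How it works

**Database build** (`build_database()`):

* Gene trees larger than `max_subtree_size` (default *2500* genes) are split
  by a greedy root-to-tip traversal into subtrees of at most that size; each
  subtree is anchored by one **outgroup** gene (the branch-length-nearest
  leaf outside the subtree) and the subtrees are linked by a **supertree**
  (the original tree with each subtree contracted to a leaf).
* For every (sub)tree of *N* genes, *k* = ⌈*N*/10⌉ representative sequences
  (never fewer than min(20, *N*)) are chosen by k-means clustering of the
  one-hot-encoded MSA rows; the member closest to each centroid becomes a
  representative. These representatives form the search profile.

**Search** (`shoot_search()`):

* The query is aligned against every representative by Smith–Waterman local
  alignment (BLOSUM62, gap open 11 / extend 1). Bit scores follow the
  Karlin–Altschul form *S′* = (λ*S* − ln *K*)/ln 2 with the standard gapped
  constants λ = 0.267, *K* = 0.041, and *E* = *mn*·2^(−*S′*). Hits with
  *E* > 10⁻³ are discarded; if nothing survives, a sensitive retry pass
  aligns every representative without the heuristic 4-mer prefilter.
* The best hit assigns the query to a (sub)tree; any other tree whose best
  hit is within 10¹⁰ × the best e-value is also considered.
* For each candidate, the query is aligned into the pre-computed MSA
  (profile alignment that never alters the reference columns), placed on the
  tree by an exhaustive minimum-parsimony edge scan, and — for split
  families — the subtree is rooted on its outgroup, the outgroup removed,
  and the subtree grafted back through the supertree.
* Orthologs are inferred by the **species-overlap** rule: an internal node
  is a duplication iff the species sets of its children intersect; a gene is
  an ortholog of the query iff their last common ancestor is a speciation
  node.

**Evaluation** (`run_benchmark()` and friends) re-implements the standard
protocols at desk scale: leave-one-out "cherry" tests (high-support
mutual-sister pairs, pruned from the database and re-searched), MAP@k of the
predicted closest-homolog ranking, ortholog precision/recall/F-score against
simulated truth, and normalized Robinson–Foulds distances between original
and re-placed trees. A duplication–loss gene-family simulator
(`make_fixture()`) generates complete build inputs with known ground truth,
so everything is testable without downloads.

## Worked example

```r
library(phyloshoot)

cfg <- sim_config(seed = 5L, n_species = 8L, n_families = 4L,
                  seq_len = 120L, dup_rate = 0.3)
make_fixture(cfg, "demo-fixture")
groups <- read_groups_dir("demo-fixture")
map    <- read_species_map("demo-fixture/species_map.tsv")
db     <- build_database(groups, map, build_config(seed = 3L))
db
#> phyloshoot database: 4 families, 38 genes, 38 profile representatives
#>   split families: 0 | species: 8

query <- gsub("-", "", db$families$fam001$group$seqs[["fam001_sp8_1"]])
res <- shoot_search(query, db, query_id = "my_query", query_species = "sp8")
res
#> phyloshoot search for my_query - ok
#> Placement of my_query in family fam001 (subtree fam001_s1,
#>   e-value 2.59e-77, parsimony score 189)
#>   tree: 9 leaves | 7 orthologs, 1 paralogs

head(res$results[[1]]$orthologs, 4)
#>        gene_id species_id relation  lca_event
#> 7 fam001_sp1_1        sp1 ortholog speciation
#> 4 fam001_sp2_1        sp2 ortholog speciation
#> 6 fam001_sp3_1        sp3 ortholog speciation
#> 5 fam001_sp4_1        sp4 ortholog speciation

closest_ranking(res$results[[1]]$tree, "my_query")[1:3]
#> [1] "fam001_sp8_1" "fam001_sp6_1" "fam001_sp2_1"
```

The query (a copy of gene `fam001_sp8_1`) lands in the right family with a
highly significant e-value, its nearest leaf by branch-length distance is the
gene it was copied from, and the ortholog table labels one same-species
co-member as a paralog (same-species pairs always coalesce at a duplication
node) and the other species' genes as orthologs.

The same pipeline is available from a shell via the installed script
(`inst/cli/phyloshoot` once the package is installed):

```sh
phyloshoot simulate --out fixture --seed 17
phyloshoot build --groups fixture --species-map fixture/species_map.tsv --out db
phyloshoot search --db db --query query.fa --out results/
```

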