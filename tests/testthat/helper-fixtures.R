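# Shared fixtures and independent oracles, all built in code.

random_aa <- function(n, len, seed) {
  with_seed <- get("with_seed", asNamespace("phyloshoot"))
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
                   replace = TRUE), collapse = "")
    }, character(1))
  })
}

# caterpillar family with aligned gap-free sequences (toy builder input)
make_toy_group <- function(id, n, len = 60L, seed = 1L) {
  tips <- paste0(id, "_g", seq_len(n))
  nwk <- paste0(tips[n], ":0.1")
  for (i in (n - 1):1) {
    nwk <- paste0("(", tips[i], ":0.1,", nwk, ":0.1)90")
  }
  nwk <- paste0(nwk, ";")
  seqs <- stats::setNames(random_aa(n, len, seed), tips)
  homolog_group(id, seqs = seqs, msa = seqs, tree = parse_newick(nwk))
}

toy_species_map <- function(groups) {
  genes <- unlist(lapply(groups, function(g) names(g$seqs)), use.names = FALSE)
  stats::setNames(rep_len(paste0("sp", 1:5), length(genes)), genes)
}

# small simulated database shared across tests (built once per run)
.shared <- new.env()
shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    dir <- file.path(tempdir(), "phyloshoot-shared-fixture")
    cfg <- sim_config(seed = 101L, n_species = 8L, n_families = 8L,
                      seq_len = 150L, dup_rate = 0.3, loss_rate = 0)
    fx <- make_fixture(cfg, dir, force = TRUE)
    groups <- read_groups_dir(dir)
    map <- read_species_map(file.path(dir, "species_map.tsv"))
    db <- build_database(groups, map, build_config(seed = 7L))
    .shared$fx <- list(cfg = cfg, truth = fx, groups = groups, map = map,
                       db = db, dir = dir)
  }
  .shared$fx
}

# oracle: every member set is a union of complete child clades of its MRCA
expect_valid_partition <- function(tree, sets) {
  all_tips <- tree$tip.label
  members <- unlist(sets, use.names = FALSE)
  expect_setequal(members, all_tips)
  expect_equal(anyDuplicated(members), 0L)
  ns <- asNamespace("phyloshoot")
  tipsets <- get("clade_tip_sets", ns)(tree)
  children <- get("tree_children", ns)(tree)
  for (s in sets) {
    if (length(s) == length(all_tips)) next
    m <- get("mrca_of_tips", ns)(tree, s)
    if (length(s) == 1L) next
    ok <- vapply(children[[m]], function(c_node) {
      ts <- tipsets[[c_node]]
      all(ts %in% s) || !any(ts %in% s)
    }, logical(1))
    expect_true(all(ok),
                label = paste("set is a union of complete child clades of",
                              "its MRCA"))
    covered <- unlist(tipsets[children[[m]][vapply(children[[m]],
      function(c_node) all(tipsets[[c_node]] %in% s), logical(1))]])
    expect_setequal(covered, s)
  }
}

# oracle: splits of the original tree induced on subtree ids equal the
# supertree's splits (independent of the contraction construction)
induced_supertree_splits <- function(tree, sets, ids) {
  gene_to_id <- stats::setNames(rep(ids, lengths(sets)),
                                unlist(sets, use.names = FALSE))
  ns <- asNamespace("phyloshoot")
  tipsets <- get("clade_tip_sets", ns)(tree)
  n_tip <- ape::Ntip(tree)
  ref <- sort(ids)[1L]
  out <- character(0)
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    inside <- unique(gene_to_id[tipsets[[node]]])
    # a split of subtree ids is induced iff no id straddles the edge
    outside <- unique(gene_to_id[setdiff(tree$tip.label, tipsets[[node]])])
    if (length(intersect(inside, outside))) next
    side <- if (ref %in% inside) outside else inside
    if (length(side) <= 1L || length(side) >= length(ids) - 1L) next
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

expect_supertree_consistent <- function(tree, split) {
  sets <- lapply(split$subtrees, `[[`, "members")
  ids <- vapply(split$subtrees, `[[`, character(1), "id")
  st <- split$supertree
  expect_setequal(st$tip.label, ids)
  if (length(ids) >= 4L) {
    ns <- asNamespace("phyloshoot")
    expect_setequal(get("tree_bipartitions", ns)(st),
                    induced_supertree_splits(tree, sets, ids))
  }
}

# brute-force species-overlap labels: direct pairwise intersection of the
# children's descendant species sets at every internal node
brute_force_events <- function(tree, species_map) {
  ns <- asNamespace("phyloshoot")
  tipsets <- get("clade_tip_sets", ns)(tree)
  children <- get("tree_children", ns)(tree)
  n_tip <- ape::Ntip(tree)
  vapply((n_tip + 1L):(n_tip + tree$Nnode), function(node) {
    kids <- children[[node]]
    sets <- lapply(kids, function(k) unique(species_map[tipsets[[k]]]))
    dup <- FALSE
    if (length(kids) >= 2L) {
      for (i in seq_along(kids)) {
        for (j in seq_along(kids)) {
          if (i < j && length(intersect(sets[[i]], sets[[j]]))) dup <- TRUE
        }
      }
    }
    if (dup) "duplication" else "speciation"
  }, character(1))
}

# independent Fitch cost over all columns of a gap-free alignment
phangorn_parsimony <- function(tree, rows) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  dat <- phangorn::phyDat(mat, type = "AA")
  phangorn::parsimony(tree, dat)
}

# random rooted tree with random species labels
random_labeled_tree <- function(n, n_species, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = TRUE)
  tree$node.label <- NULL
  map <- stats::setNames(paste0("s", sample.int(n_species, n, replace = TRUE)),
                         tree$tip.label)
  list(tree = tree, map = map)
}
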