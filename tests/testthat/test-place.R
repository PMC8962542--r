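test_that("MSA extension is exact on profile matches and keeps length", {
  msa <- stats::setNames(random_aa(4, 50, seed = 6L), paste0("g", 1:4))
  ext <- add_to_msa(msa[["g2"]], msa, "q")
  expect_identical(ext$query_row, unname(msa[["g2"]]))
  expect_identical(ext$ref, msa)

  # query missing the first residue aligns with a leading gap
  trimmed <- substring(msa[["g3"]], 2)
  ext2 <- add_to_msa(trimmed, msa, "q")
  expect_identical(ext2$query_row,
                   paste0("-", substring(msa[["g3"]], 2)))
  expect_equal(nchar(ext2$query_row), nchar(msa[[1]]))
  expect_error(add_to_msa("MKV", msa), "shorter than 10")
})

test_that("a query identical to a leaf is placed as its sister", {
  fx <- shared_fixture()
  fam <- fx$db$families[[1]]
  tree <- fam$group$tree
  x <- tree$tip.label[2]
  ext <- add_to_msa(gsub("-", "", fam$group$msa[[x]]), fam$group$msa, "q")
  placed <- place_in_tree(ext, tree)
  out <- placed$tree
  qi <- match("q", out$tip.label)
  parent <- out$edge[out$edge[, 2] == qi, 1]
  siblings <- out$edge[out$edge[, 1] == parent, 2]
  sib_tips <- out$tip.label[setdiff(siblings, qi)]
  expect_identical(sib_tips, x)
})

test_that("equal-cost attachments resolve deterministically", {
  # identical sequences everywhere: no informative columns, full tie
  seqs <- stats::setNames(rep(random_aa(1, 40, seed = 2L), 4),
                          c("a", "b", "c", "d"))
  tree <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  ext <- add_to_msa(seqs[["a"]], seqs, "q")
  p1 <- place_in_tree(ext, tree)
  p2 <- place_in_tree(ext, tree)
  expect_identical(write_newick(p1$tree), write_newick(p2$tree))
  ns <- asNamespace("phyloshoot")
  lab <- get("min_tip_labels", ns)(tree)
  expect_identical(lab[p1$edge_child], "a")
  # with a tie-break anchor, the attachment tracks the anchor's leaf
  p3 <- place_in_tree(ext, tree, best_rep = "d")
  expect_identical(get("min_tip_labels", ns)(tree)[p3$edge_child], "d")
})

test_that("parsimony scores agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  ns <- asNamespace("phyloshoot")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:12, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    tree$node.label <- NULL
    rows <- stats::setNames(random_aa(n, 40, seed = seed + 50),
                            tree$tip.label)
    mat <- do.call(rbind, strsplit(unname(rows), ""))
    masks <- apply(mat, 1, get("char_masks", ns))  # 40 x n
    n_all <- n + tree$Nnode
    full <- matrix(bitwShiftL(1L, 20L) - 1L, 40, n_all)
    full[, seq_len(n)] <- masks
    storage.mode(full) <- "integer"
    cost <- get(".fitch_cost", ns)(get("tree_children", ns)(tree),
                                   get("postorder_nodes", ns)(tree), full)
    expect_equal(cost, phangorn_parsimony(tree, rows))
  }
})

test_that("pruned-leaf re-placement restores the original topology", {
  fx <- shared_fixture()
  checked <- 0L
  for (fam in fx$db$families) {
    tree <- fam$group$tree
    if (ape::Ntip(tree) < 6L) next
    leaf <- sort(tree$tip.label)[3]
    pruned <- ape::drop.tip(tree, leaf, collapse.singles = TRUE)
    msa <- extract_sub_msa(fam$group$msa, pruned$tip.label)
    ext <- add_to_msa(gsub("-", "", fam$group$seqs[[leaf]]), msa, leaf)
    placed <- place_in_tree(ext, pruned)
    expect_equal(normalized_rf(tree, placed$tree), 0)
    checked <- checked + 1L
    if (checked >= 3L) break
  }
  expect_gte(checked, 2L)
})

test_that("outgroup rooting fixes the root bipartition then removes it", {
  tree <- parse_newick("((a:1,b:1):1,(c:1,OUT:1):1);")
  out <- root_on_outgroup(tree, "OUT")
  expect_setequal(out$tip.label, c("a", "b", "c"))
  ns <- asNamespace("phyloshoot")
  root_kids <- get("tree_children", ns)(out)[[get("tree_root", ns)(out)]]
  kid_sets <- lapply(get("clade_tip_sets", ns)(out)[root_kids], sort)
  expect_true(any(vapply(kid_sets, identical, logical(1), y = c("a", "b"))))
  expect_true(any(vapply(kid_sets, identical, logical(1), y = "c")))

  small <- parse_newick("(a:1,OUT:2);")
  out2 <- root_on_outgroup(small, "OUT")
  expect_identical(out2$tip.label, "a")
  expect_error(root_on_outgroup(tree, "nope"), "absent")
})

test_that("grafting restores the full family and matches the supertree", {
  g <- make_toy_group("cat", 12, len = 80L, seed = 13L)
  split <- split_large_tree(g, build_config(max_subtree_size = 5L))
  expect_true(split$is_split)
  s <- split$subtrees[[1]]
  query_seq <- gsub("-", "", g$seqs[[s$members[1]]])
  ext <- add_to_msa(query_seq, s$msa, "q")
  placed <- place_in_tree(ext, s$tree)
  rooted <- root_on_outgroup(placed$tree, s$outgroup)
  full <- graft(rooted, split, s$id)
  expect_setequal(full$tip.label, c(g$tree$tip.label, "q"))
  expect_equal(sum(full$tip.label == "q"), 1L)
  sets <- lapply(split$subtrees, `[[`, "members")
  sets[[1]] <- c(sets[[1]], "q")
  ids <- names(split$subtrees)
  if (length(ids) >= 4L) {
    expect_setequal(induced_supertree_splits(full, sets, ids),
                    get("tree_bipartitions",
                        asNamespace("phyloshoot"))(split$supertree))
  }
  expect_error(graft(rooted, split, "bogus"), "unknown subtree")
  # unsplit families graft as the identity
  unsplit <- split_large_tree(g, build_config())
  expect_identical(graft(rooted, unsplit, names(unsplit$subtrees)[1]),
                   rooted)
})

test_that("full search conserves leaves and flags missing homologs", {
  fx <- shared_fixture()
  fam <- fx$db$families[[2]]
  gene <- names(fam$group$seqs)[1]
  res <- shoot_search(gsub("-", "", fam$group$seqs[[gene]]), fx$db,
                      query_id = gene)
  expect_identical(res$status, "ok")
  expect_identical(res$query_id, paste0("query_", gene))
  r <- res$results[[1]]
  expect_setequal(r$tree$tip.label,
                  c(names(fam$group$seqs), res$query_id))
  expect_identical(closest_ranking(r$tree, res$query_id)[1], gene)

  none <- shoot_search(paste(rep("W", 40), collapse = ""), fx$db)
  expect_identical(none$status, "no homologs found")
  expect_length(none$results, 0L)
})
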