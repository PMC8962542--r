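test_that("cherry selection applies median, support and one-per-tree rules", {
  trees <- list(
    low = parse_newick("((a:1,b:1)97:1,(c:1,d:1)90:1);"),
    good = parse_newick("((a:1,b:1)97:1,(c:1,d:1)96:1);"))
  cases <- find_cherries(trees, min_support = 95, min_median_support = 95)
  expect_equal(nrow(cases), 1L)
  expect_identical(cases$family, "good")
  expect_identical(cases$query, "a")
  expect_identical(cases$expected, "b")
  expect_equal(cases$support, 97)
})

test_that("every selected cherry is a mutual-sister pair", {
  fx <- shared_fixture()
  trees <- lapply(fx$db$families, function(f) f$group$tree)
  cases <- find_cherries(trees)
  expect_lte(nrow(cases), length(trees))
  ns <- asNamespace("phyloshoot")
  for (i in seq_len(nrow(cases))) {
    tree <- trees[[cases$family[i]]]
    ch <- get("tree_children", ns)(tree)
    qi <- match(cases$query[i], tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == qi, 1]
    kids <- ch[[parent]]
    expect_length(kids, 2L)
    expect_setequal(tree$tip.label[kids],
                    c(cases$query[i], cases$expected[i]))
  }
})

test_that("closest ranking orders by path length with lexicographic ties", {
  tree <- parse_newick("((q:0.1,x:0.1):0.2,(y:0.1,z:0.1):0.1);")
  expect_identical(closest_ranking(tree, "q")[1], "x")
  star <- parse_newick("(q:1,b:1,a:1,c:1);")
  expect_identical(closest_ranking(star, "q"), c("a", "b", "c"))
  # oracle: patristic distance matrix
  for (seed in 1:5) {
    set.seed(seed)
    tree <- ape::rtree(12, rooted = TRUE)
    d <- ape::cophenetic.phylo(tree)["t1", ]
    d <- d[names(d) != "t1"]
    expected <- names(d)[order(d, names(d))]
    expect_identical(closest_ranking(tree, "t1"), expected)
  }
})

test_that("precision-at-k matches direct set enumeration", {
  res <- map_at_k(c("a", "b", "c", "d"), c("a", "b", "c", "d"), k_max = 4)
  expect_equal(res$map, rep(1, 4))
  res2 <- map_at_k(c("a", "b", "c", "d"), c("a", "c", "b", "d"), k_max = 4)
  expect_equal(unname(res2$precision[1, ]), c(1, 0.5, 1, 1))
  res3 <- map_at_k(c("a", "b"), c("x", "y"), k_max = 2)
  expect_equal(unname(res3$precision[1, ]), c(0, 0))
  # random rankings vs an inline enumeration oracle
  for (seed in 1:5) {
    set.seed(seed)
    genes <- paste0("g", 1:20)
    p <- sample(genes); e <- sample(genes)
    got <- map_at_k(p, e, k_max = 25)$precision[1, ]
    oracle <- vapply(1:25, function(k) {
      kk <- min(k, 20)
      length(intersect(p[seq_len(kk)], e[seq_len(kk)])) / kk
    }, numeric(1))
    expect_equal(unname(got), oracle)
  }
  expect_error(map_at_k(c("a", "a"), c("a", "b"), 2), "duplicate")
  expect_error(map_at_k("a", "a", 0), "k_max")
})

test_that("classic average precision matches rank-by-rank enumeration", {
  p <- c("a", "x", "b", "c")
  e <- c("a", "b", "c", "y")
  got <- map_at_k(p, e, k_max = 4, method = "average_precision")
  # k = 4: relevant = {a,b,c}; hits at ranks 1, 3, 4 with running
  # precisions 1, 2/3, 3/4; AP@4 = (1 + 2/3 + 3/4) / 4
  expect_equal(got$precision[1, 4], (1 + 2 / 3 + 3 / 4) / 4)
  expect_equal(got$precision[1, 1], 1)
  identical_case <- map_at_k(e, e, k_max = 4,
                             method = "average_precision")
  expect_equal(unname(identical_case$precision[1, ]), rep(1, 4))
})

test_that("ortholog precision/recall/F handles all degenerate cases", {
  r <- ortholog_prf(c("x", "y"), c("x", "z"))
  expect_equal(c(r$precision, r$recall, r$f), c(0.5, 0.5, 0.5))
  r2 <- ortholog_prf(c("x", "y"), c("x", "y"))
  expect_equal(c(r2$precision, r2$recall, r2$f), c(1, 1, 1))
  r3 <- ortholog_prf(character(0), "x")
  expect_equal(c(r3$precision, r3$recall, r3$f), c(0, 0, 0))
  r4 <- ortholog_prf(character(0), character(0))
  expect_equal(c(r4$precision, r4$recall, r4$f), c(1, 1, 1))
})

test_that("normalized RF matches bipartition enumeration and phangorn", {
  t1 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- parse_newick("((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(normalized_rf(t1, t1), 0)
  expect_equal(normalized_rf(t1, t2), 1)
  expect_error(normalized_rf(t1, parse_newick("((a:1,b:1):1,(c:1,e:1):1);")),
               "leaf sets differ")
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    set.seed(seed)
    x <- ape::rtree(20, rooted = TRUE)
    y <- ape::rtree(20, rooted = TRUE)
    expect_equal(normalized_rf(x, y),
                 phangorn::RF.dist(ape::unroot(x), ape::unroot(y),
                                   normalize = TRUE))
  }
})

test_that("normalized RF behaves as a metric on random triples", {
  for (seed in 1:5) {
    set.seed(seed)
    trees <- replicate(3, ape::rtree(10, rooted = TRUE), simplify = FALSE)
    d12 <- normalized_rf(trees[[1]], trees[[2]])
    d21 <- normalized_rf(trees[[2]], trees[[1]])
    d13 <- normalized_rf(trees[[1]], trees[[3]])
    d23 <- normalized_rf(trees[[2]], trees[[3]])
    expect_equal(d12, d21)
    expect_equal(normalized_rf(trees[[1]], trees[[1]]), 0)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_gte(d12, 0); expect_lte(d12, 1)
  }
})

test_that("leave-one-out fully removes the query gene from the database", {
  fx <- shared_fixture()
  cases <- find_cherries(lapply(fx$db$families, function(f) f$group$tree))
  skip_if(nrow(cases) == 0L)
  case <- cases[1, ]
  pruned <- get("prune_gene_from_db",
                asNamespace("phyloshoot"))(fx$db, case$family, case$query)
  f <- pruned$families[[case$family]]
  expect_false(case$query %in% names(f$group$seqs))
  expect_false(case$query %in% names(f$group$msa))
  expect_false(case$query %in% f$group$tree$tip.label)
  expect_false(case$query %in% pruned$profiles$rep_id)
  expect_false(case$query %in% names(pruned$species_map))
  loo <- leave_one_out(fx$db, case, "shoot")
  expect_false(isTRUE(loo$skipped))
  expect_type(loo$hit, "logical")
  bh <- leave_one_out(fx$db, case, "best_hit")
  expect_type(bh$hit, "logical")
})
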