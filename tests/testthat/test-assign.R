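test_that("a database sequence queried against itself is the top hit", {
  reps <- stats::setNames(random_aa(6, 80, seed = 2L), paste0("r", 1:6))
  hits <- builtin_search(reps[["r3"]], reps)
  expect_identical(hits$rep_id[1], "r3")
  expect_lt(hits$evalue[1], 1e-3)
})

test_that("self-match e-value follows the Karlin-Altschul formula", {
  query <- random_aa(1, 50, seed = 8L)
  others <- stats::setNames(random_aa(3, 70, seed = 9L), paste0("u", 1:3))
  reps <- c(stats::setNames(query, "self"), others)
  hits <- builtin_search(query, reps)
  expect_identical(hits$rep_id[1], "self")
  # independent oracle: the local self-alignment score is the sum of the
  # BLOSUM62 diagonal over the query's residues
  B <- get("blosum62", asNamespace("phyloshoot"))()
  qchars <- strsplit(query, "")[[1]]
  S <- sum(B[cbind(qchars, qchars)])
  bits <- (0.267 * S - log(0.041)) / log(2)
  expected_e <- 50 * sum(nchar(reps)) * 2^(-bits)
  expect_equal(hits$evalue[1], expected_e, tolerance = 1e-9)
  expect_lt(hits$evalue[1], 1e-3)
})

test_that("identical alignments are ordered by lexicographic id", {
  seqs <- random_aa(1, 60, seed = 4L)
  reps <- stats::setNames(c(seqs, seqs, random_aa(1, 60, seed = 5L)),
                          c("zeta", "alpha", "other"))
  hits <- builtin_search(seqs, reps)
  expect_identical(hits$rep_id[1:2], c("alpha", "zeta"))
})

test_that("tree assignment applies cutoff and the ambiguity-ratio rule", {
  hits <- data.frame(
    rep_id = c("a1", "b1", "c1"),
    family = c("A", "B", "C"), subtree = c("A_s1", "B_s1", "C_s1"),
    evalue = c(1e-50, 1e-45, 1e-30), bitscore = c(200, 180, 120),
    score = c(500, 450, 300), stringsAsFactors = FALSE)
  cands <- assign_trees(hits, search_config())
  expect_identical(cands$family, c("A", "B"))

  single <- hits[2, , drop = FALSE]
  single$evalue <- 1e-5
  expect_identical(assign_trees(single, search_config())$family, "B")

  weak <- hits
  weak$evalue <- c(0.01, 0.5, 1)
  expect_equal(nrow(assign_trees(weak, search_config())), 0L)
  expect_equal(nrow(assign_trees(hits[0, ], search_config())), 0L)
})

test_that("candidate ordering is deterministic and a subset of input", {
  fx <- shared_fixture()
  reps <- get("db_representatives", asNamespace("phyloshoot"))(fx$db)
  for (gene in names(reps)[c(1, 5, 9)]) {
    hits <- builtin_search(reps[[gene]], reps, fx$db$profiles)
    cands <- assign_trees(hits, search_config())
    expect_true(all(cands$family %in% hits$family))
    expect_false(is.unsorted(cands$evalue))
  }
})

test_that("self-queries always assign the true family across the fixture", {
  fx <- shared_fixture()
  for (fam in names(fx$db$families)) {
    seqs <- fx$db$families[[fam]]$group$seqs
    for (gene in names(seqs)[seq_len(min(3, length(seqs)))]) {
      cands <- search_with_retry(seqs[[gene]], fx$db)
      expect_identical(cands$family[1], fam)
    }
  }
})

test_that("the sensitive retry pass recovers prefilter-blind homologs", {
  base <- random_aa(1, 90, seed = 14L)
  reps <- c(stats::setNames(base, "target"),
            stats::setNames(random_aa(2, 90, seed = 15L), c("u1", "u2")))
  # mutate every 3rd residue: no shared 4-mer survives, similarity does
  v <- strsplit(base, "")[[1]]
  idx <- seq(1, length(v), by = 3)
  v[idx] <- ifelse(v[idx] == "A", "G", "A")
  query <- paste(v, collapse = "")
  stopifnot(!any(get("kmer_set", asNamespace("phyloshoot"))(query) %in%
                   get("kmer_set", asNamespace("phyloshoot"))(base)))
  expect_equal(nrow(builtin_search(query, reps)), 0L)
  hits <- builtin_search(query, reps, sensitive = TRUE)
  expect_identical(hits$rep_id[1], "target")

  groups <- list(make_toy_group("famZ", 4, len = 90L, seed = 14L))
  groups[[1]]$seqs["famZ_g1"] <- base
  groups[[1]]$msa["famZ_g1"] <- base
  db <- build_database(groups, toy_species_map(groups))
  cands <- search_with_retry(query, db)
  expect_gt(nrow(cands), 0L)
  expect_true(attr(cands, "sensitive_pass"))
})

test_that("unrelated short queries find no homologs in either pass", {
  reps <- stats::setNames(random_aa(5, 200, seed = 21L), paste0("r", 1:5))
  query <- random_aa(1, 30, seed = 99L)
  strict <- builtin_search(query, reps, sensitive = TRUE)
  expect_true(all(strict$evalue > 1e-3))
  expect_equal(nrow(assign_trees(strict, search_config())), 0L)
})

test_that("growing the database rescales e-values but keeps the ranking", {
  reps <- stats::setNames(random_aa(4, 80, seed = 31L), paste0("r", 1:4))
  query <- reps[["r2"]]
  h1 <- builtin_search(query, reps, sensitive = TRUE)
  bigger <- c(reps, stats::setNames(random_aa(3, 120, seed = 32L),
                                    paste0("pad", 1:3)))
  h2 <- builtin_search(query, bigger, sensitive = TRUE)
  shared <- intersect(h2$rep_id, h1$rep_id)
  expect_identical(h2$rep_id[h2$rep_id %in% shared], h1$rep_id)
  expect_true(all(h2$evalue[match(h1$rep_id, h2$rep_id)] >= h1$evalue))
})

test_that("query validation rejects malformed input", {
  reps <- stats::setNames(random_aa(2, 50, seed = 1L), c("a", "b"))
  expect_error(builtin_search("", reps), "empty query")
  expect_error(builtin_search("MKVLL", reps), "shorter than 10")
  expect_error(builtin_search("MKVLLBZJ*!MKVLL", reps), "amino-acid")
})
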