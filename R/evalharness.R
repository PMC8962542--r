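# Evaluation protocols at desk scale: leave-one-out cherry tests, MAP@k,
# ortholog precision/recall/F-score, and normalized Robinson-Foulds
# placement accuracy.

#' Find high-support cherry test cases
#'
#' Only trees whose median internal-node support is at least
#' `min_median_support` are considered; within each, cherries (mutual-sister
#' leaf pairs) whose parent support is at least `min_support` qualify. At
#' most one case is kept per tree (highest support, ties by the
#' lexicographically smallest gene pair); the lexicographically smaller gene
#' is designated the query, the other the expected closest gene.
#'
#' @param trees Named list of \code{phylo} objects (names are family ids).
#' @param min_support,min_median_support Support thresholds (0-100).
#' @return Data frame with columns `family`, `query`, `expected`, `support`.
#' @export
find_cherries <- function(trees, min_support = 95, min_median_support = 95) {
  rows <- list()
  for (fam in names(trees)) {
    tree <- trees[[fam]]
    sup <- tree_supports(tree)
    if (all(is.na(sup))) next
    if (stats::median(sup, na.rm = TRUE) < min_median_support) next
    ch <- tree_children(tree)
    n_tip <- ape::Ntip(tree)
    best <- NULL
    for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
      kids <- ch[[node]]
      if (length(kids) != 2L || any(kids > n_tip)) next
      s <- sup[node - n_tip]
      if (is.na(s) || s < min_support) next
      pair <- sort(tree$tip.label[kids])
      cand <- list(pair = pair, support = s)
      if (is.null(best) || s > best$support ||
          (s == best$support &&
           paste(pair, collapse = "\r") < paste(best$pair, collapse = "\r"))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[fam]] <- data.frame(family = fam, query = best$pair[1L],
                                expected = best$pair[2L],
                                support = best$support,
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(family = character(0), query = character(0),
                      expected = character(0), support = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# rebuild one family of the database with a gene removed (sequences, MSA
# row, tree leaf, and representatives re-selected)
prune_gene_from_db <- function(db, family, gene) {
  f <- db$families[[family]]
  if (is.null(f)) stop("unknown family ", family)
  keep <- setdiff(names(f$group$seqs), gene)
  if (length(keep) < 3L) stop("family ", family, " too small after pruning")
  cfg <- build_config(db$params$max_subtree_size, db$params$rep_divisor,
                      db$params$rep_floor, db$params$seed)
  group <- homolog_group(family,
                         seqs = f$group$seqs[keep],
                         msa = extract_sub_msa(f$group$msa, keep),
                         tree = ape::drop.tip(f$group$tree, gene,
                                              collapse.singles = TRUE))
  split <- split_large_tree(group, cfg)
  profiles <- db$profiles[db$profiles$family != family, , drop = FALSE]
  for (s in split$subtrees) {
    reps <- select_representatives(extract_sub_msa(group$msa, s$members),
                                   cfg)
    profiles <- rbind(profiles,
                      data.frame(rep_id = reps, family = family,
                                 subtree = s$id, stringsAsFactors = FALSE))
  }
  db$families[[family]] <- list(group = group, split = split)
  db$profiles <- profiles
  db$species_map <- db$species_map[names(db$species_map) != gene]
  db$path <- NULL
  db
}

#' Branch-length ranking of a placed query's closest homologs
#'
#' All non-query leaves sorted by ascending path (branch-length) distance to
#' the query leaf; ties broken lexicographically.
#'
#' @param tree \code{phylo} containing the query leaf.
#' @param query_id Query leaf label.
#' @return Character vector of gene ids, closest first.
#' @export
closest_ranking <- function(tree, query_id) {
  q <- match(query_id, tree$tip.label)
  if (is.na(q)) stop("query leaf ", query_id, " absent from the tree")
  d <- node_dists_from(tree, q)[seq_len(ape::Ntip(tree))]
  ids <- tree$tip.label
  ord <- order(d, ids)
  setdiff(ids[ord], query_id)
}

#' Leave-one-out test of a single cherry case
#'
#' The query gene is removed from its family (sequences, MSA row, tree leaf
#' with its degree-2 parent suppressed, and representatives re-selected),
#' the query sequence is searched against the pruned database, and the case
#' is a hit iff the top-ranked gene equals the expected closest gene.
#'
#' @param db A `shoot_db` containing the case's family.
#' @param case One row of [find_cherries()] output.
#' @param method `"shoot"` (full placement pipeline, ranking by branch-length
#'   distance in the result tree) or `"best_hit"` (profile-search e-value
#'   ranking over all database sequences, the BLAST-like baseline).
#' @param cfg A [search_config()].
#' @return List with `hit`, `top`, `ranking`, and for the placement method
#'   the `result` tree; `skipped = TRUE` (with `reason`) when the family is
#'   too small.
#' @export
leave_one_out <- function(db, case, method = c("shoot", "best_hit"),
                          cfg = search_config()) {
  method <- match.arg(method)
  fam <- case$family
  gene <- case$query
  f <- db$families[[fam]]
  if (length(f$group$seqs) - 1L < 3L) {
    return(list(skipped = TRUE, reason = "family too small after pruning"))
  }
  query_seq <- gsub("-", "", f$group$seqs[[gene]])
  pruned <- prune_gene_from_db(db, fam, gene)
  if (method == "best_hit") {
    all_seqs <- unlist(lapply(pruned$families,
                              function(x) as.list(x$group$seqs)))
    names(all_seqs) <- unlist(lapply(pruned$families,
                                     function(x) names(x$group$seqs)))
    idx <- data.frame(rep_id = names(all_seqs),
                      family = rep(names(pruned$families),
                                   vapply(pruned$families,
                                          function(x) length(x$group$seqs),
                                          integer(1))),
                      subtree = "all", stringsAsFactors = FALSE)
    hits <- builtin_search(query_seq, unlist(all_seqs), idx)
    if (nrow(hits) == 0L) {
      hits <- builtin_search(query_seq, unlist(all_seqs), idx,
                             sensitive = TRUE)
    }
    ranking <- hits$rep_id
    return(list(skipped = FALSE, hit = length(ranking) > 0L &&
                  ranking[1L] == case$expected,
                top = if (length(ranking)) ranking[1L] else NA_character_,
                ranking = ranking))
  }
  res <- shoot_search(query_seq, pruned, cfg, query_id = gene,
                      query_species = db$species_map[[gene]])
  if (res$status != "ok") {
    return(list(skipped = FALSE, hit = FALSE, top = NA_character_,
                ranking = character(0), result = res))
  }
  ranking <- closest_ranking(res$results[[1L]]$tree, gene)
  list(skipped = FALSE, hit = ranking[1L] == case$expected,
       top = ranking[1L], ranking = ranking, result = res)
}

#' Mean average precision at k
#'
#' With the default `"set_overlap"` method, precision@k for a case is the
#' overlap of the top-k predicted and top-k expected gene sets divided by
#' `min(k, available genes)`; MAP@k averages precision@k over cases. The
#' `"average_precision"` method instead computes the classic AP@k (mean of
#' the running precision at every rank <= k holding a member of the expected
#' top-k, divided by `min(k, available)`).
#'
#' @param predicted,expected Character vectors (one case) or lists of
#'   character vectors (one per case), each duplicate-free and ordered
#'   closest-first.
#' @param k_max Largest k (>= 1).
#' @param method Precision definition, see above.
#' @return List with `precision` (cases x k matrix) and `map` (length
#'   `k_max` vector).
#' @export
map_at_k <- function(predicted, expected, k_max = 50L,
                     method = c("set_overlap", "average_precision")) {
  if (k_max < 1L) stop("k_max must be >= 1")
  method <- match.arg(method)
  if (!is.list(predicted)) predicted <- list(predicted)
  if (!is.list(expected)) expected <- list(expected)
  stopifnot(length(predicted) == length(expected))
  prec <- matrix(NA_real_, length(predicted), k_max)
  for (i in seq_along(predicted)) {
    p <- predicted[[i]]; e <- expected[[i]]
    if (anyDuplicated(p) || anyDuplicated(e)) {
      stop("orderings must be duplicate-free")
    }
    avail <- length(e)
    for (k in seq_len(k_max)) {
      kk <- min(k, avail)
      if (method == "set_overlap") {
        prec[i, k] <- length(intersect(utils::head(p, kk),
                                       utils::head(e, kk))) / kk
      } else {
        rel <- utils::head(e, kk)
        pk <- utils::head(p, kk)
        is_rel <- pk %in% rel
        running <- cumsum(is_rel) / seq_along(pk)
        prec[i, k] <- sum(running[is_rel]) / kk
      }
    }
  }
  list(precision = prec, map = colMeans(prec))
}

#' Precision, recall and F-score of a predicted ortholog set
#'
#' @param predicted,truth Character vectors of gene ids. Both empty gives
#'   P = R = F = 1 by convention.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
ortholog_prf <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  if (tp + fp + fn == 0L) {
    return(list(tp = 0L, fp = 0L, fn = 0L, precision = 1, recall = 1, f = 1))
  }
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f = f)
}

# non-trivial bipartitions of an unrooted leaf-labeled tree, as canonical
# strings (the side not containing the reference leaf, sorted)
tree_bipartitions <- function(tree) {
  n <- ape::Ntip(tree)
  ref <- sort(tree$tip.label)[1L]
  sets <- clade_tip_sets(tree)
  out <- character(0)
  for (node in (n + 1L):(n + tree$Nnode)) {
    s <- sets[[node]]
    side <- if (ref %in% s) setdiff(tree$tip.label, s) else s
    if (length(side) <= 1L || length(side) >= n - 1L) next
    out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric difference of the two trees' non-trivial bipartition sets
#' (trees treated as unrooted), divided by the maximum 2(n-3).
#'
#' @param t1,t2 \code{phylo} objects over identical leaf sets of >= 4
#'   leaves.
#' @return A number in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  }
  n <- ape::Ntip(t1)
  if (n < 4L) stop("trees must have at least 4 leaves")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  sym <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  sym / (2 * (n - 3))
}

#' Compare subtree-grafted against unsplit placement of identical queries
#'
#' For each cherry case, the query gene is pruned from both databases (one
#' built with a small subtree-size limit so its families are split, one
#' built unsplit from the same groups) and placed through each pipeline; the
#' normalized RF distance between the two full result trees measures the
#' topological cost of the split/graft shortcut.
#'
#' @param db_split,db_unsplit Databases built from the same homolog groups.
#' @param cases Data frame of cherry cases ([find_cherries()]).
#' @param cfg A [search_config()].
#' @return Numeric vector of per-case normalized RF distances.
#' @export
split_vs_unsplit <- function(db_split, db_unsplit, cases,
                             cfg = search_config()) {
  out <- numeric(0)
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    a <- leave_one_out(db_split, case, "shoot", cfg)
    b <- leave_one_out(db_unsplit, case, "shoot", cfg)
    if (isTRUE(a$skipped) || isTRUE(b$skipped)) next
    if (!length(a$ranking) || !length(b$ranking)) next
    ta <- a$result$results[[1L]]$tree
    tb <- b$result$results[[1L]]$tree
    if (!setequal(ta$tip.label, tb$tip.label) || ape::Ntip(ta) < 4L) next
    out <- c(out, normalized_rf(ta, tb))
  }
  out
}

#' Run the full desk-scale benchmark on a simulated database
#'
#' Reproduces the evaluation protocols: leave-one-out closest-gene accuracy
#' for the placement pipeline and the best-hit baseline, the MAP@k curve
#' against branch-length rankings in the true trees, per-case ortholog
#' precision/recall/F against the generator truth, and the normalized RF of
#' each re-placement against the original tree.
#'
#' @param db A `shoot_db` built from simulator output.
#' @param truth Truth list from [make_fixture()] or [read_fixture_truth()].
#' @param k_max MAP@k upper k.
#' @param min_support,min_median_support Cherry selection thresholds.
#' @param search_cfg A [search_config()].
#' @param max_cases Optional cap on the number of cherry cases run.
#' @param out_dir Optional directory for TSV/JSON report files.
#' @return List with `cases`, `accuracy`, `accuracy_best_hit`, `map`,
#'   `ortholog` (mean P/R/F) and `rf` (per-case normalized RF).
#' @export
run_benchmark <- function(db, truth, k_max = 50L, min_support = 95,
                          min_median_support = 95,
                          search_cfg = search_config(), max_cases = Inf,
                          out_dir = NULL) {
  fams <- names(db$families)
  truth_fams <- if (!is.null(truth$families)) names(truth$families) else
    names(truth$events)
  if (!all(fams %in% truth_fams)) {
    stop("database families missing from the truth: ",
         setdiff(fams, truth_fams)[1L])
  }
  trees <- lapply(db$families, function(f) f$group$tree)
  cases <- find_cherries(trees, min_support, min_median_support)
  if (nrow(cases) > max_cases) cases <- cases[seq_len(max_cases), ]
  rows <- list()
  rankings <- list(); expected_rankings <- list()
  prf <- list(); rf <- numeric(0)
  hits_shoot <- logical(0); hits_bh <- logical(0)
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    loo <- leave_one_out(db, case, "shoot", search_cfg)
    if (isTRUE(loo$skipped)) next
    bh <- leave_one_out(db, case, "best_hit", search_cfg)
    hits_shoot <- c(hits_shoot, isTRUE(loo$hit))
    hits_bh <- c(hits_bh, isTRUE(bh$hit))
    orig_tree <- db$families[[case$family]]$group$tree
    expected_rankings[[i]] <- closest_ranking(orig_tree, case$query)
    rankings[[i]] <- loo$ranking
    if (length(loo$ranking)) {
      result_tree <- loo$result$results[[1L]]$tree
      if (setequal(result_tree$tip.label, orig_tree$tip.label) &&
          ape::Ntip(orig_tree) >= 4L) {
        rf <- c(rf, normalized_rf(orig_tree, result_tree))
      }
      # ortholog accuracy: predicted vs generator truth for the query gene
      fam_truth <- if (!is.null(truth$families)) {
        tf <- truth$families[[case$family]]
        list(pairs = tf$ortholog_pairs)
      } else {
        op <- truth$ortholog_pairs
        list(pairs = op[op$family == case$family, , drop = FALSE])
      }
      tp <- fam_truth$pairs
      truth_orth <- c(tp$gene2[tp$gene1 == case$query],
                      tp$gene1[tp$gene2 == case$query])
      orth_tab <- loo$result$results[[1L]]$orthologs
      pred_orth <- orth_tab$gene_id[orth_tab$relation == "ortholog"]
      prf[[i]] <- ortholog_prf(pred_orth, truth_orth)
    }
    rows[[i]] <- data.frame(case, hit_shoot = isTRUE(loo$hit),
                            hit_best_hit = isTRUE(bh$hit),
                            stringsAsFactors = FALSE)
  }
  keep <- !vapply(rankings, is.null, logical(1)) & lengths(rankings) > 0L
  map <- if (any(keep)) {
    map_at_k(rankings[keep], expected_rankings[keep], k_max)
  } else NULL
  prf <- Filter(Negate(is.null), prf)
  report <- list(
    cases = if (length(rows)) do.call(rbind, rows) else cases[0, ],
    accuracy = mean(hits_shoot),
    accuracy_best_hit = mean(hits_bh),
    map = map,
    ortholog = if (length(prf)) list(
      precision = mean(vapply(prf, `[[`, numeric(1), "precision")),
      recall = mean(vapply(prf, `[[`, numeric(1), "recall")),
      f = mean(vapply(prf, `[[`, numeric(1), "f"))) else NULL,
    rf = rf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$cases, file.path(out_dir, "cases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(map)) {
      utils::write.table(
        data.frame(k = seq_along(map$map), map = map$map),
        file.path(out_dir, "map_at_k.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    jsonlite::write_json(
      list(accuracy = report$accuracy,
           accuracy_best_hit = report$accuracy_best_hit,
           ortholog = report$ortholog,
           mean_rf = if (length(rf)) mean(rf) else NA),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
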