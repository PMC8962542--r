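# Database construction: split oversized gene trees into outgroup-anchored
# subtrees linked by a supertree, extract sub-MSAs, and select k-means
# representative sequences per (sub)tree as the search profile.

#' Database build parameters
#'
#' @param max_subtree_size Largest allowed subtree member count. Trees with
#'   more genes are split into subtrees of at most this size.
#' @param rep_divisor `k = ceiling(N / rep_divisor)` representatives are
#'   selected per (sub)tree of N genes.
#' @param rep_floor Lower bound on the representative count: never fewer than
#'   `min(rep_floor, N)`.
#' @param seed Integer seed for the k-means representative selection.
#' @return A `build_config` list.
#' @export
build_config <- function(max_subtree_size = 2500L, rep_divisor = 10L,
                         rep_floor = 20L, seed = 17L) {
  stopifnot(max_subtree_size >= 3L, rep_divisor >= 1L, rep_floor >= 1L)
  structure(list(max_subtree_size = as.integer(max_subtree_size),
                 rep_divisor = as.integer(rep_divisor),
                 rep_floor = as.integer(rep_floor),
                 seed = as.integer(seed)),
            class = "build_config")
}

#' Number of representative sequences for a family of N genes
#'
#' `ceiling(N / divisor)`, but never below `min(floor, N)` and never above N.
#'
#' @param N Gene count (>= 1).
#' @param cfg A [build_config()].
#' @return Integer representative count.
#' @export
n_representatives <- function(N, cfg = build_config()) {
  stopifnot(N >= 1L)
  min(N, max(ceiling(N / cfg$rep_divisor), min(cfg$rep_floor, N)))
}

#' Select the outgroup gene for a subtree
#'
#' The outgroup is the leaf outside the member set with the smallest
#' branch-length path distance to the root (MRCA) of the member clade; ties
#' are broken by the lexicographically smallest gene id.
#'
#' @param tree Family gene tree (\code{phylo}).
#' @param subtree_members Character vector of member gene ids (a proper
#'   subset of the tree's leaves).
#' @return The outgroup gene id.
#' @export
select_outgroup <- function(tree, subtree_members) {
  outsiders <- setdiff(tree$tip.label, subtree_members)
  if (length(outsiders) == 0L) stop("no leaves outside the subtree")
  anchor <- mrca_of_tips(tree, subtree_members)
  d <- node_dists_from(tree, anchor)
  idx <- match(outsiders, tree$tip.label)
  dd <- d[idx]
  best <- dd == min(dd)
  sort(outsiders[best])[1L]
}

#' Restrict an MSA to a set of rows
#'
#' Rows are restricted to `ids` (original row order kept) and columns that
#' are all-gap in the restricted rows are removed.
#'
#' @param msa Named character vector of aligned rows.
#' @param ids Gene ids to keep.
#' @return The restricted MSA.
#' @export
extract_sub_msa <- function(msa, ids) {
  missing <- setdiff(ids, names(msa))
  if (length(missing)) stop("unknown id ", missing[1L], " in sub-MSA request")
  sub <- msa[names(msa) %in% ids]
  mat <- msa_matrix(sub)
  keep <- colSums(mat != "-") > 0L
  matrix_msa(mat[, keep, drop = FALSE])
}

# one-hot encoding of an MSA: one block of 20 indicator columns per
# alignment column; gaps and 'X' are the all-zero block
msa_one_hot <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat); C <- ncol(mat)
  code <- match(mat, AA_RESIDUES)      # n*C, column-major; NA for '-'/'X'
  X <- matrix(0, n, C * 20L)
  pos <- which(!is.na(code))
  row_i <- ((pos - 1L) %% n) + 1L
  col_j <- ((pos - 1L) %/% n) + 1L
  X[cbind(row_i, (col_j - 1L) * 20L + code[pos])] <- 1
  rownames(X) <- rownames(mat)
  X
}

#' Select representative sequences by k-means on the MSA
#'
#' Rows are one-hot encoded over (column, residue) with gaps as zeros, so
#' squared Euclidean distance counts column mismatches. k-means is run with a
#' fixed seed and 10 restarts; each cluster contributes the member closest to
#' its centroid (ties by lexicographically smallest id). If fewer than k
#' distinct representatives result (empty/collapsed clusters), the unselected
#' sequence farthest from its assigned centroid is added until k exist.
#'
#' @param sub_msa Member-only MSA (the outgroup row is excluded by callers).
#' @param cfg A [build_config()].
#' @return Character vector of representative gene ids (length
#'   `n_representatives(N, cfg)`).
#' @export
select_representatives <- function(sub_msa, cfg = build_config()) {
  N <- length(sub_msa)
  k <- n_representatives(N, cfg)
  if (k == N) return(names(sub_msa))
  X <- msa_one_hot(sub_msa)
  ids <- rownames(X)
  k_eff <- min(k, nrow(unique(X)))
  km <- with_seed(cfg$seed,
                  stats::kmeans(X, centers = k_eff, nstart = 10L,
                                iter.max = 100L))
  reps <- character(0)
  dist_to_centroid <- numeric(N)
  for (cl in seq_len(max(km$cluster))) {
    members <- which(km$cluster == cl)
    if (length(members) == 0L) next
    d2 <- rowSums((X[members, , drop = FALSE] -
                   matrix(km$centers[cl, ], length(members), ncol(X),
                          byrow = TRUE))^2)
    dist_to_centroid[members] <- d2
    best <- members[d2 == min(d2)]
    reps <- c(reps, sort(ids[best])[1L])
  }
  while (length(reps) < k) {
    pool <- setdiff(ids, reps)
    d <- dist_to_centroid[match(pool, ids)]
    far <- pool[d == max(d)]
    reps <- c(reps, sort(far)[1L])
  }
  reps
}

# single-subtree wrapper for families at or below the size limit
unsplit_family <- function(group) {
  sid <- paste0(group$id, "_s1")
  subtrees <- list(list(id = sid, members = group$tree$tip.label,
                        outgroup = NA_character_,
                        tree = group$tree, msa = group$msa))
  names(subtrees) <- sid
  structure(list(family = group$id, is_split = FALSE, subtrees = subtrees,
                 supertree = NULL),
            class = "split_family")
}

# greedy root-to-tip partition of tip labels into sets of size <= max_size;
# every set is a clade, except that a tip stranded at a split node may be
# merged into its smallest full-child-clade sibling set at the same node
split_tip_sets <- function(tree, max_size) {
  n_tip <- ape::Ntip(tree)
  ch <- tree_children(tree)
  sizes <- integer(n_tip + tree$Nnode)
  sizes[seq_len(n_tip)] <- 1L
  for (node in postorder_nodes(tree)) {
    if (node > n_tip) sizes[node] <- sum(sizes[ch[[node]]])
  }
  tipsets <- clade_tip_sets(tree)
  rec <- function(node) {
    full <- list()    # full child clades of this node, each <= max_size
    nested <- list()  # sets produced inside oversized children
    for (c_node in ch[[node]]) {
      if (sizes[c_node] <= max_size) {
        full <- c(full, list(tipsets[[c_node]]))
      } else {
        nested <- c(nested, rec(c_node))
      }
    }
    # merge stranded singleton children into their smallest sibling
    # full-clade set at this node, when the merged size still fits
    singles <- which(lengths(full) == 1L)
    if (length(singles) && length(full) > 1L) {
      ord <- singles[order(vapply(full[singles], `[[`, character(1), 1L))]
      merged_away <- logical(length(full))
      for (i in ord) {
        if (merged_away[i]) next
        cand <- setdiff(which(!merged_away), i)
        if (!length(cand)) next
        sz <- lengths(full)[cand]
        ok <- cand[sz + 1L <= max_size]
        if (!length(ok)) next
        tgt <- ok[order(lengths(full)[ok])][1L]
        full[[tgt]] <- c(full[[tgt]], full[[i]])
        merged_away[i] <- TRUE
      }
      full <- full[!merged_away]
    }
    c(full, nested)
  }
  sets <- rec(tree_root(tree))
  # deterministic order: by first appearance of a member in tip order
  first <- vapply(sets, function(s) min(match(s, tree$tip.label)), numeric(1))
  sets[order(first)]
}

# contract each member set to a single leaf named by its subtree id
contract_to_supertree <- function(tree, member_sets, ids) {
  reps <- vapply(member_sets,
                 function(s) s[which.min(match(s, tree$tip.label))],
                 character(1))
  st <- ape::keep.tip(tree, reps)
  st$tip.label <- ids[match(st$tip.label, reps)]
  st$node.label <- NULL
  st
}

#' Split an oversized gene tree into outgroup-anchored subtrees
#'
#' Families at or below `max_subtree_size` are returned unsplit. Larger trees
#' are partitioned by a greedy root-to-tip traversal: every maximal clade of
#' size at most the limit becomes one subtree (stranded single leaves are
#' merged into their smallest sibling subtree when the result still fits).
#' Each subtree gains one outgroup gene ([select_outgroup()]) and its sub-MSA
#' ([extract_sub_msa()] over members plus outgroup); a supertree records how
#' the subtrees relate (the original tree with each member set contracted to
#' a leaf named by subtree id).
#'
#' @param group A [homolog_group()].
#' @param cfg A [build_config()].
#' @return A `split_family` object.
#' @export
split_large_tree <- function(group, cfg = build_config()) {
  if (group$n <= cfg$max_subtree_size) return(unsplit_family(group))
  sets <- split_tip_sets(group$tree, cfg$max_subtree_size)
  ids <- paste0(group$id, "_s", seq_along(sets))
  subtrees <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    members <- sets[[i]]
    og <- select_outgroup(group$tree, members)
    subtrees[[i]] <- list(
      id = ids[i], members = members, outgroup = og,
      tree = ape::keep.tip(group$tree, c(members, og)),
      msa = extract_sub_msa(group$msa, c(members, og)))
  }
  names(subtrees) <- ids
  structure(list(family = group$id, is_split = TRUE, subtrees = subtrees,
                 supertree = contract_to_supertree(group$tree, sets, ids)),
            class = "split_family")
}

#' @export
print.split_family <- function(x, ...) {
  if (x$is_split) {
    cat("Split family", x$family, "with", length(x$subtrees), "subtrees (",
        paste(vapply(x$subtrees, function(s) length(s$members), integer(1)),
              collapse = ", "), "members )\n")
  } else {
    cat("Unsplit family", x$family, "(",
        length(x$subtrees[[1]]$members), "genes )\n")
  }
  invisible(x)
}

#' Build a searchable database from homolog groups
#'
#' Splits every oversized family ([split_large_tree()]), selects k-means
#' representative sequences per (sub)tree ([select_representatives()]) and
#' assembles the profile table mapping each representative to its
#' (family, subtree). Gene ids must be unique database-wide.
#'
#' @param groups List of [homolog_group()] objects.
#' @param species_map Named character vector: gene id to species id, covering
#'   every gene.
#' @param cfg A [build_config()].
#' @param path Optional output directory; when given the database is written
#'   to disk via [save_database()].
#' @return A `shoot_db` object.
#' @export
build_database <- function(groups, species_map, cfg = build_config(),
                           path = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- vapply(groups, `[[`, character(1), "id")
  }
  seen <- character(0)
  seen_fam <- character(0)
  for (g in groups) {
    clash <- intersect(names(g$seqs), seen)
    if (length(clash)) {
      other <- seen_fam[match(clash[1L], seen)]
      stop("gene id ", clash[1L], " appears in both family ", other,
           " and family ", g$id)
    }
    seen <- c(seen, names(g$seqs))
    seen_fam <- c(seen_fam, rep(g$id, length(g$seqs)))
  }
  unmapped <- setdiff(seen, names(species_map))
  if (length(unmapped)) {
    stop("gene ", unmapped[1L], " missing from the species map")
  }
  fams <- list()
  profiles <- list()
  for (g in groups) {
    split <- split_large_tree(g, cfg)
    for (s in split$subtrees) {
      member_msa <- extract_sub_msa(g$msa, s$members)
      reps <- select_representatives(member_msa, cfg)
      profiles[[length(profiles) + 1L]] <-
        data.frame(rep_id = reps, family = g$id, subtree = s$id,
                   stringsAsFactors = FALSE)
    }
    fams[[g$id]] <- list(group = g, split = split)
  }
  profiles <- do.call(rbind, profiles)
  params <- list(max_subtree_size = cfg$max_subtree_size,
                 rep_divisor = cfg$rep_divisor, rep_floor = cfg$rep_floor,
                 seed = cfg$seed)
  db <- new_shoot_db(fams, species_map[seen], profiles, params, path)
  if (!is.null(path)) save_database(db, path)
  db
}
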